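# Shared fixture builders and independent per-basepair oracles.

toyLayout <- function(len = c(chrA = 1e6), cen = NULL)
  GenomeLayout(len, centromeres = cen)

# a DomainSet from 0-based half-open triples on one layout
domainsFromDf <- function(df, layout)
  DomainSet(df, layout = layout)

# random disjoint NAD intervals on one chromosome, as a DomainSet
randomNadSet <- function(layout, chrom = names(chromLengths(layout))[1],
                         n = 5, seed = 1, tile = FALSE) {
  set.seed(seed)
  L <- chromLengths(layout)[[chrom]]
  cuts <- sort(sample.int(L - 1, 2 * n))
  df <- data.frame(chrom = chrom,
                   start = cuts[seq(1, 2 * n, 2)] - 1,
                   end = cuts[seq(2, 2 * n, 2)],
                   label = "NAD")
  if (tile) {
    # add the complement as labeled iNAD so the set tiles the chromosome
    bounds <- c(0, as.vector(rbind(df$start, df$end)), L)
    inad <- data.frame(chrom = chrom,
                       start = bounds[seq(1, length(bounds), 2)],
                       end = bounds[seq(2, length(bounds), 2)],
                       label = "iNAD")
    df <- rbind(df, inad[inad$end > inad$start, ])
  }
  DomainSet(df, layout = layout)
}

# --- per-basepair boolean oracle -------------------------------------
# a set of intervals on one chromosome as a logical vector: element i
# is TRUE when base [i-1, i) is covered

bpVector <- function(gr, L, chrom = NULL) {
  v <- logical(L)
  if (!is.null(chrom)) gr <- gr[as.character(seqnames(gr)) == chrom]
  for (k in seq_along(gr)) v[start(gr)[k]:end(gr)[k]] <- TRUE
  v
}

# logical vector back to the number of covered bp / interval count
bpRuns <- function(v) {
  r <- rle(v)
  sum(r$values)
}

# an EnrichmentTrack from explicit positions/values on one chromosome
enrTrack <- function(pos, values, chrom = "chrA", layout = NULL) {
  v <- as.matrix(values)
  gr <- GRanges(chrom, IRanges(as.integer(pos), width = 1L))
  if (!is.null(layout)) {
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(layout@seqinfo)
    GenomeInfoDb::seqinfo(gr) <- layout@seqinfo
  }
  colnames(v) <- paste0("E", seq_len(ncol(v)))
  new("EnrichmentTrack", probes = gr, values = v)
}

# bedGraph-like signal GRanges from 0-based half-open triples
signalGr <- function(chrom, start, end, score)
  GRanges(chrom, IRanges(start + 1L, end), score = score)

# brute-force Euclidean distance of every TRUE pixel to the nearest
# FALSE pixel (exhaustive; for small masks only)
bruteDistToBackground <- function(mask) {
  d <- array(Inf, dim(mask))
  bg <- which(!mask, arr.ind = TRUE)
  fg <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(fg)))
    d[fg[k, 1], fg[k, 2]] <-
      sqrt(min((bg[, 1] - fg[k, 1])^2 + (bg[, 2] - fg[k, 2])^2))
  d
}

# independent connected-component count: iterative min-label
# propagation to a fixpoint (different algorithm from the package BFS)
oracleComponentCount <- function(mask) {
  d <- dim(mask); nx <- d[1]; ny <- d[2]
  lab <- matrix(0L, nx, ny)
  lab[mask] <- seq_len(sum(mask))
  idx <- which(mask, arr.ind = TRUE)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(idx))) {
      x <- idx[k, 1]; y <- idx[k, 2]
      xs <- max(1, x - 1):min(nx, x + 1)
      ys <- max(1, y - 1):min(ny, y + 1)
      nb <- lab[xs, ys]
      m <- min(nb[nb > 0])
      if (m < lab[x, y]) { lab[x, y] <- m; changed <- TRUE }
    }
    if (!changed) break
  }
  length(unique(lab[lab > 0]))
}

# uniform-intensity toy nucleus image from explicit masks
toyImage <- function(nucleus, nucleolus = NULL, intensity = NULL,
                     pixelSize = 80.25) {
  if (is.null(nucleolus)) nucleolus <- array(FALSE, dim(nucleus))
  if (is.null(intensity)) intensity <- array(as.numeric(nucleus), dim(nucleus))
  new("NucleusImage", intensity = intensity, nucleusMask = nucleus,
      nucleolusMask = nucleolus, pixelSize = pixelSize, zStep = NA_real_)
}
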