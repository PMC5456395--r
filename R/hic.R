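# Domain-class analysis of normalized intrachromosomal Hi-C contacts.

#' Accessors for ContactSet
#' @param x A [ContactSet-class].
#' @name ContactSet-accessors
NULL

#' @rdname ContactSet-accessors
#' @export
setMethod("contactRecords", "ContactSet", function(x) x@contacts)

#' @rdname ContactSet-accessors
#' @export
setMethod("binSize", "ContactSet", function(x) x@binSize)

#' @rdname ContactSet-accessors
#' @export
setMethod("dropStats", "ContactSet", function(x) x@stats)

setMethod("show", "ContactSet", function(object) {
  df <- object@contacts
  cat("ContactSet:", nrow(df), "contacts at",
      format(object@binSize, big.mark = ","), "bp bins on",
      length(unique(df$chrom)), "chromosome(s)")
  if ("pair_class" %in% names(df)) {
    tb <- table(df$pair_class)
    cat("; classes:", paste(names(tb), tb, sep = "=", collapse = ", "))
  }
  cat("\n")
  if (length(object@stats))
    cat("  dropped:", paste(names(object@stats),
                            unlist(object@stats), sep = "=",
                            collapse = ", "), "\n")
})

#' Normalize raw contact triplets with a per-bin vector
#'
#' normalized = raw / (v\[i\] * v\[j\]), with the vector indexed by
#' bin start / binSize. Records touching a NaN, NA or zero vector entry
#' are dropped and counted.
#'
#' @param triplets data.frame with columns bin_i, bin_j (bin-start bp)
#'   and raw.
#' @param norm Numeric normalization vector, one entry per bin.
#' @param binSize Bin size in bp.
#' @param chrom Chromosome name for the records.
#' @return A [ContactSet-class] with the drop count in `dropStats()`.
#' @export
normalizeContacts <- function(triplets, norm, binSize = 10000L,
                              chrom = "chr1") {
  bi <- triplets$bin_i; bj <- triplets$bin_j
  if (any(bi %% binSize != 0) || any(bj %% binSize != 0))
    stop("triplet coordinates are not multiples of the bin size")
  ii <- bi / binSize + 1L; jj <- bj / binSize + 1L
  if (max(ii, jj) > length(norm))
    stop("normalization vector shorter than the largest bin index")
  vi <- norm[ii]; vj <- norm[jj]
  bad <- !is.finite(vi) | !is.finite(vj) | vi == 0 | vj == 0
  freq <- triplets$raw[!bad] / (vi[!bad] * vj[!bad])
  swap <- bi[!bad] > bj[!bad]
  b1 <- ifelse(swap, bj[!bad], bi[!bad])
  b2 <- ifelse(swap, bi[!bad], bj[!bad])
  df <- data.frame(chrom = chrom, bin_i = b1, bin_j = b2,
                   freq = freq, distance = b2 - b1)
  new("ContactSet", contacts = df, binSize = as.numeric(binSize),
      stats = list(dropped_norm = sum(bad)))
}

#' Load and normalize a sparse contact triplet file
#'
#' Reads a whitespace-separated `bin_i_start  bin_j_start  raw_count`
#' file and a one-value-per-line normalization vector file (NaN entries
#' allowed), and returns normalized contacts.
#'
#' @param tripletFile,normFile File paths.
#' @param binSize Bin size in bp (default 10 kb).
#' @param chrom Chromosome name of the files.
#' @return A [ContactSet-class].
#' @export
loadNormalizedContacts <- function(tripletFile, normFile,
                                   binSize = 10000L, chrom = "chr1") {
  tri <- data.table::fread(tripletFile, header = FALSE,
                           col.names = c("bin_i", "bin_j", "raw"))
  v <- as.numeric(readLines(normFile))
  normalizeContacts(as.data.frame(tri), v, binSize = binSize, chrom = chrom)
}

#' Majority-overlap NAD labels for fixed-size bins
#'
#' Labels each bin of one chromosome "NAD" when at least half its bases
#' overlap the NAD set (exact ties go to NAD), "iNAD" otherwise, and NA
#' for bins whose majority lies inside the centromere gap.
#'
#' @param chrom Chromosome name.
#' @param nBins Number of bins.
#' @param binSize Bin size in bp.
#' @param nads NAD intervals (`GRanges` or [DomainSet-class]).
#' @param layout A [GenomeLayout-class] (for the centromere interval).
#' @return Character vector of length `nBins` with NA at centromere bins.
#' @export
binDomainLabels <- function(chrom, nBins, binSize, nads, layout) {
  bins <- GRanges(chrom, IRanges((seq_len(nBins) - 1L) * binSize + 1L,
                                 width = binSize))
  nadBp <- overlapBp(bins, asRanges(nads))
  lab <- ifelse(nadBp * 2 >= binSize, "NAD", "iNAD")
  cen <- centromeres(layout)
  cen <- cen[as.character(seqnames(cen)) == chrom]
  if (length(cen)) {
    cenBp <- overlapBp(bins, cen)
    lab[cenBp * 2 >= binSize] <- NA
  }
  lab
}

# arm of each bin: "p" before the centromere start, "q" after its end,
# NA inside; without a centromere everything is "q"
binArms <- function(chrom, nBins, binSize, layout) {
  mid <- (seq_len(nBins) - 0.5) * binSize
  cen <- centromeres(layout)
  cen <- cen[as.character(seqnames(cen)) == chrom]
  if (!length(cen)) return(rep("q", nBins))
  ifelse(mid < start(cen), "p", ifelse(mid > end(cen), "q", NA))
}

#' Classify contacts by domain pair class and chromosome arm
#'
#' Assigns each contact a `pair_class` (NAD-NAD, iNAD-iNAD, or mixed)
#' from the majority-overlap NAD labels of its two bins, and an
#' `arm_class` (pp, qq intra-arm; pq inter-arm) from the bins' position
#' relative to the centromere. Contacts touching unlabeled (centromeric)
#' bins or bins beyond the chromosome end are dropped and counted.
#'
#' @param x A [ContactSet-class].
#' @param nads NAD intervals (`GRanges` or [DomainSet-class]).
#' @param layout A [GenomeLayout-class].
#' @return The classified [ContactSet-class]; conservation holds:
#'   input rows = output rows + dropped counts.
#' @export
classifyContacts <- function(x, nads, layout) {
  df <- contactRecords(x)
  bs <- binSize(x)
  len <- chromLengths(layout)
  out <- list(); droppedCen <- 0L
  for (chr in unique(df$chrom)) {
    sub <- df[df$chrom == chr, , drop = FALSE]
    if (!chr %in% names(len)) stop("chromosome ", chr, " not in layout")
    nBins <- floor(len[[chr]] / bs)
    if (any(sub$bin_j / bs + 1L > nBins + (len[[chr]] %% bs > 0)))
      stop("contact bin beyond the end of ", chr)
    lab <- binDomainLabels(chr, nBins, bs, nads, layout)
    arm <- binArms(chr, nBins, bs, layout)
    li <- lab[sub$bin_i / bs + 1L]; lj <- lab[sub$bin_j / bs + 1L]
    ai <- arm[sub$bin_i / bs + 1L]; aj <- arm[sub$bin_j / bs + 1L]
    keep <- !is.na(li) & !is.na(lj) & !is.na(ai) & !is.na(aj)
    droppedCen <- droppedCen + sum(!keep)
    sub <- sub[keep, , drop = FALSE]
    li <- li[keep]; lj <- lj[keep]; ai <- ai[keep]; aj <- aj[keep]
    sub$pair_class <- ifelse(li == "NAD" & lj == "NAD", "NAD-NAD",
                        ifelse(li == "iNAD" & lj == "iNAD",
                               "iNAD-iNAD", "mixed"))
    sub$arm_class <- ifelse(ai == aj, paste0(ai, ai), "pq")
    out[[chr]] <- sub
  }
  stats <- x@stats
  stats$dropped_centromere <- droppedCen
  new("ContactSet", contacts = do.call(rbind, out), binSize = bs,
      stats = stats)
}

#' Class-wise contact frequency by distance
#'
#' Mean normalized frequency per pair class in distance bins, optionally
#' split by arm class. The default denominator averages over observed
#' records only; `denominator = "all"` divides by the number of all
#' possible bin pairs of that class and distance bin (unobserved pairs
#' count as zero), which requires `nads`/`layout` to rebuild bin labels.
#'
#' @param x A classified [ContactSet-class].
#' @param maxDistance Largest distance (bp) included.
#' @param binWidth Distance-bin width in bp.
#' @param byArm Also split by `arm_class`.
#' @param denominator "observed" (default) or "all".
#' @param nads,layout Needed for `denominator = "all"`.
#' @return data.frame: (chrom aggregated) distance (bin midpoint bp),
#'   pair_class, optional arm_class, mean, n.
#' @export
distanceProfiles <- function(x, maxDistance = Inf, binWidth = 1e6,
                             byArm = FALSE,
                             denominator = c("observed", "all"),
                             nads = NULL, layout = NULL) {
  denominator <- match.arg(denominator)
  df <- contactRecords(x)
  if (!"pair_class" %in% names(df))
    stop("classify the contacts first (classifyContacts)")
  df <- df[df$distance <= maxDistance & df$distance > 0, , drop = FALSE]
  df$dbin <- floor(df$distance / binWidth)
  keys <- c("dbin", "pair_class", if (byArm) "arm_class")
  dt <- data.table::as.data.table(df)
  agg <- dt[, list(sum = sum(freq), n = .N), by = keys]
  agg <- as.data.frame(agg)
  if (denominator == "observed") {
    agg$mean <- agg$sum / agg$n
  } else {
    if (is.null(nads) || is.null(layout))
      stop("denominator='all' needs nads and layout")
    if (byArm) stop("denominator='all' is not implemented with byArm")
    tot <- allPairCounts(x, nads, layout, binWidth, maxDistance)
    key <- paste(agg$dbin, agg$pair_class)
    agg$nAll <- tot[key]
    agg$mean <- agg$sum / agg$nAll
    agg$n <- agg$nAll
    agg$nAll <- NULL
  }
  agg$distance <- (agg$dbin + 0.5) * binWidth
  agg$sum <- NULL
  agg[order(agg$dbin, agg$pair_class), c("distance", keys[-1], "mean", "n")]
}

# number of possible bin pairs per distance bin and pair class
allPairCounts <- function(x, nads, layout, binWidth, maxDistance) {
  bs <- binSize(x)
  len <- chromLengths(layout)
  env <- new.env()
  for (chr in unique(contactRecords(x)$chrom)) {
    nBins <- floor(len[[chr]] / bs)
    lab <- binDomainLabels(chr, nBins, bs, nads, layout)
    isN <- !is.na(lab) & lab == "NAD"
    isI <- !is.na(lab) & lab == "iNAD"
    maxd <- min(nBins - 1L, floor(maxDistance / bs))
    for (d in seq_len(maxd)) {
      a <- seq_len(nBins - d); b <- a + d
      ok <- !is.na(lab[a]) & !is.na(lab[b])
      nn <- sum(isN[a] & isN[b])
      ii <- sum(isI[a] & isI[b])
      mx <- sum(ok) - nn - ii
      db <- floor(d * bs / binWidth)
      for (p in c("NAD-NAD", "iNAD-iNAD", "mixed")) {
        k <- paste(db, p)
        add <- switch(p, "NAD-NAD" = nn, "iNAD-iNAD" = ii, mixed = mx)
        env[[k]] <- (if (is.null(env[[k]])) 0 else env[[k]]) + add
      }
    }
  }
  unlist(as.list(env))
}

#' Per-chromosome class means in fixed distance bands
#'
#' For each chromosome and pair class, the mean normalized frequency of
#' the 10 kb-window pairs whose distance falls in each band (default
#' 10-50 Mb -- the lower bound excludes intra-domain contacts -- and
#' >100 Mb). Chromosomes too short for a band are omitted with a
#' warning.
#'
#' @param x A classified [ContactSet-class].
#' @param bands List of length-2 bp ranges (use Inf for open upper
#'   bounds).
#' @return data.frame: chrom, band, pair_class, mean, n.
#' @export
bandSummaries <- function(x,
                          bands = list(`10-50Mb` = c(10e6, 50e6),
                                       `>100Mb` = c(100e6, Inf))) {
  df <- contactRecords(x)
  if (!"pair_class" %in% names(df))
    stop("classify the contacts first (classifyContacts)")
  if (is.null(names(bands)))
    names(bands) <- vapply(bands, function(b)
      paste0(b[1] / 1e6, "-", b[2] / 1e6, "Mb"), character(1))
  out <- list()
  for (chr in unique(df$chrom)) {
    sub <- df[df$chrom == chr, , drop = FALSE]
    span <- max(sub$bin_j)
    for (bn in names(bands)) {
      b <- bands[[bn]]
      if (span < b[1]) {
        warning("chromosome ", chr, " too short for band ", bn,
                "; omitted")
        next
      }
      inb <- sub[sub$distance >= b[1] & sub$distance <= b[2], ,
                 drop = FALSE]
      if (!nrow(inb)) { warning("band ", bn, " empty on ", chr); next }
      agg <- tapply(inb$freq, inb$pair_class, mean)
      nagg <- tapply(inb$freq, inb$pair_class, length)
      out[[paste(chr, bn)]] <- data.frame(
        chrom = chr, band = bn, pair_class = names(agg),
        mean = as.numeric(agg), n = as.integer(nagg))
    }
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Dense symmetric matrix of a chromosome's contacts
#'
#' @param x A [ContactSet-class].
#' @param chrom Chromosome to extract.
#' @param nBins Matrix dimension; defaults to the largest seen bin + 1.
#' @return Symmetric numeric matrix (unobserved pairs 0) with the bin
#'   start coordinates as dimnames.
#' @export
contactMatrix <- function(x, chrom, nBins = NULL) {
  df <- contactRecords(x)
  df <- df[df$chrom == chrom, , drop = FALSE]
  bs <- binSize(x)
  if (is.null(nBins)) nBins <- max(df$bin_j) / bs + 1L
  m <- matrix(0, nBins, nBins)
  ii <- df$bin_i / bs + 1L; jj <- df$bin_j / bs + 1L
  m[cbind(ii, jj)] <- df$freq
  m[cbind(jj, ii)] <- df$freq
  dimnames(m) <- list((seq_len(nBins) - 1L) * bs,
                      (seq_len(nBins) - 1L) * bs)
  m
}

#' Mask a dense contact matrix to one domain class
#'
#' Sets rows and columns of bins outside the kept class to NA, leaving
#' kept entries bit-identical (used to visualize homotypic contacts).
#'
#' @param mat Square symmetric matrix.
#' @param labels Per-bin labels ("NAD"/"iNAD", NA allowed).
#' @param keep "NAD" or "iNAD".
#' @return The masked matrix.
#' @export
maskMatrix <- function(mat, labels, keep = c("NAD", "iNAD")) {
  keep <- match.arg(keep)
  stopifnot(nrow(mat) == ncol(mat), length(labels) == nrow(mat))
  drop <- is.na(labels) | labels != keep
  mat[drop, ] <- NA
  mat[, drop] <- NA
  mat
}
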