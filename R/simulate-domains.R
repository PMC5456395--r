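#' Simulate a ground-truth NAD/iNAD segmentation
#'
#' Tiles each chromosome with alternating NAD and iNAD segments whose
#' lengths are exponential with the stated means (truncated at chromosome
#' ends) -- the segment-length law implied by a two-state Markov process.
#' Defaults give a NAD genome fraction near 0.38 with NAD widths in the
#' few-hundred-kb range, the regime typical of nucleolus-associated
#' domains in human fibroblasts.
#'
#' @param layout A [GenomeLayout-class].
#' @param meanNadLen,meanInadLen Mean segment lengths in bp.
#' @param seed Integer seed; the result is bit-reproducible given the seed.
#' @return A [DomainSet-class] that tiles every chromosome exactly
#'   (alternating labels, no gaps or overlaps).
#' @examples
#' truth <- simulateDomainTruth(GenomeLayout(c(chr1 = 1e7)), seed = 1)
#' sum(GenomicRanges::width(domainRanges(truth)))  # == 1e7
#' @export
simulateDomainTruth <- function(layout, meanNadLen = 4e5, meanInadLen = 6.5e5,
                                seed = 1L) {
  stopifnot(meanNadLen > 0, meanInadLen > 0)
  len <- chromLengths(layout)
  if (any(len <= 0)) stop("zero-length chromosome in layout")
  set.seed(seed)
  nadFrac <- meanNadLen / (meanNadLen + meanInadLen)
  out <- lapply(names(len), function(chr) {
    L <- as.numeric(len[[chr]])
    lab <- if (runif(1) < nadFrac) "NAD" else "iNAD"
    starts <- c(); ends <- c(); labs <- c()
    pos <- 0
    while (pos < L) {
      m <- if (lab == "NAD") meanNadLen else meanInadLen
      w <- max(1, round(rexp(1, rate = 1 / m)))
      e <- min(pos + w, L)
      starts <- c(starts, pos); ends <- c(ends, e); labs <- c(labs, lab)
      pos <- e
      lab <- if (lab == "NAD") "iNAD" else "NAD"
    }
    data.frame(chrom = chr, start = starts, end = ends, label = labs)
  })
  df <- do.call(rbind, out)
  DomainSet(df, layout = layout)
}

#' Simulate replicate nucleolar and background probe tracks
#'
#' Places probes on a regular grid and draws, per probe and replicate, a
#' log2 nucleolar-over-background enrichment from the Gaussian of the
#' true underlying state (bimodal overall signal). Background intensities
#' get independent per-replicate noise around a common baseline;
#' nucleolar intensities are background plus the enrichment, and both are
#' returned on the raw (linear) intensity scale so the full
#' normalization/enrichment pipeline can be exercised.
#'
#' @param truth A [DomainSet-class] ground-truth segmentation.
#' @param meanNad,meanInad True per-state enrichment means (log2 units).
#' @param sdNad,sdInad Per-state emission sds (log2 units, >= 0; 0 gives
#'   the degenerate noiseless limit).
#' @param probeSpacing Probe grid spacing in bp.
#' @param nReplicates Replicates per fraction.
#' @param baselineLog2 Background baseline, log2 intensity units.
#' @param backgroundSd Per-probe background noise sd (log2 units).
#' @param seed Integer seed.
#' @return List with elements `nucleolar` and `background`
#'   ([ProbeTrack-class]s of raw intensities), `enrichment` (the true
#'   per-replicate log2 enrichment draws as an [EnrichmentTrack-class])
#'   and `stateMean` (numeric per-probe true state mean).
#' @export
simulateEnrichmentArrays <- function(truth, meanNad = 1, meanInad = -1,
                                     sdNad = 0.3, sdInad = 0.3,
                                     probeSpacing = 1000L, nReplicates = 2L,
                                     baselineLog2 = 10, backgroundSd = 0.25,
                                     seed = 1L) {
  stopifnot(meanNad > meanInad, sdNad >= 0, sdInad >= 0, probeSpacing > 0,
            nReplicates >= 1)
  layout <- genomeLayout(truth)
  len <- chromLengths(layout)
  gr <- domainRanges(truth)
  minSeg <- min(width(gr))
  if (probeSpacing > minSeg)
    warning("probe spacing exceeds the smallest segment; ",
            "some segments will contain no probe")
  set.seed(seed)
  chrom <- character(0); pos <- integer(0)
  for (chr in names(len)) {
    p <- seq.int(1L, as.integer(len[[chr]]), by = as.integer(probeSpacing))
    chrom <- c(chrom, rep(chr, length(p)))
    pos <- c(pos, p)
  }
  probes <- GRanges(chrom, IRanges(pos, width = 1L), seqinfo = layout@seqinfo)
  hit <- findOverlaps(probes, gr, select = "first")
  lab <- as.character(mcols(gr)$label)[hit]
  mu <- ifelse(lab == "NAD", meanNad, meanInad)
  sdv <- ifelse(lab == "NAD", sdNad, sdInad)
  n <- length(probes)
  E <- matrix(rnorm(n * nReplicates, mean = mu, sd = sdv), nrow = n)
  B <- matrix(rnorm(n * nReplicates, mean = baselineLog2, sd = backgroundSd),
              nrow = n)
  N <- B + E
  mk <- function(v, prefix)
    ProbeTrack(chrom, pos, 2^v, layout = layout,
               sampleLabels = paste0(prefix, seq_len(ncol(v))))
  etrack <- new("EnrichmentTrack",
                probes = probes,
                values = `colnames<-`(E, paste0("rep", seq_len(nReplicates))))
  list(nucleolar = mk(N, "nucleolar_rep"),
       background = mk(B, "background_rep"),
       enrichment = etrack,
       stateMean = mu)
}
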