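#' Construct a DomainSet
#'
#' @param ranges A `GRanges`, or a data.frame with columns `chrom`,
#'   `start`, `end` in 0-based half-open (BED) coordinates.
#' @param label Character/factor of "NAD"/"iNAD" per interval (or a
#'   `label` metadata column on `ranges`).
#' @param score Numeric score per interval (mean log2 enrichment); NA
#'   allowed.
#' @param layout A [GenomeLayout-class].
#' @return A [DomainSet-class].
#' @export
DomainSet <- function(ranges, label = NULL, score = NULL, layout) {
  if (is.data.frame(ranges)) {
    gr <- GRanges(ranges$chrom, IRanges(ranges$start + 1L, ranges$end))
    if (is.null(label) && !is.null(ranges$label)) label <- ranges$label
    if (is.null(score) && !is.null(ranges$score)) score <- ranges$score
  } else {
    gr <- granges(ranges, use.mcols = FALSE)
    if (is.null(label)) label <- mcols(ranges)$label
    if (is.null(score)) score <- mcols(ranges)$score
  }
  if (is.null(label)) stop("domain labels are required")
  if (is.null(score)) score <- rep(NA_real_, length(gr))
  mcols(gr)$label <- factor(as.character(label), levels = c("NAD", "iNAD"))
  mcols(gr)$score <- as.numeric(score)
  seqlevels(gr) <- seqlevels(layout@seqinfo)
  seqinfo(gr) <- layout@seqinfo
  gr <- GenomicRanges::sort(gr)
  new("DomainSet", ranges = gr, layout = layout)
}

#' @describeIn DomainSet All intervals as a GRanges with `label` and
#'   `score` metadata columns.
#' @param x A DomainSet.
#' @param label Optional label ("NAD"/"iNAD") to subset to.
#' @param ... Unused.
#' @export
setMethod("domainRanges", "DomainSet", function(x, label = NULL, ...) {
  gr <- x@ranges
  if (!is.null(label)) gr <- gr[as.character(mcols(gr)$label) == label]
  gr
})

#' @describeIn DomainSet Interval labels.
#' @export
setMethod("domainLabels", "DomainSet",
          function(x) as.character(mcols(x@ranges)$label))

#' @describeIn DomainSet Interval scores.
#' @export
setMethod("domainScores", "DomainSet", function(x) mcols(x@ranges)$score)

#' @describeIn DomainSet NAD intervals only (bare ranges).
#' @export
setMethod("nadRanges", "DomainSet",
          function(x) granges(domainRanges(x, "NAD")))

#' @describeIn DomainSet iNAD intervals only (bare ranges).
#' @export
setMethod("inadRanges", "DomainSet",
          function(x) granges(domainRanges(x, "iNAD")))

#' @describeIn DomainSet The underlying GenomeLayout.
#' @export
setMethod("genomeLayout", "DomainSet", function(x) x@layout)

#' @export
setMethod("length", "DomainSet", function(x) length(x@ranges))

setMethod("show", "DomainSet", function(object) {
  gr <- object@ranges
  lab <- as.character(mcols(gr)$label)
  nadbp <- sum(as.numeric(width(gr)[lab == "NAD"]))
  cat("DomainSet:", sum(lab == "NAD"), "NADs (",
      format(nadbp, big.mark = ","), "bp ),",
      sum(lab == "iNAD"), "iNADs on",
      length(unique(as.character(seqnames(gr)))), "chromosome(s)\n")
})

#' Summary statistics of a domain set's NAD intervals
#'
#' Count, total length, median/quartile widths and the number of NADs
#' wider than a threshold (the filter used for border metaprofiles).
#'
#' @param x A [DomainSet-class].
#' @param widthThreshold Width filter in bp (default 500 kb).
#' @return A one-row data.frame.
#' @export
nadSetSummary <- function(x, widthThreshold = 5e5) {
  w <- as.numeric(width(nadRanges(x)))
  data.frame(n = length(w),
             total_bp = sum(w),
             median_width = if (length(w)) median(w) else NA_real_,
             q1_width = if (length(w)) unname(quantile(w, 0.25)) else NA_real_,
             q3_width = if (length(w)) unname(quantile(w, 0.75)) else NA_real_,
             n_above_threshold = sum(w > widthThreshold),
             genome_fraction = sum(w) /
               sum(as.numeric(chromLengths(genomeLayout(x)))))
}

#' Base-pair accuracy of a called segmentation against a truth
#'
#' Fraction of analyzed base pairs whose called label (NAD/iNAD) matches
#' the true label. Only the extent covered by both segmentations is
#' scored.
#'
#' @param called,truth [DomainSet-class] objects on the same layout.
#' @return Fraction in \[0, 1\].
#' @export
domainAccuracy <- function(called, truth) {
  common <- GenomicRanges::intersect(reduce(called@ranges, ignore.strand = TRUE),
                                     reduce(truth@ranges, ignore.strand = TRUE),
                                     ignore.strand = TRUE)
  denom <- sum(as.numeric(width(common)))
  if (denom == 0) return(NA_real_)
  agree <- 0
  for (lab in c("NAD", "iNAD")) {
    a <- GenomicRanges::intersect(granges(domainRanges(called, lab)),
                                  granges(domainRanges(truth, lab)),
                                  ignore.strand = TRUE)
    agree <- agree + sum(as.numeric(width(a)))
  }
  agree / denom
}
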