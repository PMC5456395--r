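#' GenomeLayout: chromosome lengths and centromere intervals
#'
#' Minimal description of the genome under analysis: ordered chromosome
#' names with lengths, plus an optional centromere interval per chromosome
#' used to split contacts into intra-arm (pp, qq) and inter-arm (pq)
#' classes.
#'
#' @slot seqinfo A [GenomeInfoDb::Seqinfo] with chromosome names and lengths.
#' @slot centromeres A [GenomicRanges::GRanges] with at most one interval
#'   per chromosome marking the centromere gap (may be empty).
#' @export
setClass("GenomeLayout",
  slots = c(seqinfo = "Seqinfo", centromeres = "GRanges"))

setValidity("GenomeLayout", function(object) {
  si <- object@seqinfo
  if (length(si) == 0) return("layout has no chromosomes")
  if (any(is.na(seqlengths(si)))) return("all chromosome lengths must be set")
  if (any(seqlengths(si) <= 0)) return("chromosome lengths must be positive")
  cen <- object@centromeres
  if (length(cen)) {
    if (!all(as.character(seqnames(cen)) %in% seqlevels(si)))
      return("centromere chromosome not in layout")
    if (anyDuplicated(as.character(seqnames(cen))))
      return("at most one centromere interval per chromosome")
    len <- seqlengths(si)[as.character(seqnames(cen))]
    if (any(start(cen) < 1) || any(end(cen) > len))
      return("centromere interval outside chromosome")
  }
  TRUE
})

#' ProbeTrack: ordered probe positions with per-sample values
#'
#' Probe-level measurements on a genome: width-1 positions (sorted within
#' chromosome) and a probe-by-sample value matrix. Values are raw
#' intensities or log-scale signal depending on provenance.
#'
#' @slot probes Width-1 [GenomicRanges::GRanges], sorted, strictly
#'   increasing within each chromosome.
#' @slot values Numeric matrix, one row per probe, one column per sample.
#' @export
setClass("ProbeTrack",
  slots = c(probes = "GRanges", values = "matrix"))

setValidity("ProbeTrack", function(object) {
  p <- object@probes
  v <- object@values
  if (nrow(v) != length(p)) return("values must have one row per probe")
  if (length(p)) {
    if (any(width(p) != 1)) return("probes must be width-1 positions")
    bychr <- split(start(p), as.character(seqnames(p)))
    if (!all(vapply(bychr, function(x) all(diff(x) > 0), logical(1))))
      return("probe positions must be strictly increasing within chromosome")
    if (any(!is.finite(v))) return("probe values must be finite")
  }
  TRUE
})

#' EnrichmentTrack: per-probe log2 nucleolar enrichment
#'
#' A [ProbeTrack] whose values are log2-fold enrichment of the nucleolar
#' signal over the background (one column per sample, or a single averaged
#' column).
#'
#' @export
setClass("EnrichmentTrack", contains = "ProbeTrack")

#' TwoStateHMM: fitted two-state Gaussian hidden Markov model
#'
#' Parameters of the segmentation model: a 2x2 row-stochastic transition
#' matrix, Gaussian emission means and standard deviations per state, the
#' initial state distribution, and the Baum-Welch log-likelihood
#' trajectory. By convention state "NAD" is the state with the larger
#' emission mean.
#'
#' @slot transition 2x2 row-stochastic matrix, rows/cols named NAD, iNAD.
#' @slot means,sds Named numeric(2), log2 units.
#' @slot initProb Named numeric(2), initial state distribution.
#' @slot logLik Numeric vector, log-likelihood per Baum-Welch iteration.
#' @slot converged Logical.
#' @slot nIter Integer, iterations used.
#' @export
setClass("TwoStateHMM",
  slots = c(transition = "matrix", means = "numeric", sds = "numeric",
            initProb = "numeric", logLik = "numeric",
            converged = "logical", nIter = "integer"))

setValidity("TwoStateHMM", function(object) {
  A <- object@transition
  if (!all(dim(A) == c(2, 2))) return("transition must be 2x2")
  if (any(abs(rowSums(A) - 1) > 1e-8)) return("transition rows must sum to 1")
  if (any(object@sds <= 0)) return("emission sds must be positive")
  if (object@means["NAD"] < object@means["iNAD"])
    return("NAD state must have the larger emission mean")
  TRUE
})

#' DomainSet: labeled, scored genome segmentation
#'
#' Sorted disjoint intervals labeled NAD or iNAD, each carrying a score
#' (mean log2 enrichment of its probes, where applicable), tied to a
#' [GenomeLayout].
#'
#' @slot ranges [GenomicRanges::GRanges] with metadata columns `label`
#'   (factor, NAD/iNAD) and `score` (numeric, may be NA).
#' @slot layout The [GenomeLayout] the intervals live on.
#' @export
setClass("DomainSet",
  slots = c(ranges = "GRanges", layout = "GenomeLayout"))

setValidity("DomainSet", function(object) {
  gr <- object@ranges
  if (length(gr)) {
    if (is.null(mcols(gr)$label)) return("ranges need a 'label' column")
    if (!all(as.character(mcols(gr)$label) %in% c("NAD", "iNAD")))
      return("labels must be NAD or iNAD")
    if (!IRanges::isDisjoint(gr)) return("intervals must be disjoint")
    len <- seqlengths(object@layout@seqinfo)
    chr <- as.character(seqnames(gr))
    if (!all(chr %in% names(len))) return("interval chromosome not in layout")
    if (any(end(gr) > len[chr])) return("interval exceeds chromosome length")
  }
  TRUE
})

#' DifferentialDomains: condition-specific and shared domains
#'
#' The partition of two conditions' NAD sets into young-only,
#' senescent-only and constitutive (shared) intervals.
#'
#' @slot youngOnly,senescentOnly,constitutive [GenomicRanges::GRanges].
#' @slot layout The common [GenomeLayout].
#' @export
setClass("DifferentialDomains",
  slots = c(youngOnly = "GRanges", senescentOnly = "GRanges",
            constitutive = "GRanges", layout = "GenomeLayout"))

#' ContactSet: classified intrachromosomal Hi-C contacts
#'
#' Normalized intrachromosomal contact records at a fixed bin size, with
#' optional domain-class (NAD-NAD / iNAD-iNAD / mixed) and arm-class
#' (pp / qq / pq) annotation, plus bookkeeping about dropped records.
#'
#' @slot contacts data.frame with columns chrom, bin_i, bin_j (bin start
#'   bp, bin_i <= bin_j), freq (normalized), distance, and after
#'   classification pair_class and arm_class.
#' @slot binSize Bin size in bp.
#' @slot stats List of drop counts and other bookkeeping.
#' @export
setClass("ContactSet",
  slots = c(contacts = "data.frame", binSize = "numeric", stats = "list"))

setValidity("ContactSet", function(object) {
  df <- object@contacts
  need <- c("chrom", "bin_i", "bin_j", "freq", "distance")
  if (!all(need %in% names(df)))
    return(paste("contacts need columns:", paste(need, collapse = ", ")))
  if (nrow(df)) {
    if (any(df$bin_i > df$bin_j)) return("bin_i must be <= bin_j")
    if (any(df$distance != df$bin_j - df$bin_i))
      return("distance must equal bin_j - bin_i")
    if (any(!is.finite(df$freq)) || any(df$freq < 0))
      return("frequencies must be finite and >= 0")
  }
  TRUE
})

#' MetaProfile: border-aligned average signal profile
#'
#' Mean signal per offset bin relative to aligned domain borders, one
#' column per signal track. Negative offsets are outside the domain,
#' positive offsets inside; both 5' and 3' borders contribute after
#' mirroring the 3' side.
#'
#' @slot offsets Bin-center offsets in bp relative to the border.
#' @slot values Matrix, bins x signals.
#' @slot nDomains Number of domains passing the width filter.
#' @slot nBorders Number of borders actually averaged.
#' @export
setClass("MetaProfile",
  slots = c(offsets = "numeric", values = "matrix",
            nDomains = "integer", nBorders = "integer"))

#' NucleusImage: fluorescence intensities plus nucleus/nucleolus masks
#'
#' A 2D optical section (or 3D stack) of fluorescence intensities with
#' boolean nucleus and nucleolus masks and the physical pixel calibration.
#'
#' @slot intensity Numeric array (2D or 3D), arbitrary fluorescence units.
#' @slot nucleusMask,nucleolusMask Logical arrays, same shape as intensity;
#'   nucleolusMask is a subset of nucleusMask.
#' @slot pixelSize xy pixel edge in nm.
#' @slot zStep z step in nm (3D stacks; NA for single sections).
#' @export
setClass("NucleusImage",
  slots = c(intensity = "array", nucleusMask = "array",
            nucleolusMask = "array", pixelSize = "numeric",
            zStep = "numeric"))

setValidity("NucleusImage", function(object) {
  d <- dim(object@intensity)
  if (!length(d) %in% c(2, 3)) return("intensity must be 2D or 3D")
  if (!identical(dim(object@nucleusMask), d) ||
      !identical(dim(object@nucleolusMask), d))
    return("masks must match the intensity dimensions")
  if (!is.logical(object@nucleusMask) || !is.logical(object@nucleolusMask))
    return("masks must be logical")
  if (any(object@nucleolusMask & !object@nucleusMask))
    return("nucleolus mask must lie inside the nucleus mask")
  if (object@pixelSize <= 0) return("pixelSize must be positive (nm)")
  TRUE
})

#' ShellROI: fixed-depth shell region of interest
#'
#' Boolean region marking pixels within a fixed physical distance of the
#' nuclear (lamina) or nucleolar boundary.
#'
#' @slot mask Logical array.
#' @slot origin "lamina" or "perinucleolar".
#' @slot depthNm Shell depth in nm.
#' @slot depthPx Shell depth in pixels after rounding.
#' @export
setClass("ShellROI",
  slots = c(mask = "array", origin = "character",
            depthNm = "numeric", depthPx = "integer"))
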