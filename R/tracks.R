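#' Construct a ProbeTrack
#'
#' @param chrom Chromosome name per probe (recycled if length 1).
#' @param positions Probe positions, 1-based bp (the coordinate of the
#'   width-1 probe anchor).
#' @param values Numeric matrix (probe x sample) or vector.
#' @param layout Optional [GenomeLayout-class]; if given, chromosome
#'   lengths are attached and positions validated against them.
#' @param sampleLabels Optional column labels.
#' @return A [ProbeTrack-class].
#' @export
ProbeTrack <- function(chrom, positions, values, layout = NULL,
                       sampleLabels = NULL) {
  values <- as.matrix(values)
  if (!is.null(sampleLabels)) colnames(values) <- sampleLabels
  if (is.null(colnames(values)))
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  gr <- GRanges(chrom, IRanges(as.integer(positions), width = 1L))
  if (!is.null(layout)) {
    seqlevels(gr) <- seqlevels(layout@seqinfo)
    seqinfo(gr) <- layout@seqinfo
  }
  o <- order(as.factor(seqnames(gr)), start(gr))
  new("ProbeTrack", probes = gr[o], values = values[o, , drop = FALSE])
}

newTrackLike <- function(template, values, cls = NULL) {
  if (is.null(cls)) cls <- class(template)
  new(cls, probes = template@probes, values = as.matrix(values))
}

#' @describeIn ProbeTrack Probe positions as a width-1 GRanges.
#' @param x A ProbeTrack.
#' @export
setMethod("probePositions", "ProbeTrack", function(x) x@probes)

#' @describeIn ProbeTrack Probe-by-sample value matrix.
#' @export
setMethod("trackValues", "ProbeTrack", function(x) x@values)

#' @describeIn ProbeTrack Sample labels (column names).
#' @export
setMethod("sampleLabels", "ProbeTrack", function(x) colnames(x@values))

#' @export
setMethod("length", "ProbeTrack", function(x) length(x@probes))

setMethod("show", "ProbeTrack", function(object) {
  cat(class(object), "with", length(object@probes), "probes on",
      length(unique(as.character(seqnames(object@probes)))),
      "chromosome(s),", ncol(object@values), "sample(s):",
      paste(head(colnames(object@values), 4), collapse = ", "), "\n")
})

# identical probe grids?
sameGrid <- function(a, b) {
  ga <- a@probes; gb <- b@probes
  length(ga) == length(gb) &&
    all(as.character(seqnames(ga)) == as.character(seqnames(gb))) &&
    all(start(ga) == start(gb))
}

# split a vector of per-probe values into per-chromosome pieces, in the
# track's storage order
chromFactor <- function(track)
  factor(as.character(seqnames(track@probes)),
         levels = unique(as.character(seqnames(track@probes))))
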