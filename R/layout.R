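#' Construct a GenomeLayout
#'
#' @param chromLengths Named numeric vector of chromosome lengths (bp).
#' @param centromeres Optional centromere intervals: a `GRanges`, or a
#'   data.frame with columns `chrom`, `start`, `end` in 0-based half-open
#'   (BED) coordinates.
#' @return A [GenomeLayout-class] object.
#' @examples
#' GenomeLayout(c(chr1 = 10e6, chr2 = 5e6))
#' @export
GenomeLayout <- function(chromLengths, centromeres = NULL) {
  if (is.null(names(chromLengths)) || any(!nzchar(names(chromLengths))))
    stop("chromLengths must be a named vector")
  si <- Seqinfo(seqnames = names(chromLengths),
                seqlengths = as.integer(chromLengths))
  if (is.null(centromeres)) {
    cen <- GRanges(seqinfo = si)
  } else if (is(centromeres, "GRanges")) {
    cen <- centromeres
    seqlevels(cen) <- seqlevels(si)
    seqinfo(cen) <- si
  } else {
    cen <- GRanges(centromeres$chrom,
                   IRanges(centromeres$start + 1L, centromeres$end),
                   seqinfo = si)
  }
  new("GenomeLayout", seqinfo = si, centromeres = cen)
}

#' @describeIn GenomeLayout Named chromosome lengths (bp).
#' @param x A GenomeLayout.
#' @export
setMethod("chromLengths", "GenomeLayout", function(x) seqlengths(x@seqinfo))

#' @describeIn GenomeLayout Centromere intervals as a GRanges.
#' @export
setMethod("centromeres", "GenomeLayout", function(x) x@centromeres)

setMethod("show", "GenomeLayout", function(object) {
  len <- seqlengths(object@seqinfo)
  cat("GenomeLayout with", length(len), "chromosome(s),",
      format(sum(as.numeric(len)), big.mark = ","), "bp total;",
      length(object@centromeres), "centromere interval(s)\n")
})

# Full-extent GRanges of the layout (one range per chromosome).
layoutExtent <- function(layout) {
  len <- seqlengths(layout@seqinfo)
  GRanges(names(len), IRanges(1L, as.integer(len)), seqinfo = layout@seqinfo)
}

# Read a centromere/arm table (chrom, start, end; BED-style half-open).
#' Read a centromere table
#'
#' Reads a whitespace- or tab-separated table with columns chrom, start,
#' end in 0-based half-open coordinates (the UCSC gap-table convention)
#' and returns centromere intervals as a GRanges.
#'
#' @param file Path to the table (no header required; a header line
#'   starting with "chrom" is tolerated).
#' @return A `GRanges` of centromere intervals.
#' @export
readCentromereTable <- function(file) {
  first <- readLines(file, n = 1L)
  hdr <- grepl("^chrom", first)
  df <- if (hdr) read.table(file, header = TRUE, stringsAsFactors = FALSE)
        else read.table(file, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  GRanges(df$chrom, IRanges(df$start + 1L, df$end))
}
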