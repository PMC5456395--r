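#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @export
setGeneric("centromeres", function(x) standardGeneric("centromeres"))

#' @export
setGeneric("probePositions", function(x) standardGeneric("probePositions"))

#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))

#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @export
setGeneric("domainRanges", function(x, ...) standardGeneric("domainRanges"))

#' @export
setGeneric("domainLabels", function(x) standardGeneric("domainLabels"))

#' @export
setGeneric("domainScores", function(x) standardGeneric("domainScores"))

#' @export
setGeneric("nadRanges", function(x) standardGeneric("nadRanges"))

#' @export
setGeneric("inadRanges", function(x) standardGeneric("inadRanges"))

#' @export
setGeneric("genomeLayout", function(x) standardGeneric("genomeLayout"))

#' @export
setGeneric("contactRecords", function(x) standardGeneric("contactRecords"))

#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @export
setGeneric("dropStats", function(x) standardGeneric("dropStats"))

#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @export
setGeneric("nucleusMask", function(x) standardGeneric("nucleusMask"))

#' @export
setGeneric("nucleolusMask", function(x) standardGeneric("nucleolusMask"))

#' @export
setGeneric("intensityValues", function(x) standardGeneric("intensityValues"))

#' @export
setGeneric("roiMask", function(x) standardGeneric("roiMask"))
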