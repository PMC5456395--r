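# Readers and writers for the exchange formats: BED (0-based,
# half-open), 4-column bedGraph, sparse Hi-C triplets + normalization
# vectors, TIFF images, JSON ground truth.

#' Write a domain set as BED6 plus a full-precision sidecar
#'
#' BED columns: chrom, start, end, label, score (NAD score x 1000,
#' rounded, clamped to the BED 0-1000 range), strand ".". Full-precision
#' scores go to `<file>.scores.tsv`.
#'
#' @param domains A [DomainSet-class].
#' @param file Output BED path.
#' @return Invisibly, the BED path.
#' @export
writeDomainBED <- function(domains, file) {
  gr <- domainRanges(domains)
  sc <- mcols(gr)$score
  bed <- data.frame(chrom = as.character(seqnames(gr)),
                    start = start(gr) - 1L, end = end(gr),
                    name = as.character(mcols(gr)$label),
                    score = pmin(1000L, pmax(0L, round(sc * 1000))),
                    strand = ".")
  bed$score[is.na(bed$score)] <- 0L
  write.table(bed, file, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  tsv <- data.frame(bed[, 1:4], score = sc)
  write.table(tsv, paste0(file, ".scores.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a BED6 domain file written by [writeDomainBED()]
#'
#' Prefers the full-precision sidecar when present.
#'
#' @param file BED path.
#' @param layout A [GenomeLayout-class].
#' @return A [DomainSet-class].
#' @export
readDomainBED <- function(file, layout) {
  side <- paste0(file, ".scores.tsv")
  if (file.exists(side)) {
    df <- read.table(side, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    names(df)[1:4] <- c("chrom", "start", "end", "label")
    return(DomainSet(df[, c("chrom", "start", "end", "label")],
                     label = df$label, score = df$score, layout = layout))
  }
  df <- read.table(file, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE)
  names(df)[1:5] <- c("chrom", "start", "end", "label", "score")
  DomainSet(df[, c("chrom", "start", "end")], label = df$label,
            score = df$score / 1000, layout = layout)
}

#' Write differential domains as three BED files
#'
#' @param x A [DifferentialDomains-class].
#' @param prefix Path prefix; writes `<prefix>_young_only.bed`,
#'   `<prefix>_senescent_only.bed`, `<prefix>_constitutive.bed`.
#' @return Invisibly, the three paths.
#' @export
writeDifferentialBEDs <- function(x, prefix) {
  sets <- list(young_only = x@youngOnly,
               senescent_only = x@senescentOnly,
               constitutive = x@constitutive)
  paths <- character(0)
  for (nm in names(sets)) {
    gr <- sets[[nm]]
    p <- paste0(prefix, "_", nm, ".bed")
    write.table(data.frame(as.character(seqnames(gr)), start(gr) - 1L,
                           end(gr)),
                p, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write a bedGraph signal track
#' @param gr `GRanges` with a `score` column.
#' @param file Output path.
#' @return Invisibly, the path.
#' @export
writeBedGraph <- function(gr, file) {
  rtracklayer::export(gr, file, format = "bedGraph")
  invisible(file)
}

#' Read a bedGraph signal track
#' @param file Path.
#' @return `GRanges` with a `score` column.
#' @export
readBedGraph <- function(file)
  rtracklayer::import(file, format = "bedGraph")

#' Write one sample of a probe track as bedGraph
#' @param track A [ProbeTrack-class].
#' @param file Output path.
#' @param sample Column name or index.
#' @return Invisibly, the path.
#' @export
writeProbeBedGraph <- function(track, file, sample = 1L) {
  gr <- probePositions(track)
  mcols(gr)$score <- trackValues(track)[, sample]
  writeBedGraph(gr, file)
}

#' Read per-sample probe bedGraphs into one ProbeTrack
#'
#' All files must share an identical probe grid (width-1 intervals).
#'
#' @param files Named character vector of bedGraph paths; names become
#'   sample labels.
#' @param layout Optional [GenomeLayout-class].
#' @return A [ProbeTrack-class].
#' @export
readProbeTrack <- function(files, layout = NULL) {
  if (is.null(names(files))) names(files) <- basename(files)
  grs <- lapply(files, readBedGraph)
  ref <- grs[[1]]
  vals <- vapply(grs, function(g) {
    if (length(g) != length(ref) ||
        !all(start(g) == start(ref)) ||
        !all(as.character(seqnames(g)) == as.character(seqnames(ref))))
      stop("probe grids differ between bedGraph files")
    mcols(g)$score
  }, numeric(length(ref)))
  ProbeTrack(as.character(seqnames(ref)), end(ref),
             vals, layout = layout, sampleLabels = names(files))
}

#' Write a NucleusImage as TIFF files plus a JSON sidecar
#'
#' Intensities are stored as 32-bit float TIFF scaled to \[0, 1\]; the
#' scale factor and pixel calibration go to `<prefix>.json`; masks are
#' 8-bit 0/1 TIFFs.
#'
#' @param image A [NucleusImage-class] (2D).
#' @param prefix Path prefix.
#' @return Invisibly, the sidecar path.
#' @export
writeNucleusImage <- function(image, prefix) {
  I <- intensityValues(image)
  if (length(dim(I)) != 2) stop("TIFF output supports 2D sections")
  scale <- max(I, 1e-12)
  tiff::writeTIFF(I / scale, paste0(prefix, "_intensity.tif"),
                  bits.per.sample = 32L)
  tiff::writeTIFF(nucleusMask(image) * 1, paste0(prefix, "_nucleus.tif"),
                  bits.per.sample = 8L)
  tiff::writeTIFF(nucleolusMask(image) * 1,
                  paste0(prefix, "_nucleolus.tif"), bits.per.sample = 8L)
  side <- paste0(prefix, ".json")
  jsonlite::write_json(list(scale = scale, pixelSize = pixelSize(image),
                            zStep = image@zStep),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' Read a NucleusImage written by [writeNucleusImage()]
#' @param prefix Path prefix used when writing.
#' @return A [NucleusImage-class].
#' @export
readNucleusImage <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  I <- tiff::readTIFF(paste0(prefix, "_intensity.tif")) * meta$scale
  nuc <- tiff::readTIFF(paste0(prefix, "_nucleus.tif")) > 0.5
  nlo <- tiff::readTIFF(paste0(prefix, "_nucleolus.tif")) > 0.5
  zs <- suppressWarnings(as.numeric(meta$zStep))
  if (!length(zs) || is.na(zs)) zs <- NA_real_
  new("NucleusImage", intensity = I, nucleusMask = nuc,
      nucleolusMask = nlo, pixelSize = meta$pixelSize, zStep = zs)
}

#' Write a ground-truth record as JSON
#' @param x List of ground-truth values.
#' @param file Output path.
#' @return Invisibly, the path.
#' @export
writeTruthJSON <- function(x, file) {
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(file)
}
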