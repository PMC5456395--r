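#' Quantile-normalize probe tracks
#'
#' Makes every sample column share the same distribution: each column's
#' sorted values are replaced by the across-sample mean of the order
#' statistics (ties averaged), preserving probe order. When two tracks
#' are given (e.g. nucleolar and background fractions) their columns are
#' normalized jointly, as one array set.
#'
#' @param x A [ProbeTrack-class].
#' @param y Optional second [ProbeTrack-class] on the same probe grid.
#' @return The normalized track, or a list of the two normalized tracks
#'   when `y` is given.
#' @export
quantileNormalize <- function(x, y = NULL) {
  if (is.null(y)) {
    v <- limma::normalizeQuantiles(trackValues(x), ties = TRUE)
    colnames(v) <- colnames(trackValues(x))
    return(newTrackLike(x, v))
  }
  if (!sameGrid(x, y)) stop("probe grids differ between the two tracks")
  nx <- ncol(trackValues(x))
  v <- limma::normalizeQuantiles(cbind(trackValues(x), trackValues(y)),
                                 ties = TRUE)
  list(newTrackLike(x, `colnames<-`(v[, seq_len(nx), drop = FALSE],
                                    colnames(trackValues(x)))),
       newTrackLike(y, `colnames<-`(v[, -seq_len(nx), drop = FALSE],
                                    colnames(trackValues(y)))))
}

#' Compute per-probe log2 nucleolar enrichment
#'
#' E = log2(nucleolar) - log2(background) per probe and replicate.
#' Columns are paired positionally; a single background column is
#' recycled against all nucleolar columns (both the genomic-input and
#' supernatant background dialects are just denominator tracks).
#' Probes with a nonpositive intensity in any used column are masked
#' (removed) and counted.
#'
#' @param nucleolar,background [ProbeTrack-class]s on identical probe
#'   grids.
#' @param log2Input Set TRUE if the values are already log2-scale, in
#'   which case the difference is taken directly and no positivity
#'   masking applies.
#' @return An [EnrichmentTrack-class]; the number of masked probes is
#'   available via `metadata` on its probes (`maskedProbes`).
#' @export
computeEnrichment <- function(nucleolar, background, log2Input = FALSE) {
  if (!sameGrid(nucleolar, background))
    stop("probe grids differ between nucleolar and background tracks")
  vn <- trackValues(nucleolar)
  vb <- trackValues(background)
  if (ncol(vb) == 1L && ncol(vn) > 1L)
    vb <- vb[, rep(1L, ncol(vn)), drop = FALSE]
  if (ncol(vb) != ncol(vn))
    stop("sample counts differ and background is not a single column")
  if (log2Input) {
    E <- vn - vb
    keep <- rep(TRUE, nrow(E))
  } else {
    keep <- rowSums(vn <= 0) == 0 & rowSums(vb <= 0) == 0
    E <- log2(vn[keep, , drop = FALSE]) - log2(vb[keep, , drop = FALSE])
  }
  colnames(E) <- paste0("E", seq_len(ncol(E)))
  probes <- probePositions(nucleolar)[keep]
  S4Vectors::metadata(probes)$maskedProbes <- sum(!keep)
  new("EnrichmentTrack", probes = probes, values = E)
}

#' Number of probes masked when an enrichment track was computed
#' @param track An [EnrichmentTrack-class] from [computeEnrichment()].
#' @return Integer count.
#' @export
maskedProbeCount <- function(track) {
  n <- S4Vectors::metadata(probePositions(track))$maskedProbes
  if (is.null(n)) 0L else n
}

#' Smooth an enrichment track by sliding medians
#'
#' Replaces each probe's value by the median over all probes whose
#' position lies within a window of the stated width centered on the
#' probe, per chromosome and per sample. Windows truncate at chromosome
#' ends; a window narrower than the probe spacing leaves values
#' unchanged.
#'
#' @param track An [EnrichmentTrack-class] (or [ProbeTrack-class]).
#' @param window Window width in bp (default 100 kb).
#' @return A track of the same class with smoothed values.
#' @export
smoothSlidingMedian <- function(track, window = 1e5) {
  stopifnot(window > 0)
  v <- trackValues(track)
  pos <- start(probePositions(track))
  chr <- chromFactor(track)
  half <- window / 2
  out <- v
  for (idx in split(seq_along(pos), chr)) {
    p <- pos[idx]
    lo <- findInterval(p - half, p, left.open = TRUE) + 1L
    hi <- findInterval(p + half, p)
    for (col in seq_len(ncol(v))) {
      x <- v[idx, col]
      out[idx, col] <- vapply(seq_along(p), function(k)
        median.default(x[lo[k]:hi[k]]), numeric(1))
    }
  }
  newTrackLike(track, out)
}

#' Average replicate enrichment tracks
#'
#' Arithmetic mean per probe across replicate columns (and across tracks
#' when a list is given), e.g. to pool the replicates of one growth
#' condition before model fitting.
#'
#' @param tracks An [EnrichmentTrack-class] or a list of them on
#'   identical probe grids.
#' @return A single-column [EnrichmentTrack-class] named "mean".
#' @export
averageReplicates <- function(tracks) {
  if (is(tracks, "ProbeTrack")) tracks <- list(tracks)
  ref <- tracks[[1]]
  for (t in tracks[-1]) if (!sameGrid(ref, t))
    stop("probe grids differ between replicate tracks")
  all <- do.call(cbind, lapply(tracks, trackValues))
  newTrackLike(ref, matrix(rowMeans(all), ncol = 1,
                           dimnames = list(NULL, "mean")))
}
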