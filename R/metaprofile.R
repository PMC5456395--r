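#' Border-aligned signal metaprofile
#'
#' Averages one or more signal tracks in fixed-width bins around the
#' borders of wide domains, with both borders of each domain aligned so
#' that negative offsets lie outside the domain and positive offsets
#' inside. On the p-to-q chromosome axis the 5' (left) border is used
#' as-is and the 3' (right) border is mirrored before averaging, so the
#' offset axis consistently points from outside into the domain. Only
#' NAD domains wider than `minWidth` contribute, and only borders whose
#' full flank window fits inside the chromosome.
#'
#' @param domains A [DomainSet-class].
#' @param signals A bedGraph-like `GRanges` with a `score` column, or a
#'   named list of them (e.g. the five replication-timing fractions).
#' @param flank Flank width in bp on each side of the border.
#' @param bin Bin width in bp; `flank` must be divisible by `bin`.
#' @param minWidth Minimum domain width (strict) for inclusion.
#' @return A [MetaProfile-class].
#' @export
borderMetaprofile <- function(domains, signals, flank = 5e5, bin = 1e3,
                              minWidth = 5e5) {
  if (flank %% bin != 0) stop("flank must be divisible by bin")
  if (is(signals, "GRanges")) signals <- list(signal = signals)
  if (is.null(names(signals)))
    names(signals) <- paste0("signal", seq_along(signals))
  layout <- genomeLayout(domains)
  len <- chromLengths(layout)
  nad <- nadRanges(domains)
  wide <- nad[width(nad) > minWidth]
  nBins <- as.integer(2 * flank / bin)
  offsets <- -flank + (seq_len(nBins) - 0.5) * bin

  # collect border windows: for each border a matrix of per-bin windows
  # (start positions), orientation handled by bin ordering
  winStarts <- list(); winChrom <- character(0); winRev <- logical(0)
  usedDomain <- logical(length(wide))
  for (k in seq_along(wide)) {
    chr <- as.character(seqnames(wide))[k]
    L <- len[[chr]]
    b5 <- start(wide)[k]          # first bp inside the domain (1-based)
    b3 <- end(wide)[k]            # last bp inside
    # 5' border: window [b5 - flank, b5 + flank), bins left to right
    if (b5 - flank >= 1 && b5 + flank - 1 <= L) {
      winStarts[[length(winStarts) + 1L]] <- b5 - flank + (seq_len(nBins) - 1L) * bin
      winChrom <- c(winChrom, chr); winRev <- c(winRev, FALSE)
      usedDomain[k] <- TRUE
    }
    # 3' border: window (b3 - flank, b3 + flank], bins mirrored
    if (b3 - flank + 1 >= 1 && b3 + flank <= L) {
      winStarts[[length(winStarts) + 1L]] <- b3 + 1L - flank + (seq_len(nBins) - 1L) * bin
      winChrom <- c(winChrom, chr); winRev <- c(winRev, TRUE)
      usedDomain[k] <- TRUE
    }
  }
  vals <- matrix(NA_real_, nBins, length(signals),
                 dimnames = list(NULL, names(signals)))
  if (length(winStarts)) {
    for (s in seq_along(signals)) {
      cov <- signalCoverage(signals[[s]], layout)
      acc <- matrix(0, length(winStarts), nBins)
      for (w in seq_along(winStarts)) {
        st <- winStarts[[w]]
        vw <- Views(cov[[winChrom[w]]], st, st + bin - 1L)
        m <- viewMeans(vw)
        acc[w, ] <- if (winRev[w]) rev(m) else m
      }
      vals[, s] <- colMeans(acc)
    }
  }
  new("MetaProfile", offsets = offsets, values = vals,
      nDomains = sum(usedDomain), nBorders = length(winStarts))
}

#' @describeIn borderMetaprofile Tidy data.frame of a MetaProfile.
#' @param x A [MetaProfile-class].
#' @export
metaProfileFrame <- function(x) {
  data.frame(offset = rep(x@offsets, ncol(x@values)),
             signal = rep(colnames(x@values), each = length(x@offsets)),
             mean = as.vector(x@values))
}

setMethod("show", "MetaProfile", function(object) {
  cat("MetaProfile:", length(object@offsets), "bins x",
      ncol(object@values), "signal(s);", object@nDomains,
      "domains /", object@nBorders, "borders averaged\n")
})
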