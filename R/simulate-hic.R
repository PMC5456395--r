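#' Simulate sparse intrachromosomal Hi-C contacts with homotypic boost
#'
#' Generates normalized intrachromosomal contact values whose expectation
#' follows a power-law distance decay, multiplied by `homotypicBoost`
#' when both 10 kb bins lie in NADs and the pair distance falls inside
#' `band`; applies multiplicative lognormal noise (mean 1, stated CV) and
#' then un-normalizes with a per-bin vector (uniform in \[0.5, 2\], with a
#' configurable fraction of NaN entries) so that raw triplets plus the
#' vector reproduce the intended normalized values on division. A random
#' subset of all bin pairs (`pairFraction`) is materialized; the
#' per-pair expectation is unchanged by the subsetting, so class-wise
#' means remain unbiased.
#'
#' @param truth A [DomainSet-class] ground-truth segmentation.
#' @param binSize Bin size in bp (default 10 kb).
#' @param decayExponent Power-law decay exponent (expected value
#'   proportional to distance^-decayExponent).
#' @param homotypicBoost Multiplier for NAD-NAD pairs inside `band`
#'   (>= 1; 1 is the null model).
#' @param band Length-2 bp range of the boosted distance band.
#' @param noiseCV Coefficient of variation of the multiplicative noise.
#' @param pairFraction Fraction of all intrachromosomal bin pairs to
#'   materialize.
#' @param normNaFrac Fraction of normalization-vector entries set to NaN
#'   (exercises the loader's dropping logic).
#' @param baseLevel Normalized value at one-bin distance.
#' @param seed Integer seed.
#' @return List with `contacts` (data.frame chrom/bin_i/bin_j/raw/
#'   normalized; bin coordinates are bin-start bp), `norm` (named list of
#'   per-chromosome normalization vectors, NaN included), `binLabels`
#'   (named list of per-bin "NAD"/"iNAD" labels) and `params`.
#' @export
simulateHiC <- function(truth, binSize = 10000L, decayExponent = 1,
                        homotypicBoost = 2, band = c(10e6, 50e6),
                        noiseCV = 0.2, pairFraction = 0.1,
                        normNaFrac = 0.02, baseLevel = 100, seed = 1L) {
  stopifnot(binSize > 0, homotypicBoost >= 1, band[1] < band[2],
            pairFraction > 0, pairFraction <= 1, noiseCV >= 0)
  layout <- genomeLayout(truth)
  len <- chromLengths(layout)
  nad <- nadRanges(truth)
  set.seed(seed)
  sdlog <- sqrt(log(1 + noiseCV^2))
  allContacts <- list(); normList <- list(); labList <- list()
  for (chr in names(len)) {
    L <- as.numeric(len[[chr]])
    nbins <- floor(L / binSize)
    if (nbins < 4) stop("chromosome ", chr, " shorter than 4 bins")
    if (band[1] >= L)
      warning("boost band lies outside the span of ", chr)
    bins <- GRanges(chr, IRanges(seq_len(nbins) * binSize - binSize + 1L,
                                 width = binSize))
    isNad <- overlapBp(bins, nad) * 2 >= binSize
    labList[[chr]] <- ifelse(isNad, "NAD", "iNAD")

    maxd <- nbins - 1L
    nPairsPerD <- nbins - seq_len(maxd)
    nTotal <- sum(as.numeric(nPairsPerD))
    nSample <- max(1L, round(pairFraction * nTotal))
    d <- sample.int(maxd, nSample, replace = TRUE,
                    prob = nPairsPerD / nTotal)
    i <- floor(runif(nSample) * (nbins - d))          # 0-based bin index
    key <- i * (maxd + 1) + d
    keep <- !duplicated(key)
    d <- d[keep]; i <- i[keep]
    j <- i + d
    distBp <- d * binSize
    mu <- baseLevel * d^(-decayExponent)
    boosted <- isNad[i + 1L] & isNad[j + 1L] &
      distBp >= band[1] & distBp <= band[2]
    mu[boosted] <- mu[boosted] * homotypicBoost
    noise <- if (noiseCV > 0)
      exp(rnorm(length(mu), 0, sdlog)) / exp(sdlog^2 / 2) else 1
    normalized <- mu * noise

    v <- runif(nbins, 0.5, 2)
    raw <- normalized * v[i + 1L] * v[j + 1L]
    if (normNaFrac > 0) {
      nNa <- round(normNaFrac * nbins)
      if (nNa > 0) v[sample.int(nbins, nNa)] <- NaN
    }
    normList[[chr]] <- v
    allContacts[[chr]] <- data.frame(chrom = chr,
                                     bin_i = i * binSize,
                                     bin_j = j * binSize,
                                     raw = raw,
                                     normalized = normalized)
  }
  list(contacts = do.call(rbind, allContacts),
       norm = normList,
       binLabels = labList,
       params = list(binSize = binSize, decayExponent = decayExponent,
                     homotypicBoost = homotypicBoost, band = band,
                     noiseCV = noiseCV, pairFraction = pairFraction,
                     baseLevel = baseLevel, seed = seed))
}

#' Write simulated Hi-C contacts in the sparse triplet dialect
#'
#' Writes, per chromosome, a whitespace-separated triplet file
#' (`bin_i_start  bin_j_start  raw_count`) and a one-value-per-line
#' normalization vector file (NaN entries written as "NaN").
#'
#' @param sim Result of [simulateHiC()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Invisibly, a data.frame of written file paths per chromosome.
#' @export
writeHiCFiles <- function(sim, dir, prefix = "sim") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  chroms <- names(sim$norm)
  paths <- lapply(chroms, function(chr) {
    df <- sim$contacts[sim$contacts$chrom == chr, c("bin_i", "bin_j", "raw")]
    tf <- file.path(dir, paste0(prefix, "_", chr, ".triplets.txt"))
    nf <- file.path(dir, paste0(prefix, "_", chr, ".norm.txt"))
    write.table(df, tf, sep = " ", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    writeLines(format(sim$norm[[chr]], digits = 15, trim = TRUE,
                      scientific = FALSE), nf)
    data.frame(chrom = chr, triplets = tf, norm = nf)
  })
  invisible(do.call(rbind, paths))
}
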