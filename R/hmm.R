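# Two-state Gaussian HMM segmentation of smoothed enrichment tracks.
# The bimodal log2 enrichment distribution motivates exactly two hidden
# states (nucleolus-associated vs not); fitting is plain Baum-Welch with
# per-chromosome sequences so no transition is learned across a
# chromosome boundary.

hmmObs <- function(track) {
  v <- trackValues(track)
  if (ncol(v) != 1L)
    stop("fit on a single-column track; use averageReplicates() first")
  chr <- chromFactor(track)
  list(obs = as.numeric(v[, 1]),
       seqlen = as.integer(table(chr)[levels(chr)]),
       chrom = chr)
}

#' Fit a two-state Gaussian hidden Markov model
#'
#' Baum-Welch (EM) fit of a two-state HMM with Gaussian emissions on the
#' concatenated per-chromosome probe sequences of a smoothed, averaged
#' enrichment track. Initialization is deterministic: emission means at
#' the 25th/75th percentiles of the data, equal sds, sticky transitions
#' (0.99 self), uniform initial distribution. The state with the larger
#' fitted mean is labeled NAD. The log-likelihood is non-decreasing over
#' iterations; degenerate fits (collapsing sd or an empty state) trigger
#' restarts from wider percentile pairs and finally an error.
#'
#' @param track Single-column [EnrichmentTrack-class].
#' @param tol Stop when the log-likelihood improves by less than this.
#' @param maxIter Maximum EM iterations.
#' @param seed Accepted for interface stability; the default fit is
#'   fully deterministic and does not consume randomness.
#' @param maxRestarts Restarts allowed on degenerate fits.
#' @return A [TwoStateHMM-class].
#' @export
fitTwoStateHMM <- function(track, tol = 1e-4, maxIter = 200L, seed = NULL,
                           maxRestarts = 3L) {
  o <- hmmObs(track)
  if (length(o$obs) < 100)
    warning("fewer than 100 probes; the fit may be unstable")
  inits <- list(c(0.25, 0.75), c(0.10, 0.90), c(0.05, 0.95))
  sdFloor <- 1e-4 * max(stats::sd(o$obs), .Machine$double.eps)
  lastErr <- NULL
  for (r in seq_len(min(maxRestarts, length(inits)))) {
    fit <- tryCatch(
      baumWelch2(o, qpair = inits[[r]], tol = tol, maxIter = maxIter,
                 sdFloor = sdFloor),
      error = function(e) e)
    if (!inherits(fit, "error")) return(fit)
    lastErr <- fit
  }
  stop("degenerate HMM fit after restarts: ", conditionMessage(lastErr))
}

baumWelch2 <- function(o, qpair, tol, maxIter, sdFloor) {
  obs <- o$obs
  mu <- unname(quantile(obs, qpair))
  if (diff(mu) < .Machine$double.eps) mu <- mu + c(-1, 1) * stats::sd(obs) / 4
  sds <- rep(max(stats::sd(obs), sdFloor * 2), 2)
  A <- matrix(c(0.99, 0.01, 0.01, 0.99), 2, 2)
  pi0 <- c(0.5, 0.5)
  ll <- numeric(0)
  for (it in seq_len(maxIter)) {
    es <- .hmm_estep2(obs, o$seqlen, pi0, A, mu, sds)
    ll <- c(ll, es$loglik)
    if (any(es$gamma_sum < 1))
      stop("state emptied during EM")
    muNew <- es$gamma_x / es$gamma_sum
    varNew <- es$gamma_xx / es$gamma_sum - muNew^2
    if (any(varNew < sdFloor^2)) stop("emission sd collapsed during EM")
    A <- es$trans_num / rowSums(es$trans_num)
    pi0 <- es$gamma_first / sum(es$gamma_first)
    mu <- muNew
    sds <- sqrt(varNew)
    if (it > 1 && ll[it] - ll[it - 1] < tol) break
  }
  converged <- length(ll) > 1 && diff(tail(ll, 2)) < tol
  # label states: NAD = larger emission mean
  ord <- order(mu, decreasing = TRUE)  # 1 -> NAD, 2 -> iNAD
  nm <- c("NAD", "iNAD")
  A <- A[ord, ord, drop = FALSE]; dimnames(A) <- list(nm, nm)
  new("TwoStateHMM", transition = A,
      means = setNames(mu[ord], nm), sds = setNames(sds[ord], nm),
      initProb = setNames(pi0[ord], nm),
      logLik = ll, converged = converged, nIter = length(ll))
}

setMethod("show", "TwoStateHMM", function(object) {
  cat("TwoStateHMM: mu(NAD) =", signif(object@means["NAD"], 4),
      ", mu(iNAD) =", signif(object@means["iNAD"], 4),
      "; sd =", paste(signif(object@sds, 3), collapse = "/"),
      "\n  self-transitions:", paste(signif(diag(object@transition), 4),
                                     collapse = "/"),
      "; logLik =", signif(tail(object@logLik, 1), 8),
      if (object@converged) "(converged)" else "(max iterations)", "\n")
})

#' Separation index of a fitted two-state model
#'
#' Distance between the two emission means in units of the summed
#' emission sds; values well above 1 indicate a genuinely bimodal signal,
#' values near or below 1 a single-mode signal carved in two.
#'
#' @param model A [TwoStateHMM-class].
#' @return Numeric.
#' @export
stateSeparation <- function(model)
  unname((model@means["NAD"] - model@means["iNAD"]) / sum(model@sds))

#' Call NAD/iNAD domains from a fitted model
#'
#' Viterbi-decodes the state path per chromosome, merges consecutive
#' same-state probes into intervals (each probe's extent reaches to the
#' next probe's position; the last probe extends by the median spacing),
#' relabels NAD intervals shorter than `minLen` as iNAD and merges them
#' into their flanks, and scores every interval with the mean smoothed
#' enrichment of its probes.
#'
#' @param track Single-column smoothed [EnrichmentTrack-class] (the same
#'   one the model was fitted on).
#' @param model A [TwoStateHMM-class].
#' @param minLen Minimum NAD length in bp (default 10 kb).
#' @param layout Optional [GenomeLayout-class]; defaults to one built
#'   from the track's seqinfo (falling back to the probe extent).
#' @return A [DomainSet-class] tiling the analyzed extent of each
#'   chromosome with >= 2 probes (shorter chromosomes are skipped with a
#'   warning).
#' @export
callDomains <- function(track, model, minLen = 1e4, layout = NULL) {
  o <- hmmObs(track)
  pos <- start(probePositions(track))
  A <- model@transition
  # internal state order 1=NAD, 2=iNAD matches means ordering
  path <- .hmm_viterbi2(o$obs, o$seqlen,
                        unname(model@initProb), unname(A),
                        unname(model@means), unname(model@sds))
  if (is.null(layout)) {
    sl <- seqlengths(probePositions(track))
    if (any(is.na(sl))) {
      ext <- tapply(pos, o$chrom, max)
      sp <- median(unlist(tapply(pos, o$chrom, diff)))
      sl[is.na(sl)] <- ext[names(sl)[is.na(sl)]] + sp
    }
    layout <- GenomeLayout(sl)
  }
  pieces <- list()
  for (chr in levels(o$chrom)) {
    idx <- which(o$chrom == chr)
    if (length(idx) < 2) {
      warning("chromosome ", chr, " has < 2 probes; skipped")
      next
    }
    p <- pos[idx]; st <- path[idx]
    sp <- median(diff(p))
    r <- rle(st)
    endsIdx <- cumsum(r$lengths)
    startsIdx <- c(1L, head(endsIdx, -1) + 1L)
    segStart <- p[startsIdx]
    segEnd <- c(p[head(endsIdx, -1) + 1L], p[length(p)] + sp)
    lab <- c("NAD", "iNAD")[r$values]
    w <- segEnd - segStart
    lab[lab == "NAD" & w < minLen] <- "iNAD"
    # merge adjacent equal labels after relabeling
    m <- rle(lab)
    me <- cumsum(m$lengths); ms <- c(1L, head(me, -1) + 1L)
    chrEnd <- min(segEnd[length(segEnd)] - 1L,
                  chromLengths(layout)[[chr]])
    pieces[[chr]] <- data.frame(
      chrom = chr,
      start = segStart[ms] - 1L,             # to 0-based half-open
      end = c(segStart[ms][-1] - 1L, chrEnd),
      label = m$values)
  }
  if (!length(pieces)) stop("no chromosome had enough probes")
  df <- do.call(rbind, pieces)
  ds <- DomainSet(df, layout = layout)
  scoreDomains(ds, track)
}

#' Score domains with mean enrichment
#'
#' Sets each interval's score to the mean enrichment of the probes it
#' contains (NA for probe-free intervals).
#'
#' @param domains A [DomainSet-class].
#' @param track Single-column [EnrichmentTrack-class].
#' @return The rescored [DomainSet-class].
#' @export
scoreDomains <- function(domains, track) {
  gr <- domains@ranges
  hits <- findOverlaps(probePositions(track), gr, ignore.strand = TRUE)
  v <- trackValues(track)[queryHits(hits), 1]
  sc <- rep(NA_real_, length(gr))
  agg <- tapply(v, subjectHits(hits), mean)
  sc[as.integer(names(agg))] <- agg
  mcols(gr)$score <- sc
  new("DomainSet", ranges = gr, layout = domains@layout)
}

#' Partition two conditions' NADs into differential classes
#'
#' Splits the base pairs covered by either condition's NADs into
#' young-only (lost in senescence), senescent-only (gained in
#' senescence) and constitutive (shared) interval sets.
#'
#' @param young,senescent [DomainSet-class]s on the same layout.
#' @return A [DifferentialDomains-class].
#' @export
differentialDomains <- function(young, senescent) {
  ly <- chromLengths(genomeLayout(young))
  ls <- chromLengths(genomeLayout(senescent))
  if (!identical(ly, ls)) stop("the two domain sets use different layouts")
  y <- reduce(nadRanges(young), ignore.strand = TRUE)
  s <- reduce(nadRanges(senescent), ignore.strand = TRUE)
  new("DifferentialDomains",
      youngOnly = GenomicRanges::setdiff(y, s, ignore.strand = TRUE),
      senescentOnly = GenomicRanges::setdiff(s, y, ignore.strand = TRUE),
      constitutive = GenomicRanges::intersect(y, s, ignore.strand = TRUE),
      layout = genomeLayout(young))
}

#' Total base pairs per differential class
#' @param x A [DifferentialDomains-class].
#' @return Named numeric vector (young_only, senescent_only,
#'   constitutive).
#' @export
differentialTotals <- function(x) {
  c(young_only = sum(as.numeric(width(x@youngOnly))),
    senescent_only = sum(as.numeric(width(x@senescentOnly))),
    constitutive = sum(as.numeric(width(x@constitutive))))
}

setMethod("show", "DifferentialDomains", function(object) {
  tt <- differentialTotals(object)
  cat("DifferentialDomains:",
      length(object@youngOnly), "young-only (",
      format(tt[1], big.mark = ","), "bp ),",
      length(object@senescentOnly), "senescent-only (",
      format(tt[2], big.mark = ","), "bp ),",
      length(object@constitutive), "constitutive (",
      format(tt[3], big.mark = ","), "bp )\n")
})
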