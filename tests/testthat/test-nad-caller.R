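# Normalization, enrichment, smoothing, HMM fitting and domain calling.

test_that("quantile normalization matches the rank/row-mean oracle", {
  tr <- ProbeTrack("chrA", c(1, 1001, 2001), cbind(a = c(1, 2, 3),
                                                   b = c(4, 5, 6)))
  qn <- quantileNormalize(tr)
  expect_equal(unname(trackValues(qn)[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(trackValues(qn)[, 2]), c(2.5, 3.5, 4.5))
  # identical columns and single columns are fixed points
  tr2 <- ProbeTrack("chrA", c(1, 1001), cbind(c(2, 1), c(2, 1)))
  expect_equal(trackValues(quantileNormalize(tr2)), trackValues(tr2))
  tr3 <- ProbeTrack("chrA", c(1, 1001), cbind(c(5, 9)))
  expect_equal(trackValues(quantileNormalize(tr3)), trackValues(tr3))
  # afterwards all columns share one multiset of values
  set.seed(1)
  tr4 <- ProbeTrack("chrA", seq(1, 5001, 500),
                    matrix(rnorm(33), ncol = 3))
  qn4 <- quantileNormalize(tr4)
  v <- trackValues(qn4)
  expect_equal(sort(v[, 1]), sort(v[, 2]))
  expect_equal(sort(v[, 2]), sort(v[, 3]))
})

test_that("enrichment is the per-probe log2 ratio with masking", {
  pos <- c(1, 1001, 2001, 3001)
  nuc <- ProbeTrack("chrA", pos, cbind(c(4, 8, 2, 1)))
  bg <- ProbeTrack("chrA", pos, cbind(c(4, 2, 2, 1)))
  E <- computeEnrichment(nuc, bg)
  expect_equal(unname(trackValues(E)[, 1]), c(0, 2, 0, 0))
  # nonpositive intensities are masked and counted
  nuc2 <- ProbeTrack("chrA", pos, cbind(c(4, -1, 2, 0)))
  E2 <- computeEnrichment(nuc2, bg)
  expect_equal(length(E2), 2L)
  expect_equal(maskedProbeCount(E2), 2L)
  # mismatched grids rejected
  bg2 <- ProbeTrack("chrA", pos + 1, cbind(c(4, 2, 2, 1)))
  expect_error(computeEnrichment(nuc, bg2), "grids differ")
})

test_that("sliding median matches the brute-force window oracle", {
  pos <- c(1, 500, 1200, 1300, 2500, 2600, 4000)
  val <- c(5, 1, 4, 2, 9, 3, 7)
  tr <- enrTrack(pos, val)
  w <- 1500
  sm <- smoothSlidingMedian(tr, w)
  oracle <- vapply(seq_along(pos), function(k)
    median(val[abs(pos - pos[k]) <= w / 2]), numeric(1))
  expect_equal(unname(trackValues(sm)[, 1]), oracle)
  # constant tracks and sub-spacing windows are unchanged
  trc <- enrTrack(pos, rep(2, 7))
  expect_equal(trackValues(smoothSlidingMedian(trc, 1e5)),
               trackValues(trc))
  expect_equal(trackValues(smoothSlidingMedian(tr, 10)),
               trackValues(tr))
  # smoothing never crosses a chromosome boundary
  tr2 <- new("EnrichmentTrack",
             probes = GRanges(rep(c("chrA", "chrB"), each = 3),
                              IRanges(rep(c(1, 101, 201), 2), width = 1)),
             values = matrix(c(0, 0, 0, 10, 10, 10), ncol = 1,
                             dimnames = list(NULL, "E1")))
  sm2 <- smoothSlidingMedian(tr2, 1e4)
  expect_equal(unname(trackValues(sm2)[, 1]), c(0, 0, 0, 10, 10, 10))
})

test_that("replicate averaging is the probe-wise mean", {
  pos <- c(1, 1001, 2001)
  tr <- enrTrack(pos, cbind(c(1, 2, 3), c(3, 2, 1)))
  av <- averageReplicates(tr)
  expect_equal(unname(trackValues(av)[, 1]), c(2, 2, 2))
  # antisymmetric replicates cancel
  tr2 <- enrTrack(pos, cbind(c(1, -2, 3), -c(1, -2, 3)))
  expect_equal(unname(trackValues(averageReplicates(tr2))[, 1]),
               c(0, 0, 0))
  # single replicate is the identity
  tr3 <- enrTrack(pos, cbind(c(4, 5, 6)))
  expect_equal(unname(trackValues(averageReplicates(tr3))[, 1]),
               c(4, 5, 6))
})

test_that("the HMM recovers two delta-like clusters exactly", {
  set.seed(2)
  n <- 300
  states <- rep(c(0, 1), each = n / 2)
  obs <- ifelse(states == 1, 2, -3) + rnorm(n, 0, 1e-3)
  tr <- enrTrack(seq_len(n) * 1000 - 999, obs)
  suppressWarnings(m <- fitTwoStateHMM(tr))
  expect_equal(unname(m@means["NAD"]), 2, tolerance = 1e-2)
  expect_equal(unname(m@means["iNAD"]), -3, tolerance = 1e-2)
  # labeling convention
  expect_gte(m@means["NAD"], m@means["iNAD"])
})

test_that("Baum-Welch log-likelihood is non-decreasing", {
  layout <- toyLayout(c(chrA = 2e6))
  truth <- simulateDomainTruth(layout, seed = 1)
  sim <- simulateEnrichmentArrays(truth, seed = 2)
  Em <- averageReplicates(smoothSlidingMedian(sim$enrichment))
  m <- fitTwoStateHMM(Em)
  expect_true(all(diff(m@logLik) > -1e-6))
})

test_that("unimodal signal never yields a confidently bimodal fit", {
  set.seed(5)
  obs <- rnorm(2000, 0, 0.3)
  tr <- enrTrack(seq_len(2000) * 1000 - 999, obs)
  res <- tryCatch(fitTwoStateHMM(tr), error = function(e) e)
  if (!inherits(res, "error")) {
    expect_lt(stateSeparation(res), 1)
  } else {
    expect_match(conditionMessage(res), "degenerate")
  }
})

test_that("domain calling recovers the simulated truth", {
  layout <- toyLayout(c(chrA = 5e6, chrB = 3e6))
  truth <- simulateDomainTruth(layout, seed = 3)
  sim <- simulateEnrichmentArrays(truth, seed = 4)
  Em <- averageReplicates(smoothSlidingMedian(sim$enrichment))
  m <- fitTwoStateHMM(Em)
  called <- callDomains(Em, m, layout = layout)
  expect_gte(domainAccuracy(called, truth), 0.95)
  expect_lt(abs(m@means["NAD"] - 1), 0.1)
  expect_lt(abs(m@means["iNAD"] + 1), 0.1)
  # the called set tiles each analyzed chromosome
  gr <- domainRanges(called)
  for (chr in c("chrA", "chrB")) {
    sub <- gr[seqnames(gr) == chr]
    expect_true(all(start(sub)[-1] == head(end(sub), -1) + 1))
  }
})

test_that("uniformly extreme probes give one chromosome-wide NAD", {
  m <- new("TwoStateHMM",
           transition = matrix(c(0.99, 0.01, 0.01, 0.99), 2, 2,
                               dimnames = list(c("NAD", "iNAD"),
                                               c("NAD", "iNAD"))),
           means = c(NAD = 1, iNAD = -1), sds = c(NAD = 0.3, iNAD = 0.3),
           initProb = c(NAD = 0.5, iNAD = 0.5), logLik = 0,
           converged = TRUE, nIter = 1L)
  tr <- enrTrack(seq(1, 99001, 1000), rep(3, 100),
                 layout = toyLayout(c(chrA = 1e5)))
  called <- callDomains(tr, m, layout = toyLayout(c(chrA = 1e5)))
  expect_equal(length(called), 1L)
  expect_equal(domainLabels(called), "NAD")
  expect_equal(width(domainRanges(called)), 1e5)
})

test_that("sub-minimum NAD islands are absorbed into flanking iNAD", {
  m <- new("TwoStateHMM",
           transition = matrix(c(0.99, 0.01, 0.01, 0.99), 2, 2,
                               dimnames = list(c("NAD", "iNAD"),
                                               c("NAD", "iNAD"))),
           means = c(NAD = 1, iNAD = -1), sds = c(NAD = 0.1, iNAD = 0.1),
           initProb = c(NAD = 0.5, iNAD = 0.5), logLik = 0,
           converged = TRUE, nIter = 1L)
  pos <- seq(1, 100000, 1000)
  val <- rep(-1, length(pos))
  val[41:48] <- 1                       # an 8 kb island of NAD signal
  tr <- enrTrack(pos, val, layout = toyLayout(c(chrA = 1e5)))
  called <- callDomains(tr, m, minLen = 1e4,
                        layout = toyLayout(c(chrA = 1e5)))
  expect_equal(domainLabels(called), "iNAD")
  expect_equal(length(called), 1L)
  # a 10 kb island survives the same rule
  val[41:51] <- 1
  tr2 <- enrTrack(pos, val, layout = toyLayout(c(chrA = 1e5)))
  called2 <- callDomains(tr2, m, minLen = 1e4,
                         layout = toyLayout(c(chrA = 1e5)))
  expect_true("NAD" %in% domainLabels(called2))
})

test_that("domain scores are the mean enrichment of their probes", {
  pos <- seq(1, 10000, 1000)
  val <- c(rep(2, 5), rep(-1, 5))
  m <- new("TwoStateHMM",
           transition = matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2,
                               dimnames = list(c("NAD", "iNAD"),
                                               c("NAD", "iNAD"))),
           means = c(NAD = 2, iNAD = -1), sds = c(NAD = 0.1, iNAD = 0.1),
           initProb = c(NAD = 0.5, iNAD = 0.5), logLik = 0,
           converged = TRUE, nIter = 1L)
  tr <- enrTrack(pos, val, layout = toyLayout(c(chrA = 1e4)))
  called <- callDomains(tr, m, minLen = 1000,
                        layout = toyLayout(c(chrA = 1e4)))
  expect_equal(domainScores(called)[domainLabels(called) == "NAD"], 2)
  expect_equal(domainScores(called)[domainLabels(called) == "iNAD"], -1)
})

test_that("differential domains follow bp-exact set algebra", {
  layout <- toyLayout(c(chrA = 200))
  y <- DomainSet(data.frame(chrom = "chrA", start = 0, end = 100),
                 label = "NAD", layout = layout)
  s <- DomainSet(data.frame(chrom = "chrA", start = 50, end = 150),
                 label = "NAD", layout = layout)
  dd <- differentialDomains(y, s)
  expect_equal(start(dd@youngOnly) - 1, 0)
  expect_equal(end(dd@youngOnly), 50)
  expect_equal(start(dd@senescentOnly) - 1, 100)
  expect_equal(end(dd@senescentOnly), 150)
  expect_equal(start(dd@constitutive) - 1, 50)
  expect_equal(end(dd@constitutive), 100)
  expect_equal(unname(differentialTotals(dd)), c(50, 50, 50))
  # identical inputs: differences empty, constitutive = input
  dd2 <- differentialDomains(y, y)
  expect_equal(length(dd2@youngOnly), 0L)
  expect_equal(length(dd2@senescentOnly), 0L)
  expect_equal(unname(differentialTotals(dd2)[3]), 100)
  # empty senescent set: young-only = young
  e <- DomainSet(data.frame(chrom = "chrA", start = 0, end = 200),
                 label = "iNAD", layout = layout)
  dd3 <- differentialDomains(y, e)
  expect_equal(unname(differentialTotals(dd3)),
               c(100, 0, 0))
  # layout mismatch rejected
  other <- DomainSet(data.frame(chrom = "chrB", start = 0, end = 10),
                     label = "NAD", layout = toyLayout(c(chrB = 100)))
  expect_error(differentialDomains(y, other), "layout")
})

test_that("random differential partitions satisfy the set identities", {
  layout <- toyLayout(c(chrA = 1e5))
  for (seed in 1:5) {
    y <- randomNadSet(layout, n = 6, seed = seed)
    s <- randomNadSet(layout, n = 6, seed = seed + 100)
    dd <- differentialDomains(y, s)
    L <- 1e5
    vy <- bpVector(nadRanges(y), L)
    vs <- bpVector(nadRanges(s), L)
    expect_equal(sum(bpVector(dd@youngOnly, L)), sum(vy & !vs))
    expect_equal(sum(bpVector(dd@senescentOnly, L)), sum(!vy & vs))
    expect_equal(sum(bpVector(dd@constitutive, L)), sum(vy & vs))
    # pairwise disjoint and reconstructive
    expect_true(!any(bpVector(dd@youngOnly, L) &
                       bpVector(dd@constitutive, L)))
    expect_equal(bpVector(dd@youngOnly, L) | bpVector(dd@constitutive, L),
                 vy)
  }
})
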