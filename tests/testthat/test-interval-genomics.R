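# Interval-set statistics against per-basepair boolean oracles.

test_that("complement matches bp enumeration and is an involution", {
  layout <- toyLayout(c(chrA = 50))
  d <- DomainSet(data.frame(chrom = "chrA", start = 10, end = 20),
                 label = "NAD", layout = layout)
  comp <- complementIntervals(d, layout)
  expect_equal(start(comp) - 1, c(0, 20))
  expect_equal(end(comp), c(10, 50))
  # empty input -> whole layout; full input -> empty
  empty <- GRanges(seqinfo = layout@seqinfo)
  expect_equal(width(complementIntervals(empty, layout)), 50)
  full <- GRanges("chrA", IRanges(1, 50))
  expect_equal(length(complementIntervals(full, layout)), 0L)
  # involution
  twice <- complementIntervals(complementIntervals(nadRanges(d), layout),
                               layout)
  expect_equal(as.data.frame(twice)[, 1:3],
               as.data.frame(nadRanges(d))[, 1:3])
  # out-of-range intervals rejected
  bad <- GRanges("chrA", IRanges(40, 60))
  expect_error(complementIntervals(bad, layout), "exceeds")
})

test_that("overlap statistics match the bp oracle and are symmetric", {
  layout <- toyLayout(c(chrA = 1000))
  a <- DomainSet(data.frame(chrom = "chrA", start = 0, end = 100),
                 label = "NAD", layout = layout)
  b <- DomainSet(data.frame(chrom = "chrA", start = 50, end = 150),
                 label = "NAD", layout = layout)
  st <- overlapStats(a, b)
  expect_equal(st$intersection_bp, 50)
  expect_equal(st$union_bp, 150)
  expect_equal(st$jaccard, 1 / 3)
  # identity and disjoint extremes
  expect_equal(overlapStats(a, a)$jaccard, 1)
  c <- DomainSet(data.frame(chrom = "chrA", start = 500, end = 600),
                 label = "NAD", layout = layout)
  expect_equal(overlapStats(a, c)$jaccard, 0)
  # symmetry
  st2 <- overlapStats(b, a)
  expect_equal(st$a_only_bp, st2$b_only_bp)
  expect_equal(st$jaccard, st2$jaccard)
})

test_that("interval operations agree with the boolean-array oracle", {
  L <- 10000
  layout <- toyLayout(c(chrA = L))
  for (seed in 1:25) {
    a <- randomNadSet(layout, n = 4, seed = seed)
    b <- randomNadSet(layout, n = 4, seed = seed + 1000)
    va <- bpVector(nadRanges(a), L)
    vb <- bpVector(nadRanges(b), L)
    st <- overlapStats(a, b)
    expect_equal(st$intersection_bp, sum(va & vb))
    expect_equal(st$union_bp, sum(va | vb))
    expect_equal(st$a_only_bp, sum(va & !vb))
    expect_equal(st$b_only_bp, sum(!va & vb))
    if (st$union_bp > 0)
      expect_equal(st$jaccard, sum(va & vb) / sum(va | vb))
    comp <- complementIntervals(a, layout)
    expect_equal(bpVector(comp, L), !va)
  }
})

test_that("state composition matches brute-force bp counting", {
  layout <- toyLayout(c(chrA = 100))
  d <- DomainSet(data.frame(chrom = "chrA", start = c(0, 60),
                            end = c(40, 80),
                            label = c("NAD", "iNAD")),
                 layout = layout)
  # note: domain set does not tile; fractions are of each class extent
  states <- GRanges("chrA", IRanges(c(1, 31, 71), c(30, 70, 100)),
                    state = c("X", "Y", "X"))
  sc <- stateComposition(d, states)
  # NAD = [1,40]; iNAD = [61,80]
  expect_equal(sc$nad_bp[sc$state == "X"], 30)
  expect_equal(sc$nad_bp[sc$state == "Y"], 10)
  expect_equal(sc$inad_bp[sc$state == "Y"], 10)
  expect_equal(sc$inad_bp[sc$state == "X"], 10)
  expect_equal(sc$nad_frac[sc$state == "X"], 30 / 40)
  expect_equal(sc$inad_frac[sc$state == "X"], 10 / 20)
  # a single state covering everything: fractions 1, ratio 0
  all1 <- GRanges("chrA", IRanges(1, 100), state = "Z")
  sc1 <- stateComposition(d, all1)
  expect_equal(sc1$nad_frac, 1)
  expect_equal(sc1$inad_frac, 1)
  expect_equal(sc1$log2_ratio, 0)
  # a state exactly equal to the NAD set: infinite ratio sentinel
  nadOnly <- GRanges("chrA", IRanges(1, 40), state = "N")
  sc2 <- stateComposition(d, nadOnly)
  expect_equal(sc2$inad_frac, 0)
  expect_true(is.infinite(sc2$log2_ratio))
  # overlapping states rejected
  bad <- GRanges("chrA", IRanges(c(1, 20), c(30, 50)),
                 state = c("X", "Y"))
  expect_error(stateComposition(d, bad), "overlap")
})

test_that("feature density uses majority assignment with ties to NAD", {
  layout <- toyLayout(c(chrA = 1000))
  d <- DomainSet(data.frame(chrom = "chrA", start = c(0, 500),
                            end = c(500, 1000),
                            label = c("NAD", "iNAD")),
                 layout = layout)
  # 60/40 in NAD, 40/60 in NAD, exact 50/50 straddler
  f <- GRanges("chrA", IRanges(c(441, 461, 451), width = 100),
               featureClass = "gene")
  fd <- featureDensity(d, f, per = 100)
  n <- fd[fd$domainClass == "NAD", ]
  i <- fd[fd$domainClass == "iNAD", ]
  expect_equal(n$n, 2L)      # majority-NAD + tie
  expect_equal(i$n, 1L)
  expect_equal(n$density_class, 2 / (500 / 100))
  expect_equal(n$density_genome, 2 / (1000 / 100))
  # all features inside NADs leaves zero iNAD density
  f2 <- GRanges("chrA", IRanges(c(1, 101), width = 50),
                featureClass = "gene")
  fd2 <- featureDensity(d, f2)
  expect_equal(fd2$n[fd2$domainClass == "iNAD"], 0L)
})

test_that("segment mean signal is the zero-filled per-base mean", {
  layout <- toyLayout(c(chrA = 100))
  d <- DomainSet(data.frame(chrom = "chrA", start = c(0, 50),
                            end = c(50, 100),
                            label = c("NAD", "iNAD")),
                 layout = layout)
  # constant signal 1 everywhere
  s1 <- signalGr("chrA", 0, 100, 1)
  sm <- segmentMeanSignal(d, s1)
  expect_equal(sm$mean, c(1, 1))
  # signal only in iNADs -> NAD mean 0
  s2 <- signalGr("chrA", 50, 100, 3)
  sm2 <- segmentMeanSignal(d, s2)
  expect_equal(sm2$mean[sm2$label == "NAD"], 0)
  expect_equal(sm2$mean[sm2$label == "iNAD"], 3)
  # half-covered segment at value 2 -> mean 1
  s3 <- signalGr("chrA", 0, 25, 2)
  sm3 <- segmentMeanSignal(d, s3)
  expect_equal(sm3$mean[sm3$label == "NAD"], 1)
})

test_that("border metaprofiles align, mirror and filter correctly", {
  layout <- toyLayout(c(chrA = 3e6))
  d <- DomainSet(data.frame(chrom = "chrA",
                            start = c(4e5, 14e5, 24e5),
                            end = c(8e5, 20e5, 32e5) - c(0, 0, 4e5),
                            label = "NAD"),
                 layout = layout)
  # widths: 400 kb, 600 kb, 400 kb; only the middle one passes 500 kb
  step <- signalGr("chrA", c(0, 14e5), c(14e5, 20e5), c(0, 1))
  # extend outside-zero signal to the whole chromosome
  step <- c(step, signalGr("chrA", 20e5, 30e5, 0))
  mp <- borderMetaprofile(d, list(x = step), flank = 1e5, bin = 1e4,
                          minWidth = 5e5)
  expect_equal(mp@nDomains, 1L)
  expect_equal(mp@nBorders, 2L)
  v <- mp@values[, "x"]
  nb <- length(v)
  expect_equal(unname(v[1:(nb / 2)]), rep(0, nb / 2))     # outside
  expect_equal(unname(v[(nb / 2 + 1):nb]), rep(1, nb / 2))  # inside
  # constant signal -> flat profile at the constant
  const <- signalGr("chrA", 0, 30e5, 7)
  mpc <- borderMetaprofile(d, const, flank = 1e5, bin = 1e4,
                           minWidth = 5e5)
  expect_equal(unname(mpc@values[, 1]), rep(7, 20))
  # width filter: 400/600/800 kb with min 500 kb keeps two domains
  d2 <- DomainSet(data.frame(chrom = "chrA",
                             start = c(1e5, 8e5, 18e5),
                             end = c(5e5, 14e5, 26e5),
                             label = "NAD"),
                  layout = layout)
  mp2 <- borderMetaprofile(d2, const, flank = 5e4, bin = 1e4,
                           minWidth = 5e5)
  expect_equal(mp2@nDomains, 2L)
  # no qualifying domain -> empty profile with n = 0
  mp3 <- borderMetaprofile(d2, const, flank = 5e4, bin = 1e4,
                           minWidth = 1e7)
  expect_equal(mp3@nDomains, 0L)
  expect_true(all(is.na(mp3@values)))
  expect_error(borderMetaprofile(d2, const, flank = 55e3, bin = 1e4),
               "divisible")
})

test_that("class summaries implement the notch formula", {
  # IQR 2 and n 16 give a notch half-width of 0.79
  v <- rep(c(1, 1, 3, 3), 4)
  cs <- classScoreSummary(v, rep("a", 16))
  expect_equal(cs$notch, 1.58 * 2 / sqrt(16))
  expect_equal(cs$notch, 0.79)
  # single-value class: IQR 0, notch 0
  cs2 <- classScoreSummary(5, "b")
  expect_equal(cs2$notch, 0)
  # medians match a sort-based oracle on two toy classes
  set.seed(3)
  vals <- c(rnorm(11), rnorm(15, 2))
  cls <- rep(c("p", "q"), c(11, 15))
  cs3 <- classScoreSummary(vals, cls)
  expect_equal(cs3$median[cs3$class == "p"], sort(vals[1:11])[6])
  expect_equal(cs3$median[cs3$class == "q"], sort(vals[12:26])[8])
  # empty classes warn and are omitted
  expect_warning(
    out <- classScoreSummary(c(1, 2), factor(c("a", "a"),
                                             levels = c("a", "b"))),
    "empty")
  expect_equal(out$class, "a")
})
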