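# Contact loading, classification, aggregation and masking.

toyCen <- function() data.frame(chrom = "chrA", start = 140000,
                                end = 160000)

test_that("normalization divides by the vector product and drops NaN", {
  tri <- data.frame(bin_i = c(0, 10000, 20000),
                    bin_j = c(10000, 30000, 40000),
                    raw = c(10, 8, 6))
  v <- c(2, 5, 1, 2, NaN)
  cs <- normalizeContacts(tri, v, 10000L, "chrA")
  df <- contactRecords(cs)
  # raw 10 with v_i 2, v_j 5 -> 1.0
  expect_equal(df$freq[1], 1.0)
  expect_equal(df$freq[2], 8 / (5 * 2))
  # the record touching the NaN entry is dropped and counted
  expect_equal(nrow(df), 2L)
  expect_equal(dropStats(cs)$dropped_norm, 1L)
  # all-ones vector: normalized equals raw
  cs1 <- normalizeContacts(tri[1:2, ], rep(1, 4), 10000L, "chrA")
  expect_equal(contactRecords(cs1)$freq, tri$raw[1:2])
  # invalid coordinates and short vectors rejected
  expect_error(normalizeContacts(data.frame(bin_i = 5, bin_j = 10000,
                                            raw = 1), v, 10000L),
               "multiples")
  expect_error(normalizeContacts(tri, c(1, 1), 10000L), "shorter")
})

test_that("triplet files round-trip through the loader", {
  layout <- toyLayout(c(chrA = 5e6))
  truth <- simulateDomainTruth(layout, seed = 2)
  sim <- simulateHiC(truth, band = c(1e6, 3e6), pairFraction = 0.3,
                     seed = 3)
  dir <- tempfile(); dir.create(dir)
  writeHiCFiles(sim, dir, prefix = "toy")
  cs <- loadNormalizedContacts(file.path(dir, "toy_chrA.triplets.txt"),
                               file.path(dir, "toy_chrA.norm.txt"),
                               10000L, "chrA")
  df <- contactRecords(cs)
  # loaded normalized values equal the simulator's stored truth on
  # the retained records
  v <- sim$norm$chrA
  keep <- is.finite(v[sim$contacts$bin_i / 1e4 + 1]) &
    is.finite(v[sim$contacts$bin_j / 1e4 + 1])
  expect_equal(nrow(df), sum(keep))
  expect_equal(df$freq, sim$contacts$normalized[keep], tolerance = 1e-6)
  expect_equal(dropStats(cs)$dropped_norm, sum(!keep))
})

test_that("contact classification matches a per-bin brute-force oracle", {
  layout <- toyLayout(c(chrA = 300000), cen = toyCen())
  nads <- GRanges("chrA", IRanges(c(1, 200001), c(90000, 250000)))
  # all 30 x 30 bin pairs as records
  bins <- (0:29) * 10000
  pairs <- expand.grid(bin_i = bins, bin_j = bins)
  pairs <- pairs[pairs$bin_i <= pairs$bin_j, ]
  cs <- new("ContactSet",
            contacts = data.frame(chrom = "chrA", bin_i = pairs$bin_i,
                                  bin_j = pairs$bin_j, freq = 1,
                                  distance = pairs$bin_j - pairs$bin_i),
            binSize = 10000, stats = list())
  cc <- classifyContacts(cs, nads, layout)
  df <- contactRecords(cc)
  # oracle: per-bin labels by majority bp, arms by bin midpoint
  binLab <- function(b) {
    v <- bpVector(nads, 300000)
    frac <- mean(v[(b + 1):(b + 10000)])
    if (frac >= 0.5) "NAD" else "iNAD"
  }
  binArm <- function(b) {
    mid <- b + 5000
    if (mid < 140000) "p" else if (mid > 160000) "q" else NA
  }
  for (k in seq_len(nrow(df))) {
    li <- binLab(df$bin_i[k]); lj <- binLab(df$bin_j[k])
    expect_equal(df$pair_class[k],
                 if (li == "NAD" && lj == "NAD") "NAD-NAD"
                 else if (li == "iNAD" && lj == "iNAD") "iNAD-iNAD"
                 else "mixed")
    ai <- binArm(df$bin_i[k]); aj <- binArm(df$bin_j[k])
    expect_equal(df$arm_class[k], if (ai == aj) paste0(ai, ai) else "pq")
  }
  # conservation: classified + dropped = loaded
  expect_equal(nrow(df) + dropStats(cc)$dropped_centromere,
               nrow(contactRecords(cs)))
  # bins fully inside NADs pair as NAD-NAD; cross-centromere is pq
  expect_equal(df$pair_class[df$bin_i == 0 & df$bin_j == 10000],
               "NAD-NAD")
  expect_equal(df$arm_class[df$bin_i == 0 & df$bin_j == 290000], "pq")
  # symmetry of the per-bin labeling
  lab <- binDomainLabels("chrA", 30, 10000, nads, layout)
  expect_equal(lab[1], "NAD")
  expect_true(all(is.na(lab[15:16])))
})

test_that("contacts beyond the chromosome end are rejected", {
  layout <- toyLayout(c(chrA = 100000))
  cs <- new("ContactSet",
            contacts = data.frame(chrom = "chrA", bin_i = 0,
                                  bin_j = 200000, freq = 1,
                                  distance = 200000),
            binSize = 10000, stats = list())
  expect_error(classifyContacts(cs, GRanges("chrA", IRanges(1, 10)),
                                layout), "beyond")
})

test_that("distance profiles aggregate per class and distance bin", {
  layout <- toyLayout(c(chrA = 200000))
  nads <- GRanges("chrA", IRanges(1, 100000))
  bins <- (0:19) * 10000
  pairs <- expand.grid(bin_i = bins, bin_j = bins)
  pairs <- pairs[pairs$bin_i < pairs$bin_j, ]
  set.seed(4)
  df <- data.frame(chrom = "chrA", bin_i = pairs$bin_i,
                   bin_j = pairs$bin_j, freq = runif(nrow(pairs)),
                   distance = pairs$bin_j - pairs$bin_i)
  cs <- new("ContactSet", contacts = df, binSize = 10000, stats = list())
  cc <- classifyContacts(cs, nads, layout)
  dp <- distanceProfiles(cc, binWidth = 50000)
  rec <- contactRecords(cc)
  for (k in seq_len(nrow(dp))) {
    sel <- floor(rec$distance / 50000) == (dp$distance[k] - 25000) / 50000 &
      rec$pair_class == dp$pair_class[k]
    expect_equal(dp$mean[k], mean(rec$freq[sel]))
    expect_equal(dp$n[k], sum(sel))
  }
  # all-pairs denominator divides by every possible pair of the class
  dpAll <- distanceProfiles(cc, binWidth = 50000, denominator = "all",
                            nads = nads, layout = layout)
  obs <- dp[dp$pair_class == "NAD-NAD" & dp$distance == 25000, ]
  allRow <- dpAll[dpAll$pair_class == "NAD-NAD" &
                    dpAll$distance == 25000, ]
  # 10 NAD bins: distances 1..4 bins have 9+8+7+6 = 30 ordered pairs
  expect_equal(allRow$n, 30)
  expect_equal(allRow$mean * 30, obs$mean * obs$n)
})

test_that("band summaries recover the simulated homotypic boost", {
  layout <- toyLayout(c(chrA = 30e6))
  truth <- simulateDomainTruth(layout, seed = 6)
  sim <- simulateHiC(truth, homotypicBoost = 2, band = c(2e6, 10e6),
                     noiseCV = 0.1, pairFraction = 0.4, seed = 7)
  cs <- normalizeContacts(sim$contacts[, c("bin_i", "bin_j", "raw")],
                          sim$norm$chrA, 10000L, "chrA")
  cc <- classifyContacts(cs, truth, layout)
  bs <- bandSummaries(cc, bands = list(inband = c(2e6, 10e6)))
  w <- bs[bs$band == "inband", ]
  ratio <- w$mean[w$pair_class == "NAD-NAD"] /
    w$mean[w$pair_class == "iNAD-iNAD"]
  expect_lt(abs(ratio - 2), 0.2)
  # a band beyond the chromosome span is omitted with a warning
  expect_warning(bandSummaries(cc, bands = list(far = c(100e6, Inf))),
                 "omitted")
})

test_that("matrix masking keeps exactly the homotypic sub-block", {
  m <- matrix(seq_len(25), 5, 5)
  m <- m + t(m)
  lab <- c("NAD", "NAD", "iNAD", "NAD", "iNAD")
  mk <- maskMatrix(m, lab, keep = "NAD")
  keepIdx <- which(lab == "NAD")
  expect_identical(mk[keepIdx, keepIdx], m[keepIdx, keepIdx])
  expect_true(all(is.na(mk[3, ])) && all(is.na(mk[, 5])))
  # idempotence
  expect_identical(maskMatrix(mk, lab, keep = "NAD"), mk)
  # the two complementary masks plus the cross-class cells rebuild the
  # original support
  mi <- maskMatrix(m, lab, keep = "iNAD")
  cross <- is.na(mk) & is.na(mi)
  rebuilt <- ifelse(!is.na(mk), mk, ifelse(!is.na(mi), mi, NA))
  rebuilt[cross] <- m[cross]
  expect_identical(rebuilt, m)
})
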