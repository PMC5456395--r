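# Interval-set comparative genomics. All coordinates are GRanges
# (1-based closed) internally; BED half-open conversion happens at I/O.

asRanges <- function(x, which = "NAD") {
  if (is(x, "DomainSet")) {
    if (which == "NAD") nadRanges(x) else inadRanges(x)
  } else granges(x, use.mcols = FALSE)
}

#' Complement an interval set over a genome layout
#'
#' Per-chromosome set complement over the full layout extent: the
#' returned ranges are disjoint from the input and together with it tile
#' every chromosome (this is how the iNAD set is defined from the NAD
#' set).
#'
#' @param x A `GRanges`, or a [DomainSet-class] (whose NAD intervals are
#'   complemented).
#' @param layout A [GenomeLayout-class].
#' @return A `GRanges` of the complementary intervals.
#' @export
complementIntervals <- function(x, layout) {
  gr <- asRanges(x)
  len <- chromLengths(layout)
  chr <- as.character(seqnames(gr))
  if (!all(chr %in% names(len))) stop("interval chromosome not in layout")
  if (any(end(gr) > len[chr])) stop("interval exceeds chromosome length")
  rr <- IRanges::ranges(gr)
  idx <- split(seq_along(gr), factor(chr, levels = names(len)))
  pieces <- lapply(names(len), function(c)
    IRanges::gaps(rr[idx[[c]]], start = 1L, end = as.integer(len[[c]])))
  out <- GRanges(rep(names(len), lengths(pieces)), do.call(c, pieces),
                 seqinfo = layout@seqinfo)
  out
}

# per-chromosome reduced IRanges of a GRanges (strand ignored); all bp
# set arithmetic below runs on these lists, off the GRanges dispatch
# path
perChromRanges <- function(gr) {
  chr <- as.character(seqnames(gr))
  rr <- IRanges::ranges(gr)
  lapply(split(seq_along(gr), chr), function(i) IRanges::reduce(rr[i]))
}

bpOf <- function(rl)
  sum(vapply(rl, function(r) sum(as.numeric(IRanges::width(r))),
             numeric(1)), 0)

# |A u B| via per-chromosome reduce; |A n B| = |A| + |B| - |A u B|
unionBpOf <- function(ra, rb) {
  tot <- 0
  for (c in union(names(ra), names(rb))) {
    r <- IRanges::reduce(c(ra[[c]], rb[[c]]))
    tot <- tot + sum(as.numeric(IRanges::width(r)))
  }
  tot
}

#' Base-pair overlap statistics and Jaccard index of two interval sets
#'
#' Intersection, set-difference and union sizes in bp, plus the Jaccard
#' similarity (intersecting bp / union bp).
#'
#' @param a,b `GRanges` or [DomainSet-class]s (NAD intervals used).
#' @return Named list: `intersection_bp`, `a_only_bp`, `b_only_bp`,
#'   `union_bp`, `jaccard`.
#' @export
overlapStats <- function(a, b) {
  ra <- perChromRanges(asRanges(a))
  rb <- perChromRanges(asRanges(b))
  abp <- bpOf(ra)
  bbp <- bpOf(rb)
  ubp <- unionBpOf(ra, rb)
  ibp <- abp + bbp - ubp
  list(intersection_bp = ibp,
       a_only_bp = abp - ibp,
       b_only_bp = bbp - ibp,
       union_bp = ubp,
       jaccard = if (ubp > 0) ibp / ubp else NA_real_)
}

#' Chromatin-state composition of NADs and iNADs
#'
#' For every chromatin state, the bp of overlap with each domain class,
#' the class-size-normalized fractions, and the log2 ratio of the two
#' fractions. States absent from one class get an infinite ratio
#' (reported, never dropped); states absent from both get NaN.
#'
#' @param domains A [DomainSet-class].
#' @param states `GRanges` with a `state` metadata column; the state
#'   intervals must not overlap each other.
#' @return data.frame: state, nad_bp, inad_bp, nad_frac, inad_frac,
#'   log2_ratio.
#' @export
stateComposition <- function(domains, states) {
  if (!IRanges::isDisjoint(states))
    stop("state intervals overlap; states must partition the genome")
  st <- as.character(mcols(states)$state)
  if (is.null(st)) stop("states need a 'state' metadata column")
  rn <- perChromRanges(nadRanges(domains))
  ri <- perChromRanges(inadRanges(domains))
  nadBp <- bpOf(rn)
  inadBp <- bpOf(ri)
  stateIdx <- split(seq_along(states), st)
  lv <- unique(st)
  rows <- lapply(lv, function(s) {
    g <- perChromRanges(states[stateIdx[[s]]])
    gbp <- bpOf(g)
    a <- gbp + nadBp - unionBpOf(g, rn)
    b <- gbp + inadBp - unionBpOf(g, ri)
    fa <- if (nadBp > 0) a / nadBp else NA_real_
    fb <- if (inadBp > 0) b / inadBp else NA_real_
    data.frame(state = s, nad_bp = a, inad_bp = b,
               nad_frac = fa, inad_frac = fb,
               log2_ratio = log2(fa / fb))
  })
  do.call(rbind, rows)
}

#' Feature densities per domain class
#'
#' Counts features per Mb of each domain class. A feature is assigned to
#' the class containing the majority of its length (exact ties go to
#' NAD). Densities are emitted under both normalizations: per Mb of the
#' assigned class and per Mb of the whole layout.
#'
#' @param domains A [DomainSet-class].
#' @param features `GRanges`, optionally with a `featureClass` metadata
#'   column to stratify by.
#' @param per Normalization unit in bp (default 1 Mb).
#' @return data.frame: featureClass, domainClass, n, density_class,
#'   density_genome.
#' @export
featureDensity <- function(domains, features, per = 1e6) {
  nad <- nadRanges(domains)
  fc <- mcols(features)$featureClass
  if (is.null(fc)) fc <- rep("feature", length(features))
  nadBp <- overlapBp(features, nad)
  assigned <- ifelse(nadBp * 2 >= width(features), "NAD", "iNAD")
  classBp <- c(NAD = sum(as.numeric(width(nad))),
               iNAD = sum(as.numeric(width(inadRanges(domains)))))
  genomeBp <- sum(as.numeric(chromLengths(genomeLayout(domains))))
  grid <- expand.grid(featureClass = unique(fc),
                      domainClass = c("NAD", "iNAD"),
                      stringsAsFactors = FALSE)
  grid$n <- mapply(function(f, d) sum(fc == f & assigned == d),
                   grid$featureClass, grid$domainClass)
  grid$density_class <- grid$n / (classBp[grid$domainClass] / per)
  grid$density_genome <- grid$n / (genomeBp / per)
  rownames(grid) <- NULL
  grid
}

# per-chromosome value-weighted coverage Rle of a bedGraph-like GRanges
signalCoverage <- function(signal, layout) {
  if (!IRanges::isDisjoint(signal))
    stop("signal intervals overlap; bedGraph tracks must be disjoint")
  v <- mcols(signal)$score
  if (is.null(v)) stop("signal needs a 'score' metadata column")
  len <- chromLengths(layout)
  sig <- signal
  seqlevels(sig) <- names(len)
  seqlengths(sig) <- as.integer(len)
  coverage(sig, weight = as.numeric(v))
}

#' Per-segment mean signal by domain class
#'
#' Length-weighted mean of a bedGraph-like signal over every domain
#' segment; bases with no signal coverage count as zero.
#'
#' @param domains A [DomainSet-class].
#' @param signal `GRanges` with non-overlapping intervals and a `score`
#'   column.
#' @return data.frame: chrom, start (0-based), end, label, mean.
#' @export
segmentMeanSignal <- function(domains, signal) {
  layout <- genomeLayout(domains)
  cov <- signalCoverage(signal, layout)
  gr <- domainRanges(domains)
  chr <- as.character(seqnames(gr))
  means <- numeric(length(gr))
  for (c in unique(chr)) {
    idx <- which(chr == c)
    vw <- Views(cov[[c]], start(gr)[idx], end(gr)[idx])
    means[idx] <- viewMeans(vw)
  }
  data.frame(chrom = chr, start = start(gr) - 1L, end = end(gr),
             label = as.character(mcols(gr)$label), mean = means)
}

#' Class-wise score summaries with notch widths
#'
#' Per class: n, median, quartiles and the notch half-width
#' 1.58 * IQR / sqrt(n) (the 95 percent confidence half-width of the
#' median used for notched boxplots). Empty classes are omitted with a
#' warning.
#'
#' @param values Numeric scores or log2 fold changes.
#' @param classes Class label per value.
#' @return data.frame: class, n, median, q1, q3, notch.
#' @export
classScoreSummary <- function(values, classes) {
  stopifnot(length(values) == length(classes))
  classes <- as.factor(classes)
  empty <- setdiff(levels(classes), unique(as.character(classes[!is.na(values)])))
  if (length(empty))
    warning("empty class(es) omitted: ", paste(empty, collapse = ", "))
  keep <- !is.na(values)
  rows <- lapply(unique(as.character(classes[keep])), function(cl) {
    v <- values[keep & classes == cl]
    q <- unname(quantile(v, c(0.25, 0.5, 0.75)))
    data.frame(class = cl, n = length(v), median = q[2],
               q1 = q[1], q3 = q[3],
               notch = 1.58 * (q[3] - q[1]) / sqrt(length(v)))
  })
  do.call(rbind, rows)
}
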