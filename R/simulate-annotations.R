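#' Simulate annotation tracks coupled to a domain truth
#'
#' Generates the fixture annotations the downstream comparative-genomics
#' stages consume: (i) a multi-state chromatin-state partition with one
#' heterochromatic state enriched inside NADs; (ii) five
#' percentage-normalized "replication fraction" signal tracks whose
#' timing shifts across NAD borders (early outside, late inside);
#' (iii) gene features with class labels; (iv) per-gene log2 fold changes
#' whose mean couples to a domain-change class (positive for genes losing
#' nucleolus association, negative for genes gaining it).
#'
#' @param truth A [DomainSet-class] ground-truth segmentation.
#' @param seed Integer seed.
#' @param tileSize Tile size (bp) at which chromatin states are drawn.
#' @param hetProbNad,hetProbInad Probability that a tile is the
#'   heterochromatic state inside NADs / iNADs. Equal values give the
#'   null (uncoupled) model.
#' @param repliProfile "sigmoid" for a smooth timing shift over
#'   `repliScale` bp around borders, "step" for an ideal step at the
#'   border.
#' @param repliScale Length scale (bp) of the sigmoid timing shift.
#' @param nGenes Number of simulated genes.
#' @param geneWidth Gene width (bp).
#' @param fcEffect Effect size of the fold-change coupling (log2 units);
#'   0 gives the null model.
#' @param fcSd Per-gene fold-change noise sd (log2 units).
#' @return List with `states` (GRanges, `state` column), `repli` (named
#'   list of five bedGraph-style GRanges with `score`), `genes` (GRanges
#'   with `gene`, `geneClass`, `changeClass` columns) and `foldChanges`
#'   (data.frame gene/changeClass/log2fc).
#' @export
simulateAnnotationTracks <- function(truth, seed = 1L, tileSize = 10000L,
                                     hetProbNad = 0.7, hetProbInad = 0.1,
                                     repliProfile = c("sigmoid", "step"),
                                     repliScale = 1e5,
                                     nGenes = 300L, geneWidth = 20000L,
                                     fcEffect = 0.5, fcSd = 0.4) {
  repliProfile <- match.arg(repliProfile)
  stopifnot(hetProbNad >= 0, hetProbNad <= 1, hetProbInad >= 0,
            hetProbInad <= 1)
  layout <- genomeLayout(truth)
  len <- chromLengths(layout)
  nad <- nadRanges(truth)
  set.seed(seed)

  stateNames <- c("Het", "Quies", "Tx", "Enh", "TSS")
  tileChrom <- character(0); tileStart <- integer(0); tileEnd <- integer(0)
  for (chr in names(len)) {
    s <- seq.int(0L, as.integer(len[[chr]]) - 1L, by = tileSize)
    tileChrom <- c(tileChrom, rep(chr, length(s)))
    tileStart <- c(tileStart, s)
    tileEnd <- c(tileEnd, pmin(s + tileSize, as.integer(len[[chr]])))
  }
  tiles <- GRanges(tileChrom, IRanges(tileStart + 1L, tileEnd),
                   seqinfo = layout@seqinfo)
  nadbp <- overlapBp(tiles, nad)
  inNad <- nadbp * 2 >= width(tiles)
  pHet <- ifelse(inNad, hetProbNad, hetProbInad)
  isHet <- runif(length(tiles)) < pHet
  other <- sample(stateNames[-1], length(tiles), replace = TRUE)
  state <- ifelse(isHet, "Het", other)
  # merge adjacent tiles of equal state into maximal intervals
  states <- tiles
  mcols(states)$state <- state
  states <- unlist(GenomicRanges::reduce(
    GenomicRanges::split(states, mcols(states)$state)))
  mcols(states)$state <- names(states)
  names(states) <- NULL
  states <- GenomicRanges::sort(states)

  # replication fractions: latentness u in [0,1]; 0 = early (outside
  # NADs), 1 = late (deep inside). Five fractions respond at centers
  # spread over [0,1]; values are percentage-normalized per bin.
  fracNames <- c("G1b", "S1", "S2", "S3", "S4")
  centers <- c(0.05, 0.28, 0.5, 0.72, 0.95)
  binSize <- 10000L
  repli <- vector("list", 5); names(repli) <- fracNames
  binChrom <- character(0); binStart <- integer(0); binEnd <- integer(0)
  uAll <- numeric(0)
  for (chr in names(len)) {
    s <- seq.int(0L, as.integer(len[[chr]]) - 1L, by = binSize)
    e <- pmin(s + binSize, as.integer(len[[chr]]))
    mid <- (s + e) / 2
    d <- signedDistanceToNad(chr, mid, nad)  # >0 inside NAD
    u <- if (repliProfile == "step") as.numeric(d > 0)
         else plogis(d / repliScale * 4)
    binChrom <- c(binChrom, rep(chr, length(s)))
    binStart <- c(binStart, s); binEnd <- c(binEnd, e)
    uAll <- c(uAll, u)
  }
  resp <- vapply(centers, function(cc) dnorm(uAll, cc, 0.22), numeric(length(uAll)))
  resp <- resp / rowSums(resp) * 100
  for (k in seq_along(fracNames)) {
    gr <- GRanges(binChrom, IRanges(binStart + 1L, binEnd),
                  seqinfo = layout@seqinfo)
    mcols(gr)$score <- resp[, k]
    repli[[k]] <- gr
  }

  # genes with activity classes and domain-change classes
  geneChrom <- sample(names(len), nGenes, replace = TRUE,
                      prob = as.numeric(len) / sum(as.numeric(len)))
  geneStart <- vapply(geneChrom, function(chr)
    sample.int(max(1L, as.integer(len[[chr]]) - geneWidth), 1L), integer(1))
  genes <- GRanges(geneChrom, IRanges(geneStart + 1L, geneStart + geneWidth),
                   seqinfo = layout@seqinfo)
  mcols(genes)$gene <- sprintf("G%04d", seq_len(nGenes))
  mcols(genes)$geneClass <- sample(c("escaper", "heterogeneous", "inactive"),
                                   nGenes, replace = TRUE,
                                   prob = c(0.2, 0.3, 0.5))
  changeClass <- sample(c("constitutive", "young_only", "senescent_only"),
                        nGenes, replace = TRUE, prob = c(0.6, 0.2, 0.2))
  mcols(genes)$changeClass <- changeClass
  effect <- c(constitutive = 0, young_only = fcEffect,
              senescent_only = -fcEffect)[changeClass]
  fc <- rnorm(nGenes, mean = effect, sd = fcSd)
  list(states = states, repli = repli, genes = genes,
       foldChanges = data.frame(gene = mcols(genes)$gene,
                                changeClass = changeClass,
                                log2fc = fc))
}

# bp of overlap of each query range with a subject set
overlapBp <- function(query, subject) {
  subject <- reduce(subject, ignore.strand = TRUE)
  hits <- findOverlaps(query, subject, ignore.strand = TRUE)
  ov <- width(pintersect(query[queryHits(hits)], subject[subjectHits(hits)]))
  out <- numeric(length(query))
  if (length(hits)) {
    agg <- tapply(ov, queryHits(hits), sum)
    out[as.integer(names(agg))] <- agg
  }
  out
}

# signed distance (bp) of positions on one chromosome to the nearest NAD
# border: positive inside a NAD, negative outside
signedDistanceToNad <- function(chr, pos, nad) {
  nad <- reduce(nad[seqnames(nad) == chr], ignore.strand = TRUE)
  if (!length(nad)) return(rep(-Inf, length(pos)))
  s <- start(nad) - 0.5; e <- end(nad) + 0.5   # borders between bp
  inside <- rep(FALSE, length(pos))
  idx <- findInterval(pos, as.vector(rbind(s, e)))
  inside <- idx %% 2 == 1
  borders <- sort(c(s, e))
  dmin <- vapply(pos, function(p) min(abs(p - borders)), numeric(1))
  ifelse(inside, dmin, -dmin)
}
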