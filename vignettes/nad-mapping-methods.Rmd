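---
title: "Mapping nucleolus-associated domains and analysing them across scales"
author: "nadkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping nucleolus-associated domains and analysing them across scales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nadkit)
```

# The problem

Nucleolus-associated chromosomal domains (NADs) are the genomic regions
that reproducibly co-purify with biochemically isolated nucleoli. They
are mapped by comparative hybridization: DNA from the nucleolar fraction
and from a background fraction (genomic input or the non-nucleolar
supernatant) is measured on the same probe grid, and the per-probe log2
ratio of nucleolar over background signal forms an enrichment track.
Because a probe is either inside or outside nucleolus-associated
chromatin, this enrichment is bimodally distributed, which motivates a
two-state segmentation model rather than a threshold. nadkit implements
that segmentation and the three downstream analysis scales used to
characterize the resulting domain maps: comparative interval genomics,
domain-class Hi-C contact aggregation, and shell-ROI image
quantification. A synthetic-data module generates every input with
known ground truth, so each stage is validated by parameter recovery
rather than by fixed expected outputs.

# The segmentation model

The caller works on a smoothed, replicate-averaged enrichment track:

1. **Quantile normalization** makes every array share the distribution
   of mean order statistics. Replicates of each fraction are normalized
   together; nucleolar and background fractions are normalized as
   separate groups by default, because their marginal distributions
   genuinely differ (the nucleolar fraction is bimodal) and forcing a
   common marginal would compress the very signal being mapped. A joint
   mode is available for arrays of the same design.
2. **Enrichment** is `log2(nucleolar) - log2(background)` per probe and
   replicate. Probes with nonpositive intensities are masked and
   counted, never silently dropped.
3. **Smoothing** replaces each probe by the median over a 100 kb window
   centered on it (per chromosome, truncated at ends). The median is
   deliberate: it suppresses single-probe noise but keeps domain edges
   sharp, because the windowed median switches state when the window
   majority switches.
4. **Replicate averaging** pools the smoothed replicates of one
   condition into a single track.

A two-state hidden Markov model with Gaussian emissions is then fitted
by Baum–Welch on the concatenated per-chromosome sequences; no
transition is learned or decoded across a chromosome boundary. The
emission family is a package convention: a two-state model with
heavy-tailed emissions would behave almost identically on smoothed
tracks, and the Gaussian keeps the M-step closed-form. Initialization
is deterministic — emission means at the 25th/75th percentiles of the
track, equal standard deviations, sticky transitions (0.99
self-transition), uniform initial distribution — so a fit is
reproducible without a random seed. Degenerate fits (a collapsing
emission standard deviation or an emptied state) trigger restarts from
wider percentile pairs (10/90, then 5/95) and finally an error; a
unimodal track therefore either fails loudly or yields two
barely-separated states, which `stateSeparation()` exposes, and never a
confidently bimodal segmentation.

Decoding uses the Viterbi path. Consecutive same-state probes become
intervals, with each probe's extent reaching to the next probe's
position (the last probe extends by the median spacing). NAD intervals
shorter than 10 kb are relabeled iNAD and merged into their flanks;
merging rather than deleting keeps the segmentation a tiling of the
analyzed extent, which the interval statistics downstream rely on. Each
interval's score is the mean smoothed enrichment of its probes (the NAD
score). Differential domains between two conditions are plain bp-level
set algebra on the two NAD sets: condition-specific differences and the
shared (constitutive) intersection.

**Tunable parameters.** Smoothing window 100 kb (bp; the scale below
which single-probe evidence is not trusted); minimum NAD length 10 kb
(bp); EM tolerance `1e-4` on the log-likelihood and at most 200
iterations (the fit typically converges in fewer than 10 on smoothed
tracks).

# Interval genomics

All interval statistics are bp-exact and are tested against an
exhaustive per-basepair boolean-array oracle. Conventions, chosen once:

* Coordinates are BED-style 0-based half-open at every file boundary
  and 1-based closed `GRanges` internally.
* The Jaccard index is intersecting bp over union bp of two reduced
  interval sets.
* Chromatin-state composition normalizes overlaps by each domain
  class's total size; a state absent from one class yields an infinite
  log2 ratio, reported as a sentinel rather than dropped.
* A feature straddling a domain border is assigned to the class holding
  the majority of its length; an exact 50/50 tie goes to NAD. Feature
  densities are emitted under both normalizations (per Mb of the
  assigned class and per Mb of the genome) because either can be wanted
  for comparisons across maps.
* Per-segment signal means count uncovered bases as zero — the
  conservative bedGraph reading, since absence of a record is absence
  of signal, not missing data.
* Border metaprofiles use only NADs wider than 500 kb, so that the
  ±500 kb flank (1 kb bins by default) is not dominated by the opposite
  border of the same domain. Profiles from the 3' border are mirrored
  before averaging so the offset axis always points from outside into
  the domain on the p→q chromosome axis; borders whose full flank
  window does not fit inside the chromosome are skipped and the numbers
  of contributing domains and borders are reported.
* Class summaries report median, quartiles and the notch half-width
  `1.58 * IQR / sqrt(n)`, the standard 95% confidence half-width for a
  boxplot median.

# Hi-C contact classes

Normalized intrachromosomal contacts at 10 kb resolution are obtained
by dividing raw triplet counts by the product of the per-bin
normalization vector entries; records touching NaN or zero vector
entries are dropped and counted. Each bin gets a domain label by
majority-bp overlap with the NAD set (ties to NAD, the same rule as for
features); bins whose majority lies in the centromere gap are unlabeled
and their contacts dropped with a count, so loaded records always equal
classified plus dropped. Pairs are NAD-NAD, iNAD-iNAD or mixed, and
intra-arm (pp, qq) or inter-arm (pq) by bin position relative to the
centromere interval, which is a required input table, not a hard-coded
assembly fact. Distance is bin-start to bin-start.

Class-wise distance profiles and band summaries average over observed
records by default; an all-pairs denominator (unobserved pairs counted
as zero) is available because sparse matrices make the two averages
genuinely different quantities. Band summaries default to 10–50 Mb —
the lower bound excludes intra-domain contacts — and >100 Mb, per
chromosome and class, with chromosomes too short for a band omitted
with a warning. Matrix masking to one domain class (for visualizing
homotypic blocks) sets complementary rows/columns to `NA` and is
idempotent.

# Image quantification

Shell ROIs are fixed-physical-depth bands: the lamina shell is the
nucleus pixels within 240 nm (inward, Euclidean on the pixel grid) of
the nuclear boundary, and the perinucleolar shell the non-nucleolar
nucleus pixels within 240 nm (outward) of the nucleolar boundary. Depth
is rounded to whole pixels (240 nm at 80.25 nm pixels is 3 px); the two
shells are not forced to be exclusive because nothing in the underlying
measurement makes them so. Per ROI the package reports the fraction of
total nuclear intensity, the coefficient of variation (sd/mean, a NaN
sentinel when the ROI carries no signal), and the share of bright
nuclear pixels in the ROI. "Bright" has two incompatible operational
readings — at or above 90% of the maximal nuclear intensity, or the top
decile of pixels by rank — and both are implemented, with the threshold
reading as the default; the two disagree whenever the intensity
histogram's upper tail is not exactly 10% of pixels, so the choice is
exposed rather than hidden. All three metrics are invariant to positive
rescaling of the image. Object counting uses 8-connectivity in 2D and
26-connectivity in 3D, with volumes as voxel count times voxel volume.

# The synthetic-data generators

The generators define the conditions under which the pipeline is
validated; their defaults are fixed study conditions, not tuning knobs.

* **Domain truth**: alternating NAD/iNAD segments with exponential
  lengths (truncated at chromosome ends), the segment-length law of a
  two-state Markov process. Default means 400 kb (NAD) and 650 kb
  (iNAD) give a NAD genome fraction near 0.38 and median NAD widths of
  a few hundred kb, the regime reported for human fibroblast NAD maps.
* **Enrichment arrays**: probes on a regular 1 kb grid (the probe
  density of the original arrays is not public knowledge, so a regular
  grid is the neutral convention); per-probe, per-replicate enrichment
  drawn from the state's Gaussian (defaults ±1, sd 0.3 — well-separated
  but noisy at the single-probe level), added onto an independent
  background baseline and exported on the raw intensity scale so the
  whole normalization path is exercised.
* **Annotations**: a five-state chromatin partition with one
  heterochromatic state enriched in NADs by a tunable coupling; five
  percentage-normalized replication-timing fractions whose latentness
  shifts across NAD borders (smooth sigmoid by default, an ideal step
  for border-alignment checks); genes with activity-class labels; and
  per-gene log2 fold changes whose sign couples to a domain-change
  class. Every coupling has a null setting, and the downstream
  pipeline is required to report null results on null data.
* **Hi-C**: expected normalized contact proportional to
  distance^(−1), multiplied by a homotypic boost (default 2) for
  NAD-NAD pairs in the 10–50 Mb band; multiplicative lognormal noise
  (mean 1, CV 0.2) keeps frequencies positive; a uniform-[0.5, 2]
  normalization vector with a few NaN entries is applied in reverse so
  the loader's division and dropping logic is exercised. Only a random
  subset of bin pairs (default 10%) is materialized: the per-pair
  expectation is unaffected, so class means and recovered ratios stay
  unbiased, at a fraction of the memory of the ~72 million pairs of a
  120 Mb chromosome.
* **Nucleus images**: a circular nucleus with disjoint nucleolar disks;
  intensity is deposited so that the lamina and perinucleolar shells
  receive exactly the target fractions of total nuclear intensity
  (defaults 0.095 and 0.052, typical proliferating-fibroblast medians
  for H3K9me3) before multiplicative noise; Gaussian bright foci shape
  the within-region distribution without changing region totals. A 3D
  stack mode provides ellipsoidal masks for object counting and
  volumetry.

What the generators do *not* emulate: probe-specific affinity biases,
copy-number structure, chromatin polymer physics behind the Hi-C decay,
interchromosomal contacts, optical PSF blur and uneven illumination.
Passing the recovery suites therefore shows the pipeline's inferential
machinery is correct under the stated noise models, not that every
real-data artifact is handled.

# Problem sizes and numerical choices

The validation suites run at deliberately chosen sizes: segmentation
recovery on 10 chromosomes × 10 Mb at 1 kb probes (100,000 probes, ≥95%
bp accuracy and emission means within ±0.1 required); interval-oracle
equivalence over 200 random set pairs on a 1 Mb chromosome (exact
agreement required); Hi-C recovery on one 120 Mb chromosome at 10 kb
bins (boost recovered within 10%, null ratio within 5% — the null
deviates from 1 by a small compositional effect, since the two
homotypic classes sample slightly different distance distributions
inside a band); border metaprofiles on a regular 600 kb / 800 kb domain
grid so tails are provably flat; imaging on 50 simulated nuclei, with
the recovery tolerance set by the intensity shift of a one-pixel change
in shell depth rather than by a free constant.

Remaining numerical conventions: EM underflow is prevented by per-step
scaling; emission sds are floored at `1e-4` of the track sd and going
below it is treated as degeneracy; the smoothing window uses closed
bounds (a probe exactly at the window edge is included); `round()`
half-even behavior decides shell depths in pixels; quantiles are R type
7 throughout.

# Known limitations

The caller assumes the two fractions share a probe grid and does not
model probe affinity or GC bias; sex chromosomes are not treated
specially (exclude them upstream if the map should be autosomal);
Hi-C matrix balancing is consumed, never computed; image segmentation
(producing the nucleus and nucleolus masks) is out of scope, as are
FISH spot calling and any statistical significance testing between
classes — the summaries are designed to feed standard tests, not to
replace them.
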