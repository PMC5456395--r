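# nadkit

Genome-wide mapping and multi-scale analysis of nucleolus-associated
chromosomal domains (NADs).

NADs are the genomic regions that reproducibly co-purify with
biochemically isolated nucleoli — one of the two major heterochromatic
anchoring compartments of the mammalian nucleus, alongside the
lamina-associated domains at the nuclear envelope. nadkit is for
genome biologists who have (or simulate) nucleolar-vs-background
hybridization tracks and want reproducible domain maps plus the
standard follow-up analyses: how the domains compare with other
annotations, how they interact in Hi-C space, and how the corresponding
heterochromatin is distributed inside nuclei in immunofluorescence
images.

## The model at the core

Per probe *p*, nucleolar enrichment is the log ratio

E(p) = log2 I_nucleolar(p) − log2 I_background(p),

quantile-normalized, smoothed by 100 kb sliding medians and averaged
over replicates. Because probes are either inside or outside
nucleolus-associated chromatin, E is bimodal, and domains are inferred
with a two-state hidden Markov model with Gaussian emissions
(μ_NAD > μ_iNAD by convention), fitted by Baum–Welch per chromosome and
decoded by Viterbi. NAD segments shorter than 10 kb are merged away;
each domain is scored by its mean enrichment (the "NAD score").
Downstream, interval sets are compared by bp-exact statistics
(Jaccard = intersecting bp / union bp), Hi-C contacts are classed
NAD-NAD / iNAD-iNAD / mixed by majority-overlap bin labels and averaged
in distance bands, and nuclear images are quantified in 240 nm shell
ROIs (intensity fraction, coefficient of variation sd/μ, bright-pixel
share). Every stage has a synthetic generator with known ground truth,
so the whole pipeline is validated by parameter recovery.

## Worked example

Simulate a small genome with known domain structure, run the full
calling pipeline, and check the map against the truth:

```r
library(nadkit)

layout <- GenomeLayout(setNames(rep(1e7, 4), paste0("chr", 1:4)))
truth  <- simulateDomainTruth(layout, seed = 1)
arrays <- simulateEnrichmentArrays(truth, seed = 2)

nuc <- quantileNormalize(arrays$nucleolar)
bg  <- quantileNormalize(arrays$background)
E   <- computeEnrichment(nuc, bg)
Em  <- averageReplicates(smoothSlidingMedian(E, window = 1e5))

model  <- fitTwoStateHMM(Em)
model
#> TwoStateHMM: mu(NAD) = 0.9594 , mu(iNAD) = -0.9736 ; sd = 0.111/0.0881
#>   self-transitions: 0.9978/0.9987 ; logLik = 36492.27 (converged)

called <- callDomains(Em, model, minLen = 1e4, layout = layout)
called
#> DomainSet: 34 NADs ( 14,773,000 bp ), 34 iNADs on 4 chromosome(s)

round(nadSetSummary(called), 3)
#>    n total_bp median_width q1_width q3_width n_above_threshold genome_fraction
#> 1 34 14773000       320000   170000   506000                 9           0.369

domainAccuracy(called, truth)
#> [1] 0.9951765
round(overlapStats(called, truth)$jaccard, 3)
#> [1] 0.987
```

The fitted emission means recover the simulated ±1 log2 enrichment, the
called map covers ~37% of the genome with median NAD width ~320 kb, and
99.5% of base pairs carry the true label (Jaccard 0.987 against the true
NAD set).

From here, `differentialDomains()` contrasts two conditions' maps,
`stateComposition()` / `featureDensity()` / `segmentMeanSignal()` /
`borderMetaprofile()` compare domains with annotations and signal
tracks, `normalizeContacts()` → `classifyContacts()` →
`bandSummaries()` handle Hi-C triplets, and `shellROI()` /
`roiIntensityStats()` / `countObjectsAndVolumes()` quantify nucleus
images (see the vignette in `vignettes/`).

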