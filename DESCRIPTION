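Package: nadkit
Title: Mapping and Multi-Scale Analysis of Nucleolus-Associated Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-wide mapping of nucleolus-associated
    chromosomal domains (NADs) from nucleolar-versus-background tiling
    signal tracks, and for their downstream multi-scale analysis.
    Provides quantile normalization, log2 enrichment computation,
    sliding-median smoothing, a two-state Gaussian hidden Markov model
    segmenter with Viterbi decoding and a minimum domain length rule,
    differential (condition-specific) domain calling, interval-set
    comparative genomics (complements, Jaccard statistics, chromatin-state
    composition, feature densities, per-segment signal means,
    border-aligned metaprofiles, notched class summaries), domain-class
    annotation and aggregation of normalized intrachromosomal Hi-C
    contacts (distance profiles, distance-band summaries, masked
    matrices), and shell-ROI quantification of immunofluorescence images
    (intensity fractions, coefficients of variation, brightest-pixel
    fractions, object counts and volumes). A synthetic-data module
    generates every input with known ground truth so the whole pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    limma,
    EBImage,
    data.table,
    jsonlite,
    tiff
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
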