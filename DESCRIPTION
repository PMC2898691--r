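Package: stsDemog
Title: Demographic Inference for Crop-Weed STS Panels by Coalescent
    Simulation and Rejection ABC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for multi-locus sequence-tagged-site (STS) panels from
    crop-weed species complexes, built around the question of how weedy
    populations arise from domesticated and wild relatives.  Provides
    readers for per-locus FASTA alignments with population maps, site-class
    annotations and cytoplasm (cytotype) markers; diversity and
    differentiation statistics (Watterson's and pairwise theta, Tajima's D,
    haploid Weir-Cockerham F_st with singleton dropping and zero clamping,
    shared/private/fixed site partitions); a compiled ancestral
    recombination graph coalescent simulator for a two-population
    founder-bottleneck model in MS units; and a rejection approximate
    Bayesian computation engine that compares divergence-timing scenarios
    via approximate likelihoods and maps bottleneck intensity.  Includes
    synthetic-data generators with known truth and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
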