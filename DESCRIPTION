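Package: polypopgen
Title: Population Genetics of Tetraploid Microsatellite Data
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrated analysis pipeline for polyploid (tetraploid)
    microsatellite genotype data with allele-dosage ambiguity: genotype
    import and dominant (band presence/absence) recoding, per-population
    diversity statistics (allele counts, rarefied allelic richness, Nei
    gene diversity, inbreeding coefficients with permutation tests,
    private alleles), Bruvo inter-individual distances with exact
    handling of dosage completions, principal coordinate analysis,
    Bayesian admixture clustering of dominant data with Evanno delta-K
    model choice and greedy replicate alignment, hierarchical AMOVA with
    Phi-statistics and Slatkin gene-flow estimates, Monmonier barrier
    detection on a Delaunay network of sampling sites, standard,
    stratified and partial Mantel tests, and beta-regression models of
    genetic distance on geographic distance and barrier covariates.
    Includes a synthetic tetraploid-genotype generator with known truth
    (hierarchical-island and stepping-stone structure, planted barriers,
    heterozygote excess) so that every pipeline stage is testable
    without access to original field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    geosphere,
    jsonlite,
    MASS,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
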