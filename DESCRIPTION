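Package: chemodivgwa
Title: Integrating Chemodiversity, Population Genetics, and Mixed-Model
    Association in Natural Plant Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline linking intraspecific genetic diversity,
    untargeted LC-MS chemodiversity, environment, and disease status in
    natural tree populations. Reads aligned LC-MS peak tables, collapses
    redundant features into metabolites, and computes per-sample
    chemodiversity indices (richness, Shannon, Hill numbers, evenness,
    Berger-Parker dominance) with alpha/gamma decomposition. Provides
    genotype quality control and population-genetic statistics (exact
    Hardy-Weinberg tests, rarefied allelic richness, heterozygosities,
    nucleotide diversity, inbreeding coefficients, identity-by-state
    kinship, Weir-Cockerham F_ST), distance-congruence tests (DAPC,
    pairwise ANOSIM, full and partial Mantel tests), EMMA/EMMAX mixed-model
    SNP-metabolite association with environmental covariates, Gaussian
    graphical metabolite networks by shrinkage partial correlation, and
    health-biomarker discovery by random forests and logistic mixed models.
    Includes a synthetic-cohort generator with recorded ground truth so
    every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    lme4,
    randomForest,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    mclust,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
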