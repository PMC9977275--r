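Package: microdiv
Title: Eco-Evolutionary Diversity-Slope Analysis for Gut Metagenome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Links gut-community diversity to intra-species genetic diversity
    in shotgun-metagenome cohorts. Provides readers and validators for
    MIDAS-style merged tables (species relative abundance, per-species SNV
    depth/allele counts, gene coverage), per-sample Shannon diversity and
    (rarefied) richness at any taxonomic rank, within-species polymorphism
    rates at synonymous and nonsynonymous sites under the standard coverage
    and core-gene filters, gene copy-number estimation with presence/absence
    and gain/loss calling over time, within-sample strain-number inference by
    binomial mixture models selected with BIC, and hierarchical
    "diversity-slope" models (beta-logit smooth models and zero-truncated
    count mixed models with AIC family selection and drop-one likelihood-ratio
    tests). A synthetic cohort generator with known diversity-begets-diversity,
    ecological-controls and Black-Queen ground truth supports end-to-end
    testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    mgcv,
    glmmTMB,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
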