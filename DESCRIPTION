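Package: pollinet
Title: Partner Traits of Generalized and Specialized Species in
    Quantitative Flower-Visitation Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds quantitative plant-pollinator interaction networks
    from timed focal-census and flower-density survey tables, computes
    species-level specialization indices (linkage level L and the
    Shannon-based complementary specialization d'), classifies the most
    generalized, specialized, opportunistic and selective species per
    community, and characterizes their interaction partners by abundance
    evenness (Pielou J'), rank abundance and functional richness.
    Partner traits are compared between specificity categories and across
    monthly network snapshots with linear mixed models and multiplicity-
    adjusted contrasts, or with a stratified permutation test.  A
    synthetic community generator with planted interaction archetypes
    provides ground truth for every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    multcomp,
    rlang,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
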