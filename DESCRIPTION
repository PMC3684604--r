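Package: tridomain
Title: Cross-Domain Gut Microbiome and Diet Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An analysis toolkit for multi-domain (bacterial, archaeal, fungal)
    marker-gene surveys of the human gut and their relationship with diet.
    Provides strict readers for genus-by-sample count tables and ranked
    taxonomies; the inclusion filters and within-amplicon proportion transform
    used for such surveys; taxonomy-derived trees with unweighted, weighted and
    generalized UniFrac sample distances; distance-based permutation MANOVA
    (PERMANOVA) and a joint-permutation multi-distance omnibus (PermanovaG);
    Dice-index co-occurrence with Ward ordering; archaeal-status group tests
    (Kruskal-Wallis with Dunn post hoc), Spearman correlation screens and
    Benjamini-Hochberg FDR tiers; nutrient-inventory dimension reduction into
    per-cluster first-principal-component scores (nutrient cluster
    measurements) with a PERMANOVA screen and post hoc correlations; and a
    seeded synthetic cohort generator reproducing the statistical structure of
    a 96-sample three-domain stool survey for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    vegan,
    mclust,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
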