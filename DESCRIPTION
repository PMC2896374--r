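Package: edphylo
Title: Phylogenetic Comparative Analysis of Embryonic Developmental Period in Auks and Penguins
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for a phylogenetic comparative analysis of embryonic
    developmental period (EDP) in the marine bird families Alcidae (auks)
    and Spheniscidae (penguins). Computes allometric EDP residuals from
    egg mass via the Charadriiform power law, builds majority-rule
    consensus trees from posterior tree samples, and fits
    maximum-likelihood phylogenetic generalized least squares (PGLS)
    regressions with Pagel's lambda. Includes a seeded synthetic-data
    module (Yule trees, Brownian-motion traits, binary/ordinal
    predictors) used for parameter-recovery and calibration studies, and
    an end-to-end pipeline reproducing the published regression of EDP
    residuals on clutch size, foraging habitat, activity pattern and
    nest type.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape (>= 5.0),
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    nlme,
    MASS,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
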