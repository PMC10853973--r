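Package: glycoCE
Title: Collision-Energy Optimization for N-Glycopeptide Identification
Version: 0.1.0
Authors@R:
    person("glycoCE", "Maintainers", email = "maintainers@glycoce.org",
           role = c("aut", "cre"))
Description: Tools to determine optimal collision energies (CE) for
    N-glycopeptide tandem mass spectrometry from CE-resolved search-engine
    score tables. Extracts per-species optimal CE as the center of a
    Gaussian fitted to score-versus-energy curves, models its dependence
    on structural features (m/z, hydrophobicity, mobile protons, glycan
    mass, sialylation) per score channel via general linear models and
    lasso regression, and quantifies the identification-score gain of a
    multivariate smart CE choice over the classical m/z-only rule. A
    synthetic-data module simulates the whole CE sweep experiment so the
    pipeline is fully testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
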