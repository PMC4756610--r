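Package: rotafit
Title: Automatic Side-Chain Rebuilding into Electron Density
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic modeling of amino-acid side-chain conformations into
    real-space electron density on a fixed protein backbone. Combines a
    three-term energy function (density fit, rotamer frequency, nonbonded
    interactions), a hierarchically clustered conformer library with
    level cuts and local expansion, and a three-stage search: independent
    lazy-clash fitting, A*-based collision resolution aware of
    crystallographic symmetry, and a full dead-end-elimination cycle
    (Goldstein, split, magic-bullet and pairs criteria) with exact A*
    resolution of residual interaction clusters. Includes a synthetic
    fixture generator (models, maps, libraries), perturbation test sets
    and accuracy/validation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
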