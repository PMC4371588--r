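Package: lgcpower
Title: Power-Equivalent Design and Power Analysis for Linear Latent Growth
    Curve Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computer-aided design of longitudinal studies based on linear
    latent growth curve models (LGCM). Computes the effective error of the
    slope-variance likelihood-ratio test together with the reliability and
    effect-size indices ECR (effective curve reliability), GRR (growth rate
    reliability) and GCR (growth curve reliability); generates
    power-equivalent alternative designs by computer-adjusting a single
    design parameter so that effective errors match; traces iso-power curves
    over pairs of design parameters; fits linear LGCMs by maximum likelihood
    from raw data or sufficient statistics; and estimates statistical power
    to detect slope variance both analytically (noncentral chi-square
    approximation) and by Monte Carlo simulation, including sample-size
    solving. A command-line interface exposes all operations on
    human-editable design configuration files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
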