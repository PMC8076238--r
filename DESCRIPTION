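Package: skindrs
Title: Diffuse Reflectance Spectroscopy Analysis of Skin Water Bonding
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for near-infrared diffuse reflectance
    spectroscopy (DRS) of skin with a two-separation fiber probe. Provides a
    Monte Carlo photon-transport forward model of the probe on a homogeneous
    semi-infinite turbid medium with white-Monte-Carlo path recording, a
    reflectance lookup database over an optical-property grid, a feed-forward
    neural-network inverse model recovering absorption and reduced-scattering
    spectra from two-separation reflectance, a pure-water fitting-residual
    statistic quantifying bound-water spectral perturbation at the 970 nm and
    1230-1380 nm water overtone bands, scattering power-law fits, one-way
    ANOVA with Scheffe post-hoc tests, and a synthetic psoriasis/normal
    cohort generator that exercises the full pipeline end-to-end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
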