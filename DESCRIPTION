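Package: sascontrast
Title: Contrast-Variation Small-Angle Scattering Analysis of Core-Shell Nanoparticles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing small-angle X-ray and neutron scattering (SAXS/SANS)
    data from core-shell nanoparticles such as lipid nanocapsules. Computes neutron
    and X-ray scattering length densities from chemical compositions, builds
    H2O/D2O contrast series and contrast-match points, evaluates the absolute-scale
    polydisperse core-shell sphere form factor with optional Percus-Yevick
    hard-sphere structure factor and Gaussian Q-resolution smearing, performs
    Guinier and regularized indirect Fourier transform p(r) analysis, and fits one
    structural model simultaneously to multiple solvent/core contrasts with fixed
    computed SLDs, inferring shell hydration from the fitted shell SLD. Includes a
    synthetic-data generator emulating a four-contrast SANS design plus SAXS
    measurements so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    lhs,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
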