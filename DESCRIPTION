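Package: otomech
Title: Middle-Ear Biomechanics: Finite-Element Umbo Response and
    Vibrometry-Style Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Harmonic structural finite-element modelling of an idealized
    human middle ear (conical tympanic membrane as flat-facet shell
    elements, ossicular chain as solid tetrahedra, ligaments and cochlear
    load as spring-damper connectors) producing the umbo displacement
    transfer function (UDTF), together with the measurement-side tooling
    used to validate such models: one-third-octave pure-tone schedules,
    SPL/pressure conversion, velocity-to-displacement conversion,
    log-normal population statistics of transfer-function magnitudes, a
    synthetic-subject generator with log-normal inter-subject variability,
    and model-versus-measurement comparison with a divergence-band
    estimate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
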