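Package: faded
Title: FRET-Induced Angular Displacement Evaluation via Dim Donor
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for quantifying donor-acceptor angular displacement from
    sensitized-acceptor fluorescence anisotropy (FADED). Covers time-correlated
    single-photon-counting (TCSPC) decay fitting with instrument-response
    reconvolution, closed-form FRET and photophysical arithmetic, steady-state
    and time-resolved anisotropy with G-factor and high-NA corrections, the
    Perrin equation and dipole-angle inversion, donor bleed-through
    compensation, linear spectral unmixing of donor and acceptor emission,
    Hill calibration of anisotropy-based Ca2+ sensors, polarized two-channel
    image-stack analysis with intensity-modulated display rendering, and
    seed-deterministic synthetic-data generators for every input kind.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    minpack.lm,
    pracma,
    jsonlite,
    tiff,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
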