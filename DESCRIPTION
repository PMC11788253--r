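Package: trfd
Title: Time-Resolved Film Dosimetry for FLASH Proton Therapy Verification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-specific pre-treatment verification of pencil-beam-scanning
    (PBS) FLASH proton therapy from time-resolved radiochromic film footage.
    Converts high-speed camera frame stacks of film coloration into per-pixel
    dose-accumulation-over-time curves (transmission densitometry and a fitted
    optical-density-to-dose calibration), corrects the post-irradiation
    coloration effect by deconvolving a logarithmic film-response kernel,
    extracts per-pixel delta-t and PBS dose-rate maps (Folkerts definition),
    simulates PBS delivery from plain-text spot lists, and compares measurement
    to simulation with a local 2D gamma evaluation. A synthetic-footage forward
    model (coloration kinetics, 8-bit quantization, pixel noise) supports
    end-to-end validation without camera hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    png,
    rlang,
    stats,
    tibble,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
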