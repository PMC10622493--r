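Package: mfir
Title: Multifractal Analysis of Mid-Infrared Absorbance Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Converts attenuated total reflection Fourier-transform
    infrared (ATR-FTIR) absorbance spectra into axis-free binary trace
    images and estimates their multifractal spectra by box counting:
    mass exponents tau(Q), generalized (Renyi) dimensions D(Q), and the
    singularity spectrum f(alpha) via both the direct (Chhabra-Jensen)
    estimator and the Legendre transform. The spectrum is reduced to a
    scalar multifractal number (by default the singularity-spectrum
    width delta-alpha) used to rank samples, test concentration
    invariance, and track the cancer-cell fraction of mixed populations.
    Includes exact multiplicative-cascade generators with closed-form
    spectra for estimator verification, a synthetic FTIR spectrum
    generator with tunable cascade roughness, group-comparison and
    dose-response summaries, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
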