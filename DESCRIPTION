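Package: hfbdecode
Title: Decoding Articulator Movements from High-Density ECoG
    High-Frequency-Band Activity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Template-matching decoding of cued articulator and tongue
    movements from high-density electrocorticography (ECoG) grids over
    sensorimotor cortex. Provides a synthetic high-density ECoG generator
    (1/f background, line noise, spatially clustered high-frequency-band
    responses), preprocessing (bad-channel screening, zero-phase notch
    filtering, common-average re-referencing), Gabor-wavelet 60-130 Hz
    log-power envelopes, permutation-based electrode responsiveness with
    false-discovery-rate control, spatial and spatio-temporal template
    matching with stratified k-fold and leave-one-trial-out
    cross-validation, random-search electrode-importance mapping with a
    convergence diagnostic, searchlight accuracy-by-grid-size analysis
    with minimal-area estimation, and winner-takes-all topographic maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    signal,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
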