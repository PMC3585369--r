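Package: tacsim
Title: Biophysical Simulation of Scalp EEG Under Transcranial Current
    Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end simulation of scalp EEG under transcranial direct
    and alternating current stimulation (tDCS/tACS). A quasi-static
    multi-shell spherical volume conductor maps scalp stimulation pads to
    a cortical electric-field distribution; the field component normal to
    the cortical surface perturbs the pyramidal cells of a network of
    coupled neural mass populations generating alpha-band activity; the
    resulting regional dynamics are projected through an analytic
    three-shell spherical leadfield to scalp electrodes and analysed for
    alpha-band power changes across stimulation conditions. Includes
    spherical head and cortical mesh synthesis, region parcellation,
    standard 10-20/10-10 electrode layouts, periodogram band-power
    analysis, calibration of the field-to-membrane coupling constant, and
    tACS frequency sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    Matrix
Config/testthat/edition: 3
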