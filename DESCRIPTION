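Package: calins
Title: Classification and Modelling of Single-Neuron Calcium Responses to
    Infrared Neural Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-photon calcium imaging recordings made
    during pulsed infrared neural stimulation (INS). Converts raw ROI
    fluorescence traces to dF/F0, classifies neurons into positive and
    negative responders with a correlation index against the top-intensity
    mean response, computes pulse-train peak-to-peak amplitudes and 3-10 s
    peak areas, fits the intensity dependence of the correlation index, runs
    a voxel-grid Monte Carlo simulation of 1875 nm light from an angled
    multimode fiber through ACSF, coverglass and cortex to delineate the
    illuminated region, and combines excitatory and inhibitory cohort means
    into an 80/20 weighted population time course. Includes a seeded
    synthetic-data generator emulating the stimulation paradigms so the full
    pipeline is testable without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
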