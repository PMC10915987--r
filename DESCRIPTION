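Package: ctsim
Title: Conductance-Based Corticothalamic Sleep-Wave Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a single cortical column (six excitatory and inhibitory
    cell types across four layers) reciprocally coupled to first- and
    higher-order thalamic nuclei and their reticular (NRT) sectors, using
    Hodgkin-Huxley conductance-based neuron models with T-type calcium burst
    machinery, persistent sodium, calcium- and sodium-activated potassium
    currents and a potassium leak conductance (g_KL) that acts as the
    neuromodulatory sleep-wake dial. Includes an EEG estimator from
    transmembrane currents, up/down-state segmentation, spectral and
    cross-correlation analyses, and scripted protocols in which wake-like
    desynchronization, sleep spindles, slow (<1 Hz) and delta oscillations
    emerge from changes in g_KL alone.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
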