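Package: babblesim
Title: Spiking-Network Simulation of Canonical Babbling Acquisition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the acquisition of syllabic (canonical) babbling by a
    spiking neural network coupled to a surrogate vocal tract. A recurrent
    Izhikevich reservoir drives agonist and antagonist motor pools that control
    jaw and lip closure; vocalizations are scored for auditory salience, and
    above-threshold salience triggers dopamine release that gates
    spike-timing-dependent potentiation of the reservoir-to-motor synapses.
    Includes the adaptive reward threshold, yoked-control reward replay,
    syllable-nucleus counting, and an analysis suite for learning curves,
    muscle-activity statistics, and synaptic-weight summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
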