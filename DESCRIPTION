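Package: pfspike
Title: Branch-Specific Dendritic Calcium Spikes in a Reduced Purkinje Cell Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale biophysical model of parallel-fiber evoked dendritic
    calcium spikes in cerebellar Purkinje cells. Provides a parametric reduced
    morphology (soma, axon initial segment, three main dendritic limbs and 22
    spiny branches), Hodgkin-Huxley style membrane mechanisms with a
    submembrane calcium pool, an implicit branched cable solver with ideal
    waveform clamp, generators for clustered parallel-fiber input,
    feed-forward stellate inhibition and Poisson background bombardment, and
    the protocol/analysis battery used to characterise branch excitability:
    input-output curves with step-detection of spike thresholds, somatopetal
    attenuation profiles, source/sink ratios from axial currents, and
    peristimulus time histogram burst-pause statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    stats,
    graphics,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
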