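Package: v1net
Title: Spiking Network Model of Orientation Hypercolumns in Macaque V1 Layer 4Calpha
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and simulates a biologically constrained, conductance-based
    integrate-and-fire network model of the magnocellular input layer 4Calpha of
    macaque primary visual cortex. The model comprises a sparse ON/OFF LGN mosaic
    acting as a spatiotemporal filter bank on drifting-grating stimuli, a pinwheel
    hypercolumn sheet of excitatory and inhibitory neurons wired with
    distance-dependent Gaussian connection probabilities, a rate-indexed layer 6
    feedback population, and short-term synaptic dynamics (inhibitory synaptic
    depression, feedback facilitation, spike-threshold adaptation). An analysis
    suite computes contrast-response functions, orientation and spatial-frequency
    tuning, selectivity indices, pixelised cortical activity maps and gamma-band
    population spectra from recorded spike trains.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
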