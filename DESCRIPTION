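Package: tacsnet
Title: Spiking Brain-Network Simulation of Transcranial Alternating
    Current Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico pipeline for studying how transcranial
    alternating current stimulation (tACS) entrains cortical rhythms.
    Projects an electric field onto folded white/gray-matter surface
    meshes to obtain per-region distributions of the field component
    normal to the pyramidal-cell axis, drives multi-region networks of
    adaptive exponential integrate-and-fire neurons with heterogeneous
    sinusoidal currents sampled from those distributions, and quantifies
    entrainment regimes (Arnold tongues, 2:1 synchronization), alpha-band
    power changes, stimulation-intensity calibration, and the predictors
    of stimulation efficacy via robust regression. Includes generators
    for all synthetic inputs (gyrified meshes, uniform fields, log-normal
    connectomes, target phase-locking-value matrices, and prototypical
    amplitude distributions), so the full pipeline runs without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    MASS,
    signal,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
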