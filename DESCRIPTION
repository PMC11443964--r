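Package: condegen
Title: Decomposing Ion-Channel Degeneracy in Conductance-Based Neuron Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to study degeneracy in single-compartment conductance-based
    neuron models. Simulates a crab stomatogastric-ganglion (STG) burster and a
    midbrain dopaminergic (DA) pacemaker from declarative model-definition
    files, computes dynamic input conductances (fast/slow/ultraslow) and their
    sensitivity matrix in maximal-conductance space, generates degenerate
    neuron populations either by random sampling with electrophysiological
    post-processing or by a fast DIC-constrained algorithm, decomposes the
    resulting conductance variability into homogeneous scaling and degenerate
    conductance ratios (PCA, correlation graphs, total-least-squares
    directions, input-resistance normalization), and implements a reliable
    neuromodulation rule that retunes the slow dynamic input conductance at
    fixed ultraslow value.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
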