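Package: corticonn
Title: Stochastic Generation and Analysis of Long-Range Cortical
    Micro-Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Turns mesoscale constraints on cortical long-range connectivity
    (region-to-region projection strength matrices, laminar synapse-density
    profiles, voxelized projection tensors, and single-axon region-innervation
    statistics) into stochastic instances of a neuron-to-neuron connectome.
    Provides volumetric synapse-density budgeting with a strength cutoff,
    assignment of prototype layer profiles, barycentric topographic mapping
    between flattened cortical areas, a tree-based generative model of
    single-axon projection types fitted by a community-detection sweep and
    local least-squares, connectome instantiation onto neuron and dendritic
    segment tables, and micro-structure analyses (reciprocal-connectivity
    overexpression, cross-region triplet motifs, module edge-density
    distributions against degree-preserving controls). A synthetic-fixture
    generator with planted ground truth emulates every required input at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    MASS,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
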