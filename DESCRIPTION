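Package: lifsorn
Title: Self-Organizing Spiking Network Model of Sequence Learning in Visual Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates a self-organizing recurrent network (SORN) of noisy
    conductance-based leaky integrate-and-fire neurons on a two-dimensional
    cortical sheet, with five interacting plasticity mechanisms acting on the
    recurrent excitatory synapses: short-term plasticity, nearest-neighbour
    exponential spike-timing dependent plasticity, synaptic normalization with
    boundary correction, structural growth and pruning, and intrinsic
    threshold plasticity. Includes a moving-spot stimulus model of a
    sequence-learning experiment in rodent primary visual cortex, the
    experiment protocol (growth, test, training and relaxation phases,
    multi-electrode-style recording clusters), and an analysis layer
    quantifying cue-triggered sequence replay by rank correlation of cluster
    firing times, stimulus-induced connectivity restructuring, spontaneous
    activity transition structure, recall speed, and persistence of the
    training effect. The integration loop is implemented in C++ via Rcpp;
    all results are returned as tidy tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
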