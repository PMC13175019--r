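Package: kv4rebound
Title: Kv4.3-Dependent Rebound Delays in Dopamine Neurons and Learning from
    Negative Reward Prediction Errors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Conductance-based single-compartment modelling of atypical
    (nucleus accumbens core-projecting) midbrain dopamine neurons with a
    dual-inactivation Kv4.3 A-type potassium current, in which the fraction
    of slowly inactivating channels reflects KChIP4a auxiliary-subunit
    binding. Provides current-clamp stimulation protocols (post-inhibitory
    rebound delay, depth and duration sweeps), simulated voltage-clamp
    characterisation (open-state inactivation, recovery from inactivation),
    an in-vivo-like balanced synaptic state with Poisson excitation and
    inhibition plus correlated inhibitory trains, peristimulus time
    histograms and the percent-spikes-lost statistic. Also implements a
    dual-learning-rate Rescorla-Wagner model of appetitive acquisition and
    extinction with least-absolute-residual fitting and parameter-recovery
    benchmarking, task-mechanics utilities (reward-cycle accounting,
    spontaneous-alternation chance level, discrimination index), label-free
    proteomic stoichiometry normalisation for Kv4 channel complexes, and
    seed-deterministic synthetic-data generators for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
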