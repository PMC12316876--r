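Package: bcpnnet
Title: Spiking Attractor Networks with Bayesian-Hebbian Plasticity for
    Item-in-Context Episodic Memory Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clock-driven simulation of coupled cortical attractor memory
    networks built from adaptive exponential integrate-and-fire neurons,
    conductance-based AMPA/NMDA/GABA synapses with Tsodyks-Markram
    short-term augmentation and depression, and spike-based BCPNN
    (Bayesian Confidence Propagation Neural Network) synaptic plasticity
    with reward-gated eligibility traces.  Includes a two-network
    (item/context) model builder with hypercolumnar layout and distance
    dependent conduction delays, generators for item-in-context task
    schedules (recency arrangements, unbalanced training, extra context,
    reverse rewarding), an experiment driver, and analysis utilities for
    firing rates, recall performance and pairwise synaptic-trace
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
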