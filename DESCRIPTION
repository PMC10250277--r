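Package: planscope
Title: Inferring Planning Strategies from Mouselab-MDP Process-Tracing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A model-based "computational microscope" for measuring which
    planning strategy a person used on each trial of a Mouselab-MDP
    process-tracing experiment. Planning strategies are modelled as
    stochastic click policies whose propensities are a softmax over a bank
    of belief-state features; the trial-by-trial strategy sequence is
    treated as a hidden Markov chain with a sticky (abrupt-switch) prior
    and decoded by the Viterbi algorithm. The package also provides the
    surrounding machinery: a headless simulator for Mouselab-MDP planning
    environments, a registry of generative planning strategies, maximum
    likelihood fitting of strategy weight vectors, symmetrised
    Kullback-Leibler strategy distances with Ward clustering into strategy
    types, a decomposition of each strategy into the relative influence of
    five decision systems, and simulation studies that quantify how
    accurately strategies, strategy types, and decision-system trends are
    recovered from click data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
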