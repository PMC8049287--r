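Package: rewardnet
Title: Entropy-Regularised Reinforcement Learning and Reward Inference
    for Binary Recurrent Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for optimising the dynamics of binary recurrent
    neural networks by entropy-regularised, average-reward reinforcement
    learning, and for inverting that optimisation: inferring the reward
    function a network optimises from its observed spiking dynamics.
    Provides exact tabular solvers for KL-regularised Markov decision
    processes, asynchronous binary-network optimisation and simulation,
    closed-form and likelihood-based reward inference, an efficient-coding
    loop that discovers the stimulus feature a population encodes, and a
    scalable pairwise-Ising (quadratic value) track with sparse, pairwise
    and global parametric reward models, plus generators for the standard
    benchmark environments (maze navigation, two-level spike-count coding,
    binary pixel stimuli, ring attractors).
License: MIT
Encoding: UTF-8
Imports:
    boot,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
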