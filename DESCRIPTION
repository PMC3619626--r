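Package: pigexplore
Title: Learning-Driven Exploration in Controllable Markov Chains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation framework for studying curiosity-driven (reward-free)
    exploration by embodied agents in Controllable Markov Chains (CMCs).
    Agents maintain Bayesian internal models of the transition kernel, score
    candidate actions by the predicted information gain (PIG) of one more
    observation, and coordinate actions over time with finite-horizon value
    iteration.  The package generates three classes of synthetic worlds
    (dense random kernels, noisy mazes with transporters and an absorbing
    state, and discrete-support "1-2-3" worlds), implements a family of
    exploration strategies (random action, unembodied control, greedy and
    value-iterated PIG, predicted mode change, predicted L1 change,
    least-taken-action, counter-based, and Q-learning on surprise), measures
    learning by missing information (summed Kullback-Leibler divergence of
    the model from the world), quantifies world structure (equilibrium state
    bias, controllability, mean path length), and evaluates the generalized
    utility of learned models on navigation and reward-gathering tasks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
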