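Package: protentia
Title: Multi-Agent Active Inference with Polynomial Interfaces and Sheaf Consensus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete active inference for ensembles of agents that model one
    another. Provides finite categorical probability primitives; a finite
    polynomial-functor algebra (tensor, hom polynomials, morphism enumeration)
    for agent interfaces and Markov blankets; a POMDP engine with variational
    and expected free energy (risk/ambiguity and information-gain/value
    decompositions) and softmax action selection; a multi-agent simulator over
    joint interfaces with recursive action prediction and generalized-synchrony
    metrics; and a cellular-sheaf layer for world models over a shared base
    space, with gluing checks, disagreement obstructions, and mean-diffusion
    consensus dynamics. Includes seeded scenario generators (random generative
    models, a T-maze epistemic-foraging task, shared-world covers with
    controllable disagreement), JSON/CSV serialization, and a command-line
    entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
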