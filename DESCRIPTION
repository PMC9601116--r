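Package: politeia
Title: Transfer Entropy, Cognitive Architectures, and the Consensus
    Problem in Agent Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how an agent's cognitive architecture -- the
    number of past snapshots it stores and the interval at which it samples --
    shapes the direction of information flow it infers between two coupled
    environmental stimuli.  Implements an exactly solvable two-process
    stochastic environment (a driftless centre-of-mass diffusion coupled to an
    Ornstein-Uhlenbeck separation), closed-form Gaussian transfer entropy and
    the normalized influence statistic as functions of memory size and
    sampling interval, plug-in Gaussian estimators for empirical series,
    populations of heterogeneous agents whose per-agent estimates are pooled
    into belief distributions, and a bootstrap pipeline for paired monthly
    time series with detrending and harmonic removal.  Includes synthetic-data
    generators so every analysis stage can be exercised with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
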