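Package: lickbench
Title: Simulation and Analysis of Head-Fixed Rodent Licking Tasks
Version: 0.1.0
Authors@R: person("Lick", "Bench", email = "maintainer@lickbench.org",
    role = c("aut", "cre"))
Description: A hardware-free task engine for head-fixed rodent behavior.
    Implements the two-alternative forced-choice (2AFC), Go-NoGo and
    passive-stimulation state machines on a virtual clock, with trial
    schedulers (constrained side randomization, delay tables sampled
    without replacement, truncated-exponential intertrial intervals), a
    stochastic virtual subject parameterized by a four-parameter
    psychometric function, LED-matrix and tone stimulus renderers, a
    bit-exact session log and settings store, the three-byte device
    command codec, lick debouncing, DAQ-style multichannel traces, and
    the standard behavioral statistics: psychometric curve fitting by
    binomial maximum likelihood, d-prime, learning curves and
    stage-advancement criteria.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
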