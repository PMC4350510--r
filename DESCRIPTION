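Package: prtsim
Title: Simulation and Analysis of the Probabilistic Reward Task with
    Genotype Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for simulating and analysing the probabilistic reward
    task, a line-discrimination paradigm with asymmetric reinforcement used
    to measure reward responsiveness via signal-detection response bias.
    Generates constrained pseudo-random reinforcement schedules, runs
    sessions against programmable responder agents (including a
    drifting-criterion signal-detection learner), scores response bias and
    discriminability per block, and provides the statistical toolkit for
    candidate-gene association studies of task behaviour: Hardy-Weinberg
    and contingency chi-square tests, one-way and mixed repeated-measures
    ANOVA/ANCOVA with partial eta squared, additive and dominant genotype
    codings, t-tests, Cohen's d, Bonferroni-corrected contrasts, and
    noncentral-t power analysis. A synthetic-cohort generator calibrated to
    genotype-graded reward-learning effects allows the full pipeline to run
    end to end without human data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
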