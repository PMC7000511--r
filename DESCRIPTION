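Package: piddm
Title: Diffusion Decision Modelling of Proactive Interference in the
    Recent-Probes Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study proactive interference in short-term memory with
    the diffusion decision model (DDM). Generates recent-probes task trial
    sequences under the task's recency constraints, simulates trial-level
    behaviour from the full DDM (intertrial variability in drift rate,
    starting point and nondecision time), evaluates exact first-passage-time
    densities and likelihoods, fits six constrained model variants per
    participant by maximum likelihood with a simplex search, selects among
    them with the Bayesian information criterion, and runs the group-level
    statistics (mixed repeated-measures ANOVA, planned interference
    contrasts, independent t-tests) comparing young and older adults,
    together with quantile-probability fit diagnostics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    pracma,
    yaml,
    tibble,
    dplyr,
    tidyr,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
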