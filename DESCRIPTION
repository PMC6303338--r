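Package: phylochron
Title: Chronogram Comparison, Fossil Calibration Priors, and
    Diversification-Shift Detection
Version: 0.1.0
Authors@R:
    person("phylochron", "developers", email = "phylochron@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing independently dated time-calibrated
    phylogenies (chronograms). Reads posterior samples of ultrametric trees
    (Newick or NEXUS with translate tables), extracts crown and stem node-age
    posteriors for named clades with explicit burn-in handling, and estimates
    posterior distributions of node-age differences between two trees by
    Gaussian kernel density estimation and paired Monte Carlo resampling,
    with highest-posterior-density intervals and interval probabilities over
    user-chosen age-difference ranges. Constructs fossil calibration priors
    (offset-lognormal, truncated-normal, uniform) from stratigraphic minimum
    ages, and applies a support-threshold rule for placing calibrations on
    annotated trees. Detects exceptional diversification-rate shifts on
    richness-annotated backbone trees via constant-rate birth-death
    likelihoods with terminally unresolved clades and stepwise AICc model
    selection. Includes birth-death tree and pseudo-posterior simulators so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
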