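---
title: "Methods: comparing chronologies and detecting diversification shifts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing chronologies and detecting diversification shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylochron)
```

## The problem

Two groups of organisms — say land plants and fungi — are dated in two
*independent* Bayesian analyses, each producing a posterior sample of
time-calibrated ultrametric trees (chronograms, branch lengths in millions of
years, Ma/My). Questions such as "did the fungal event precede the plant
event, and by how much?" are questions about the distribution of a
*difference of node ages across two posteriors that share no joint MCMC
state*. `phylochron` implements that comparison, the construction of the
fossil calibration priors such analyses use, and a richness-aware
birth–death test for exceptional diversification-rate shifts on the dated
trees. A simulation module generates every input from scratch, so the whole
pipeline is testable without any external data.

## Node-age extraction

A clade is a named taxon set with a mode: `crown` (age of the MRCA of the
taxa) or `stem` (age of the MRCA's parent, i.e. the split from the sister
lineage). Ages are measured backward from the present; tips are age 0.

Burn-in is applied **per input file before concatenation**
(`floor(burnin_fraction * n)` trees dropped from the head of each file),
mirroring per-run MCMC burn-in followed by combining runs. Trees must share
a taxon set and be rooted; non-ultrametric trees beyond a relative tolerance
(`rtol`, default 1e-6 of the root age) are rejected unless `relax = TRUE`,
which normalizes by the mean root-to-tip path — rejection is the default
because silently normalizing hides dating errors.

Two monophyly policies: `mrca` (default) records the MRCA age in every tree,
degrading gracefully when the taxa are non-monophyletic (the MRCA then
subtends extra tips); `strict` skips non-monophyletic trees and records the
skip count. In analyses where calibrated clades were constrained to be
monophyletic the two coincide.

## Fossil calibration priors

Fossil minimum ages are `stage_lower_bound − margin`, computed on
decimal-scaled integers at 0.1 My resolution so printed values (e.g.
407.0 − 2.8 = 404.2) are reproduced exactly, free of binary floating-point
residue.

Three prior families with density and sampling contracts:

* **Offset-lognormal**: a hard minimum at the fossil age plus a lognormal on
  the exceedance, with `mu = ln(expected_fraction * fossil_age) − sigma²/2`
  so the analytic mean exceedance is exactly `expected_fraction * fossil_age`
  (defaults: 5% and `sigma = 0.75`). "Expected age" is read as the expected
  *exceedance* beyond the hard minimum — the only reading under which a
  minimum age and a lognormal prior coexist.
* **Truncated normal**: a normal on node age renormalized over
  `[min_age, ∞)`. The normal components are user inputs; calibration tables
  only derive the minima.
* **Uniform** on `[young, old]`.

`place_calibration()` implements the placement rule: start at the MRCA of
the fossil's taxon group and walk rootward to the first node with posterior
probability ≥ 0.95 **and** bootstrap ≥ 0.70 (both configurable). Raising the
thresholds can only move the chosen node rootward (tested as a property).

## Comparing two node-age posteriors

For each posterior a Gaussian kernel density estimate is fitted
(`kde_fit()`); the default bandwidth is Scott's rule, `sd * n^(−1/5)`,
matching the default of the standard scientific-Python KDE. Because the KDE
is a Gaussian mixture, its CDF is available in closed form, so interval
masses are exact integrals of the fitted density (no quadrature).

`difference_distribution()` draws `n` (default 100,000) independent ages from
each fitted density and takes elementwise differences `a − b`; positive
values mean the `a` event (by convention the fungal one) is older. Resampling
from the KDEs — rather than pairing raw MCMC draws — is the default because
the two chains are independent and of unequal length; `paired_raw = TRUE`
offers a sensitivity check that subsamples `min(nA, nB)` raw draws. Sub-seeds
for the two streams are derived from the root seed and each side's *label*
only, so swapping the labels negates the draws exactly and summaries are
bit-reproducible for a fixed seed.

Summaries (`summarize_comparison()`):

* median and mean difference;
* the 95% highest-posterior-density interval, computed by the Chen–Shao
  shortest-interval scan over sorted draws (`ceiling(mass*n)` consecutive
  order statistics; ties broken toward the smallest lower endpoint) —
  verified against an exhaustive search oracle;
* `P(a older)` = fraction of positive draws;
* interval probabilities for ranges of 1, 5, 10, 20, 40, 60 My. A "range"
  of `r` My is by default the **total width centered at zero**
  (`[−r/2, +r/2]`): the only symmetric reading that treats the two kingdoms
  exchangeably. `one_sided` (`[0, r]`) and `half_width` (`[−r, +r]`)
  semantics are selectable because the original description does not pin
  this down.

Smoothing bias: KDE resampling inflates the difference's spread by the two
squared bandwidths; at `n = 10^5` posterior draws this is a relative variance
inflation of order `n^(−2/5)` (≈1%) and is invisible at the tolerances used
here, but it is why empirical and KDE-integral interval probabilities are
allowed to differ by up to 0.01.

## Birth–death likelihood with terminally unresolved clades

Rates are parameterized as net diversification `r = λ − μ > 0` and relative
extinction `ε = μ/λ ∈ [0, 1)`. With `β(t) = (e^{rt} − 1)/(e^{rt} − ε)`:

* survival of a lineage of age `t`: `Ps(t) = (1−ε) e^{rt} / (e^{rt} − ε)`;
* extant descendants given survival are geometric:
  `P(N = n | survival) = (1−β) β^{n−1}` (the Magallón–Sanderson terminal
  term, `clade_richness_logprob()`);
* exactly one surviving lineage: `p1(t) = Ps(t) (1 − β(t))`.

The reconstructed-tree likelihood factorizes per edge: an edge from age
`t_b` down to `t_e` contributes `log p1(t_b) − log p1(t_e)` (the probability
that a lineage with surviving descendants stays a single reconstructed
lineage over the interval — multiplicative along a lineage, which makes
edge-wise rate classes consistent), each non-root branching contributes
`log λ`, and the whole tree is conditioned on survival of the two root
lineages (`−2 log Ps(root age)`, Nee-style crown conditioning). Pendant
edges either require exactly one extant species (`pendant = "exact1"`, the
fully resolved complete tree) or only survival (`"survival"`), in which case
the geometric richness term supplies the `N = n` statement. With all
richness 1 the two compositions coincide — a regression test. All terms are
evaluated in log space via `log1p(−ε e^{−rt})` forms, stable for large `rt`.

A shift configuration assigns every edge to the class of its most tipward
ancestral shift (class 1 at the root). The likelihood then separates by
class, so per-class `(r, ε)` are optimized independently: bounded
quasi-Newton on `(log r, logit ε)` with 5 seeded multistarts, tolerance
below 1e-8 on the log-likelihood; per class a Yule submodel (`ε = 0`, one
parameter) is fitted alongside and the better local AIC wins.

Model scores use AICc with `k = Σ_class k_class + n_shifts` (each shift
costs one placement parameter) and `n_obs` = internal nodes + terminal
clades; when `n_obs ≤ k + 1` plain AIC is used with a warning.
`stepwise_shift_search()` adds shifts greedily — every non-shift edge is a
candidate, classes affected by a candidate are refitted (unchanged classes
are reused, which is exact because per-class seeds depend only on the class
index) — and accepts while AICc improves by ≥ 4 units, a conventional
strong-evidence cutoff (the source analyses do not state theirs; both the
threshold and max shifts are arguments).

## What the simulators emulate — and what they do not

* `simulate_bd_tree()`: Gillespie birth–death from the two root lineages,
  rejection-conditioned on the stop state (n tips or elapsed time), extinct
  lineages pruned. Under n-tip stopping the present is placed uniformly
  within the interval during which exactly n lineages exist, so pendant
  branches are positive. Rejection conditioning is deliberately *not* the
  analytic conditioning used by the likelihood — the simulator must stay an
  independent oracle.
* `simulate_clade_size()`: direct event simulation of one lineage's extant
  descendants, resimulated on extinction; the Monte Carlo oracle for the
  geometric richness law.
* `simulate_pseudo_posterior()`: a stand-in for MCMC output with known
  truth — one tree-wide scale factor `s ~ LogNormal(−cv²/2, cv)` (unit mean)
  plus root-to-tip node-age jitter, each age resampled uniformly in a
  symmetric window of half-width
  `min(cv·age, parent − age, age − oldest child)`. Symmetry keeps each age
  conditionally unbiased; clipping guarantees parent-older-than-child. It is
  **not** an MCMC: replicates are independent, there is no autocorrelation,
  no topological uncertainty, and no calibration-induced skew. A green test
  against it establishes correct mechanics of extraction and comparison, not
  robustness to real posterior pathologies.
* `simulate_shift_scenario()`: the operating-characteristics test bed. It
  simulates the *one-shift birth–death process itself* (a two-class Gillespie
  run: background net rate 0.4/My, pure birth, total depth 6 My; at a stem
  age drawn from the contrast band one lineage switches to 10-fold rates),
  prunes extinct lineages, and collapses every maximal clade younger than a
  cutoff into a richness tip. Node times *and* richness are therefore
  realizations of the shifted model. The scenario is parameterized by the
  expected shifted-to-background tip-richness contrast, drawn log-uniformly
  from 10–300: the lower end of the design band; the upper end is capped at
  300 (rather than 10,000) so full-clade simulation stays desk-sized —
  detection is easier at larger contrasts, so the cap is conservative.
  Acceptance: with no shift, the search returns zero shifts in ≥ 90% of 50
  replicates; with the engineered shift, the true edge or its parent is
  recovered in ≥ 80% (observed ≈ 90%).

## Numerical and design choices

* **Seeds.** Every stochastic function takes an explicit seed and restores
  the caller's RNG state. Pipeline sub-seeds are derived by a stable
  polynomial hash of `(root seed, stage, label)` modulo 2³¹ − 1, so runs are
  byte-identical across sessions and platforms and label swaps mirror
  draws exactly.
* **HPD coverage check.** The calibration experiment draws each replicate's
  posterior centers around the truth with sd equal to the posterior sd (the
  regime in which Bayesian interval coverage is exactly nominal), with
  posterior n = 1500 and 20,000 paired draws — sizes chosen to keep 500
  replicates inside a test-suite budget while leaving Monte Carlo error
  (±1%) well inside the ±3% acceptance band. Observed coverage ≈ 0.95.
* **Degenerate inputs.** Zero-variance samples yield a flagged point-mass
  KDE (sampling returns the constant; CDF is a step); a difference of two
  degenerate posteriors warns rather than fails. `fossil_min_age` refuses
  negative margins and margins exceeding the bound; `stem_age` of the root
  errors; `hpd_interval` requires ≥ 20 draws.
* **Ties.** The HPD scan takes the first minimal window, i.e. the smallest
  lower endpoint; `place_calibration` treats missing support values as
  unsupported; tips count as fully supported (a singleton "clade" is its own
  calibration point).

## Limitations

* The comparison machinery assumes the two posteriors are independent; it
  is not valid for two clades dated in the *same* analysis (their joint
  posterior correlation would be ignored).
* KDE resampling adds bandwidth-scale smoothing; for very small posterior
  samples (n < 100) interval probabilities near sharp features can be
  biased by several percent.
* The shift search is greedy forward AICc: like all stepwise procedures it
  can place a shift on a neighbor of the true edge when the signal
  straddles nodes, and it does not revisit accepted shifts.
* Rate classes are constant in time; no time-varying rates, no fossil
  (non-extant) tips, no Bayesian shift inference.
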