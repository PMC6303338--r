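# phylochron

Tools for comparing independently dated phylogenies and for detecting
exceptional diversification-rate shifts on them.

When two groups of organisms — for example land plants and fungi — are dated
in two *separate* Bayesian analyses, each analysis yields a posterior sample
of chronograms (rooted ultrametric trees, branch lengths in millions of
years). Questions like *"did the fungal event precede the plant event, and
with what probability was the gap smaller than 10 My?"* concern the
distribution of a difference of node ages across two posteriors that share no
joint MCMC state. `phylochron` provides:

* **Node-age extraction** (`read_trees`, `extract_age_posterior`): Newick and
  NEXUS (translate tables, BEAST-style `[&...]` comments) tree samples,
  per-file burn-in, crown/stem ages, monophyly policies, ultrametricity
  checks, TSV age tables.
* **Fossil calibration priors** (`fossil_min_age`, `make_lognormal_prior`,
  `make_truncated_normal_prior`, `make_uniform_prior`, `place_calibration`):
  exact stratigraphic minimum-age arithmetic; an offset-lognormal with
  log-mean `ln(f·a) − σ²/2` so the expected exceedance over the fossil
  minimum `a` is exactly `f·a` (defaults `f = 0.05`, `σ = 0.75`); a
  support-threshold rule (PP ≥ 0.95, bootstrap ≥ 0.70) that walks rootward to
  the first well-supported node.
* **Posterior age comparison** (`difference_distribution`,
  `summarize_comparison`): Gaussian KDE per posterior (Scott's rule),
  100,000 paired Monte Carlo draws, the difference `a − b` (positive = `a`
  older), 95% highest-posterior-density intervals (shortest-interval scan),
  `P(a older)`, and interval probabilities over 1/5/10/20/40/60 My ranges,
  with exact Gaussian-mixture integration.
* **Diversification shifts** (`richness_tree`, `fit_bd`,
  `stepwise_shift_search`): constant-rate birth–death likelihood of the
  reconstructed tree (Nee-style crown conditioning) combined with the
  conditional-geometric probability of each terminally unresolved clade's
  extant richness, `P(N = n | t) = (1 − β)β^{n−1}` with
  `β = (e^{rt} − 1)/(e^{rt} − ε)`; per-class ML fits on `(log r, logit ε)`;
  greedy forward shift search under AICc with a 4-unit acceptance threshold.
* **Simulators** (`simulate_bd_tree`, `simulate_clade_size`,
  `simulate_pseudo_posterior`, `simulate_shift_scenario`,
  `make_richness_tree`, `make_gaussian_age_posteriors`): Gillespie
  birth–death trees, Monte Carlo clade sizes (the independent oracle for the
  richness law), pseudo-posterior tree samples with known truth, and
  one-shift scenarios with terminally collapsed richness tips.

Everything stochastic takes an explicit seed and is byte-reproducible; the
pipeline derives per-stage sub-seeds from one root seed.

## Worked example

```r
library(phylochron)

# 1. simulate a "true" chronogram and two pseudo-posterior samples around it
base <- simulate_bd_tree(1, 0.2, n_tips = 12, seed = 101)
base$edge.length <- base$edge.length * 200   # put the root near 480 Ma
fungi  <- simulate_pseudo_posterior(base, age_cv = 0.08, n_trees = 400, seed = 1)
plants <- simulate_pseudo_posterior(base, age_cv = 0.08, n_trees = 400, seed = 2)

# 2. extract crown-age posteriors for one clade from each sample
taxa <- base$tip.label[descendant_tips(base, mrca_node(base, c("t1", "t4")))]
cl <- clade_definition("focal", taxa, mode = "crown")
post_f <- extract_age_posterior(fungi,  cl)
post_p <- extract_age_posterior(plants, cl)

# 3. compare: difference distribution, HPD, interval probabilities
cmp <- summarize_comparison(post_f, post_p, n = 100000, seed = 42,
                            label_a = "fungal", label_b = "plant")
print(cmp)
#> <comparison fungal - plant>
#>   median diff -0.339 My, mean -0.290 My
#>   95% HPD [-32.772, 32.165], P(a older) = 0.4916
#>   P(|diff| in range): 1 My: 0.024, 5 My: 0.122, 10 My: 0.240, 20 My: 0.457, 40 My: 0.774, 60 My: 0.928
```

Both samples were generated around the *same* chronogram, and the comparison
says exactly that: the median age difference is a fraction of a My, the 95%
HPD of the difference spans roughly ±32 My (the joint dating uncertainty at
this noise level), `P(fungal older) ≈ 0.49`, and the probability that the two
events fall within 10 My of each other is 0.24, rising to 0.93 within 60 My.

```r
# 4. a calibration prior as used in dating
prior <- make_lognormal_prior(fossil_min_age(407.0, 2.8))
print(prior)
#> <calibration prior - offset-lognormal: offset 404.2 Ma, mu 2.72493, sigma 0.75>

# 5. diversification shifts on a richness tree with an engineered shift
sc  <- simulate_shift_scenario(seed = 3)
fit <- stepwise_shift_search(sc$rtree, max_shifts = 2, seed = 3)
print(fit)
#> <bd_shift_fit: 1 shift(s), logL = -78.139, k = 3, AICc = 162.893>
#>   class 1 (yule): r = 0.3476, eps = 0, logL = -46.214
#>   class 2 (yule): r = 3.893, eps = 0, logL = -31.924
fit$shift_edges   # 4  == sc$target_edge: the engineered 10-fold shift, found
```

The search fits the background at `r ≈ 0.35`/My and the shifted clade at
`r ≈ 3.9`/My — the engineered 10-fold contrast — and places the single
accepted shift on the true edge.

The file-level pipeline (`run_config`/`run_compare`, `run_shifts`) writes
TSV outputs with `#`-prefixed provenance headers; a thin command-line
wrapper with `extract-ages`, `compare`, `shifts` and `simulate` subcommands
lives at `inst/cli/phylochron.R`.

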