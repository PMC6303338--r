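# KDE fitting, the difference distribution, interval probabilities, and
# HPD intervals, checked against closed forms and brute-force oracles.

test_that("kde_fit recovers a standard normal density and normalizes", {
  x <- with_seed_local(1, rnorm(1e4))
  k <- kde_fit(x)
  expect_equal(kde_density(k, 0), dnorm(0), tolerance = 0.02 / dnorm(0))
  # closed-form CDF spans the full mass
  expect_equal(kde_cdf(k, max(x) + 5 * k$bw) - kde_cdf(k, min(x) - 5 * k$bw), 1,
               tolerance = 1e-3)
  expect_equal(k$bw, sd(x) * 1e4^(-1 / 5), tolerance = 1e-12)  # Scott's rule
  ks <- kde_fit(x, rule = "silverman")
  expect_equal(ks$bw, 0.9 * min(sd(x), IQR(x) / 1.34) * 1e4^(-1 / 5),
               tolerance = 1e-12)
})

test_that("degenerate samples give a flagged point mass", {
  k <- kde_fit(rep(5, 100))
  expect_true(k$degenerate)
  expect_identical(kde_density(k, 5), Inf)
  expect_identical(kde_density(k, 4), 0)
  expect_identical(kde_cdf(k, c(4, 5, 6)), c(0, 1, 1))
  expect_identical(unique(kde_sample(k, 50, seed = 1)), 5)
  expect_error(kde_fit(numeric(0)), "non-empty")
})

test_that("difference distribution matches the difference-of-normals closed form", {
  ap <- make_gaussian_age_posteriors(
    data.frame(label = c("a", "b"), mean = c(484, 482), sd = c(23, 3), n = 1e4),
    seed = 3)
  d <- difference_distribution(ap$a, ap$b, n = 5e4, seed = 9)
  expect_identical(d$n_draws, 50000L)
  expect_equal(mean(d$draws), 2, tolerance = 0.5)       # true sd/sqrt(n) margins
  expect_equal(mean(d$draws > 0), pnorm(2 / sqrt(23^2 + 3^2)), tolerance = 0.02)
  # same posterior on both sides: median difference ~ 0
  d0 <- difference_distribution(ap$a, ap$a, n = 2e4, seed = 10,
                                label_a = "a1", label_b = "a2")
  expect_equal(median(d0$draws), 0, tolerance = 3 * 23 * sqrt(2) / sqrt(2e4) * 1.5)
})

test_that("fixed seeds reproduce draws and label swap mirrors them exactly", {
  ap <- make_gaussian_age_posteriors(
    data.frame(label = c("a", "b"), mean = c(100, 90), sd = c(5, 4), n = 2000),
    seed = 4)
  d1 <- difference_distribution(ap$a, ap$b, n = 1e4, seed = 7)
  d2 <- difference_distribution(ap$a, ap$b, n = 1e4, seed = 7)
  expect_identical(d1$draws, d2$draws)
  # swapping a and b negates the draws under the mirrored sub-seed policy
  d3 <- difference_distribution(ap$b, ap$a, n = 1e4, seed = 7)
  expect_equal(d3$draws, -d1$draws, tolerance = 1e-12)
})

test_that("interval probabilities integrate correctly and are monotone", {
  z <- with_seed_local(2, rnorm(1e5))
  dd <- difference_distribution(z + 50, z * 0 + 50, n = 1e4, seed = 5,
                                label_a = "za", label_b = "zb")
  # draws approx N(0, 1 + bw^2 adjustments): +/- 1.96 window holds ~95%
  p <- interval_probability(dd, 2 * 1.96)
  expect_equal(p, 0.95, tolerance = 0.01)
  expect_identical(interval_probability(dd, 0), 0)
  # kde_integral and empirical agree
  for (w in c(1, 2, 4)) {
    expect_lt(abs(interval_probability(dd, w, method = "kde_integral") -
                  interval_probability(dd, w, method = "empirical")), 0.01)
  }
  # table is nondecreasing and approaches 1
  tab <- interval_probability_table(dd, ranges = c(1, 5, 10, 20, 40, 60))
  expect_true(all(diff(tab) >= 0))
  expect_equal(unname(tab["60"]), 1, tolerance = 1e-6)
  # N(0,10^2)-style check: range 20 (i.e. +/- 10 = 1 sd) covers ~68.3%
  z10 <- with_seed_local(3, rnorm(4e4, sd = 10)) + 100
  dd10 <- difference_distribution(z10, rep(c(100, 100 + 1e-9), 2e4), n = 4e4,
                                  seed = 6, label_a = "w", label_b = "c")
  expect_equal(interval_probability(dd10, 20), 2 * pnorm(1) - 1, tolerance = 0.02)
  # one-sided and half-width semantics
  expect_equal(interval_probability(dd, 1.96, semantics = "half_width"), 0.95,
               tolerance = 0.01)
  one <- interval_probability(dd, 1.96, semantics = "one_sided")
  expect_lt(abs(one - 0.475), 0.01)
})

test_that("hpd_interval equals the exhaustive shortest-interval oracle", {
  # deterministic grid: 1..1000 at mass 0.95 -> leftmost window of 950 points
  grid <- 1:1000
  h <- hpd_interval(grid, 0.95)
  expect_identical(unname(h), c(1, 950))
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(20:400, 1)
    draws <- switch(1 + rep %% 3,
                    rnorm(n), rexp(n), c(rnorm(n %/% 2), rnorm(n - n %/% 2, 6)))
    mass <- sample(c(0.5, 0.8, 0.95), 1)
    expect_equal(unname(hpd_interval(draws, mass)), hpd_bruteforce(draws, mass),
                 tolerance = 1e-12)
  }
  expect_identical(unname(hpd_interval(rep(3.5, 30))), c(3.5, 3.5))
  expect_error(hpd_interval(1:10), "at least 20")
  expect_error(hpd_interval(1:100, 1), "mass")
})

test_that("hpd_interval matches analytic intervals on big samples", {
  z <- with_seed_local(13, rnorm(1e5))
  h <- hpd_interval(z, 0.95)
  expect_equal(unname(h), c(-1.96, 1.96), tolerance = 0.05 / 1.96)
  e <- with_seed_local(14, rexp(1e5))
  he <- hpd_interval(e, 0.95)
  expect_lt(he[["lower"]], 0.01)
  expect_equal(he[["upper"]], -log(0.05), tolerance = 0.1 / 3)
})

test_that("summarize_comparison assembles a coherent record", {
  ap <- make_gaussian_age_posteriors(
    data.frame(label = c("f", "p"), mean = c(150, 100), sd = c(1, 1), n = 5000),
    seed = 8)
  rec <- summarize_comparison(ap$f, ap$p, n = 2e4, seed = 21)
  expect_equal(rec$mean_diff, 50, tolerance = 0.5)
  expect_equal(rec$p_a_older, 1)
  # mass sits near +50: the 60 My window around 0 ([-30, 30]) holds none,
  # under width_centered semantics
  expect_lt(rec$interval_probs[["60"]], 0.01)
  expect_equal(unname(rec$hpd),
               c(50 - 1.96 * sqrt(2), 50 + 1.96 * sqrt(2)), tolerance = 0.15)
  # HPD holds the right mass empirically
  inside <- mean(rec$diff$draws >= rec$hpd["lower"] &
                 rec$diff$draws <= rec$hpd["upper"])
  expect_gte(inside, 0.95 - 1 / rec$n_draws)
  df <- as.data.frame(rec)
  expect_identical(nrow(df), 1L)
  expect_true(all(c("median_diff", "hpd_low", "p_a_older", "p_within_60") %in%
                  names(df)))
  # identical posteriors: p_a_older ~ 0.5
  rec0 <- summarize_comparison(ap$f, ap$f, n = 2e4, seed = 22,
                               label_a = "f1", label_b = "f2")
  expect_equal(rec0$p_a_older, 0.5, tolerance = 0.02)
})
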