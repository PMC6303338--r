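# Comparison of node-age posteriors between two independently dated trees:
# Gaussian KDE of each posterior, Monte Carlo resampling of paired draws,
# the distribution of age differences, HPD intervals, and the probability
# that the difference falls within fixed My ranges.

#' Fit a Gaussian kernel density estimate to an age sample
#'
#' @param samples numeric vector of ages (Ma), at least one value.
#' @param rule bandwidth rule: `"scott"` (default, `sd * n^(-1/5)`),
#'   `"silverman"` (`0.9 * min(sd, IQR/1.34) * n^(-1/5)`), or `"fixed"`.
#' @param bw bandwidth in My, required when `rule = "fixed"`.
#' @return object of class `kde_estimate`: list with `samples`, `bw`, `rule`,
#'   `degenerate` (TRUE when the sample has zero variance, in which case the
#'   estimate is a point mass at the common value).
#' @examples
#' k <- kde_fit(rnorm(1000))
#' kde_density(k, 0)
#' @export
kde_fit <- function(samples, rule = c("scott", "silverman", "fixed"), bw = NULL) {
  rule <- match.arg(rule)
  samples <- as.numeric(samples)
  if (length(samples) == 0L || anyNA(samples)) halt("`samples` must be non-empty and free of NA")
  n <- length(samples)
  s <- stats::sd(samples)
  degenerate <- n < 2L || s == 0
  h <- if (degenerate) {
    0
  } else if (rule == "scott") {
    s * n^(-1 / 5)
  } else if (rule == "silverman") {
    0.9 * min(s, stats::IQR(samples) / 1.34) * n^(-1 / 5)
  } else {
    if (is.null(bw) || !is.numeric(bw) || bw <= 0) halt("fixed rule needs a positive `bw`")
    bw
  }
  if (degenerate && rule == "fixed") h <- bw
  structure(list(samples = samples, bw = h, rule = rule,
                 degenerate = degenerate && h == 0),
            class = "kde_estimate")
}

#' @export
print.kde_estimate <- function(x, ...) {
  cat(sprintf("<kde_estimate: n = %d, bw = %.4g (%s)%s>\n",
              length(x$samples), x$bw, x$rule,
              if (x$degenerate) ", degenerate point mass" else ""))
  invisible(x)
}

#' Evaluate a KDE density
#'
#' @param kde a `kde_estimate`.
#' @param x numeric vector of evaluation points.
#' @return density values; for a degenerate estimate, `Inf` at the point mass
#'   and 0 elsewhere.
#' @export
kde_density <- function(kde, x) {
  stopifnot(inherits(kde, "kde_estimate"))
  if (kde$degenerate) return(ifelse(x == kde$samples[1], Inf, 0))
  vapply(x, function(x0) mean(stats::dnorm(x0, kde$samples, kde$bw)), numeric(1))
}

#' Evaluate a KDE cumulative distribution function
#'
#' The CDF of a Gaussian mixture is available in closed form, so interval
#' masses computed from it are exact integrals of the fitted density (no
#' quadrature error).
#'
#' @inheritParams kde_density
#' @return `P(X <= x)` under the fitted density.
#' @export
kde_cdf <- function(kde, x) {
  stopifnot(inherits(kde, "kde_estimate"))
  if (kde$degenerate) return(as.numeric(x >= kde$samples[1]))
  vapply(x, function(x0) mean(stats::pnorm(x0, kde$samples, kde$bw)), numeric(1))
}

#' Draw from a fitted KDE
#'
#' Smoothed bootstrap: resample the data with replacement and add Gaussian
#' noise with sd equal to the bandwidth.
#'
#' @inheritParams kde_density
#' @param n number of draws.
#' @param seed integer seed, or NULL.
#' @return numeric vector of length `n`.
#' @export
kde_sample <- function(kde, n, seed = NULL) {
  stopifnot(inherits(kde, "kde_estimate"), n >= 1)
  with_seed(seed, {
    base <- kde$samples[sample.int(length(kde$samples), n, replace = TRUE)]
    if (kde$degenerate) base else base + stats::rnorm(n, 0, kde$bw)
  })
}

as_ages <- function(x, what) {
  if (inherits(x, "age_posterior")) return(x$ages)
  if (is.numeric(x) && length(x) > 0L) return(as.numeric(x))
  halt("`%s` must be an age_posterior or a non-empty numeric vector", what)
}

posterior_label <- function(x, default) {
  if (inherits(x, "age_posterior")) paste(x$clade$name, x$clade$mode, sep = ".") else default
}

#' Monte Carlo distribution of the age difference between two posteriors
#'
#' Fits a Gaussian KDE to each posterior, draws `n` independent ages from
#' each, and returns the elementwise differences `a - b` (positive values mean
#' the `a` event is older). Because the two posteriors come from independent
#' MCMC runs of possibly different lengths, paired resampling from the fitted
#' densities is the default; `paired_raw = TRUE` instead pairs
#' `min(nA, nB)` raw draws subsampled without smoothing, as a sensitivity
#' check.
#'
#' Sub-seeds for the two streams are derived from `seed` and each side's label
#' only, so swapping `a` and `b` yields exactly negated draws.
#'
#' @param post_a,post_b `age_posterior` objects or numeric age vectors.
#' @param n number of paired draws (default 100000).
#' @param seed integer root seed for the comparison.
#' @param rule bandwidth rule passed to [kde_fit()].
#' @param label_a,label_b labels used in reports and seed derivation;
#'   default to the posterior clade labels.
#' @param paired_raw pair subsampled raw draws instead of KDE draws.
#' @return object of class `difference_distribution`: list with `draws` (My),
#'   `label_a`, `label_b`, `sign_convention = "a_minus_b"`, `n_draws`, `seed`,
#'   `kde` (KDE fitted to the draws), `degenerate`.
#' @export
difference_distribution <- function(post_a, post_b, n = 100000, seed = 1,
                                    rule = "scott",
                                    label_a = posterior_label(post_a, "a"),
                                    label_b = posterior_label(post_b, "b"),
                                    paired_raw = FALSE) {
  a <- as_ages(post_a, "post_a")
  b <- as_ages(post_b, "post_b")
  stopifnot(n >= 1)
  if (paired_raw) {
    m <- min(length(a), length(b))
    ia <- with_seed(derive_seed(seed, "raw", label_a), sample.int(length(a), m))
    ib <- with_seed(derive_seed(seed, "raw", label_b), sample.int(length(b), m))
    draws <- a[ia] - b[ib]
    degenerate <- stats::sd(draws) == 0
  } else {
    kde_a <- kde_fit(a, rule = rule)
    kde_b <- kde_fit(b, rule = rule)
    draws_a <- kde_sample(kde_a, n, seed = derive_seed(seed, "kde_draw", label_a))
    draws_b <- kde_sample(kde_b, n, seed = derive_seed(seed, "kde_draw", label_b))
    draws <- draws_a - draws_b
    degenerate <- kde_a$degenerate && kde_b$degenerate
  }
  if (degenerate) {
    warning("both posteriors are degenerate: differences collapse to a constant")
  }
  structure(list(draws = draws, label_a = label_a, label_b = label_b,
                 sign_convention = "a_minus_b", n_draws = length(draws),
                 seed = seed, kde = kde_fit(draws, rule = rule),
                 degenerate = degenerate),
            class = "difference_distribution")
}

#' @export
print.difference_distribution <- function(x, ...) {
  cat(sprintf("<difference_distribution %s - %s: n = %d, median = %.3f My>\n",
              x$label_a, x$label_b, x$n_draws, stats::median(x$draws)))
  invisible(x)
}

range_bounds <- function(range_width, center,
                         semantics = c("width_centered", "one_sided", "half_width")) {
  semantics <- match.arg(semantics)
  switch(semantics,
         width_centered = c(center - range_width / 2, center + range_width / 2),
         one_sided = c(center, center + range_width),
         half_width = c(center - range_width, center + range_width))
}

#' Probability that the age difference lies within a range
#'
#' Under the default `"width_centered"` semantics a range of `r` My is the
#' interval `[center - r/2, center + r/2]`; `"one_sided"` uses
#' `[center, center + r]` and `"half_width"` uses `[center - r, center + r]`.
#'
#' @param diff a `difference_distribution`.
#' @param range_width range in My, `>= 0`.
#' @param center interval center in My (default 0, i.e. simultaneity).
#' @param method `"kde_integral"` (closed-form integral of the difference KDE,
#'   default) or `"empirical"` (fraction of draws in the interval).
#' @param semantics interval semantics, see above.
#' @return a proportion in `[0, 1]`.
#' @export
interval_probability <- function(diff, range_width, center = 0,
                                 method = c("kde_integral", "empirical"),
                                 semantics = "width_centered") {
  stopifnot(inherits(diff, "difference_distribution"), range_width >= 0)
  method <- match.arg(method)
  bounds <- range_bounds(range_width, center, semantics)
  if (bounds[1] == bounds[2]) return(0)
  if (method == "empirical") {
    mean(diff$draws >= bounds[1] & diff$draws <= bounds[2])
  } else {
    kde_cdf(diff$kde, bounds[2]) - kde_cdf(diff$kde, bounds[1])
  }
}

#' Interval-probability table over standard ranges
#'
#' @inheritParams interval_probability
#' @param ranges vector of range widths in My (default 1, 5, 10, 20, 40, 60).
#' @return named numeric vector, one probability per range, nondecreasing.
#' @export
interval_probability_table <- function(diff, ranges = c(1, 5, 10, 20, 40, 60),
                                       center = 0, method = "kde_integral",
                                       semantics = "width_centered") {
  stopifnot(all(ranges > 0))
  ranges <- sort(ranges)
  out <- vapply(ranges, function(r) {
    interval_probability(diff, r, center = center, method = method,
                         semantics = semantics)
  }, numeric(1))
  names(out) <- as.character(ranges)
  out
}

#' Highest-posterior-density interval from draws
#'
#' Chen-Shao shortest-interval estimator: among all windows of
#' `ceiling(mass * n)` consecutive sorted draws, the narrowest; ties are
#' broken by the smallest lower endpoint.
#'
#' @param draws numeric vector, `n >= 20`.
#' @param mass probability mass, strictly between 0 and 1 (default 0.95).
#' @return named numeric vector `c(lower, upper)`.
#' @examples
#' hpd_interval(rexp(1e4), 0.95)  # approx c(0, 3)
#' @export
hpd_interval <- function(draws, mass = 0.95) {
  draws <- as.numeric(draws)
  if (length(draws) < 20L) halt("need at least 20 draws for an HPD interval")
  if (!is.numeric(mass) || mass <= 0 || mass >= 1) halt("`mass` must be in (0, 1)")
  x <- sort(draws)
  n <- length(x)
  m <- ceiling(mass * n)
  widths <- x[m:n] - x[seq_len(n - m + 1L)]
  i <- which.min(widths)  # first minimum = smallest lower endpoint
  c(lower = x[i], upper = x[i + m - 1L])
}

#' Full comparison of two node-age posteriors
#'
#' Builds the difference distribution and summarizes it: median and mean
#' difference, HPD interval, probability that `a` is older (fraction of draws
#' `> 0`), and the interval-probability table.
#'
#' @inheritParams difference_distribution
#' @param hpd_mass HPD mass (default 0.95).
#' @param ranges range widths in My for the probability table.
#' @param semantics,method interval semantics and integration method, see
#'   [interval_probability()].
#' @return object of class `comparison_record`: list with `label_a`,
#'   `label_b`, `median_diff`, `mean_diff`, `hpd` (named vector),
#'   `hpd_mass`, `p_a_older`, `interval_probs`, `n_draws`, `seed`, and the
#'   underlying `diff`.
#' @export
summarize_comparison <- function(post_a, post_b, n = 100000, seed = 1,
                                 hpd_mass = 0.95,
                                 ranges = c(1, 5, 10, 20, 40, 60),
                                 semantics = "width_centered",
                                 method = "kde_integral",
                                 rule = "scott",
                                 label_a = posterior_label(post_a, "a"),
                                 label_b = posterior_label(post_b, "b"),
                                 paired_raw = FALSE) {
  d <- difference_distribution(post_a, post_b, n = n, seed = seed, rule = rule,
                               label_a = label_a, label_b = label_b,
                               paired_raw = paired_raw)
  structure(list(label_a = d$label_a, label_b = d$label_b,
                 median_diff = stats::median(d$draws),
                 mean_diff = mean(d$draws),
                 hpd = hpd_interval(d$draws, hpd_mass),
                 hpd_mass = hpd_mass,
                 p_a_older = mean(d$draws > 0),
                 interval_probs = interval_probability_table(
                   d, ranges = ranges, method = method, semantics = semantics),
                 n_draws = d$n_draws, seed = seed, diff = d),
            class = "comparison_record")
}

#' @export
print.comparison_record <- function(x, ...) {
  cat(sprintf("<comparison %s - %s>\n", x$label_a, x$label_b))
  cat(sprintf("  median diff %.3f My, mean %.3f My\n", x$median_diff, x$mean_diff))
  cat(sprintf("  %.0f%% HPD [%.3f, %.3f], P(a older) = %.4f\n",
              100 * x$hpd_mass, x$hpd["lower"], x$hpd["upper"], x$p_a_older))
  cat("  P(|diff| in range): ",
      paste(sprintf("%s My: %.3f", names(x$interval_probs), x$interval_probs),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' One-row data frame view of a comparison record
#'
#' @param x a `comparison_record`.
#' @param ... unused.
#' @return a single-row `data.frame` with columns `clade_a`, `clade_b`,
#'   `median_diff`, `mean_diff`, `hpd_low`, `hpd_high`, `p_a_older`, and one
#'   `p_within_<r>` column per range.
#' @export
as.data.frame.comparison_record <- function(x, ...) {
  row <- data.frame(clade_a = x$label_a, clade_b = x$label_b,
                    median_diff = x$median_diff, mean_diff = x$mean_diff,
                    hpd_low = unname(x$hpd["lower"]),
                    hpd_high = unname(x$hpd["upper"]),
                    p_a_older = x$p_a_older, stringsAsFactors = FALSE)
  probs <- as.list(x$interval_probs)
  names(probs) <- paste0("p_within_", names(x$interval_probs))
  cbind(row, as.data.frame(probs, check.names = FALSE))
}
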