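# Fossil calibration priors: offset-lognormal, truncated-normal, uniform,
# plus the minimum-age arithmetic and the support-threshold placement rule.

#' Fossil minimum age from a stratigraphic lower bound and its margin of error
#'
#' The minimum node age anchored by a fossil is the lower boundary age of its
#' oldest stratigraphic bin minus the chart's stated margin of error. The
#' subtraction is carried out on decimal-scaled integers (0.1 My resolution)
#' so printed ages like 407.0 - 2.8 = 404.2 are reproduced exactly, with no
#' binary floating-point residue.
#'
#' @param stage_lower_bound lower boundary age of the stratigraphic bin (Ma).
#' @param margin margin of error on that boundary (My), `>= 0` and smaller
#'   than the boundary age.
#' @return minimum age in Ma.
#' @examples
#' fossil_min_age(407.0, 2.8)  # 404.2
#' @export
fossil_min_age <- function(stage_lower_bound, margin) {
  stopifnot(is.numeric(stage_lower_bound), is.numeric(margin))
  if (any(margin < 0)) halt("`margin` must be non-negative")
  if (any(stage_lower_bound <= 0)) halt("`stage_lower_bound` must be positive")
  if (any(margin >= stage_lower_bound)) halt("`margin` must be smaller than the bound")
  (round(stage_lower_bound * 10) - round(margin * 10)) / 10
}

#' Offset-lognormal calibration prior
#'
#' A hard minimum at the fossil age plus a lognormal distribution on the
#' exceedance (node age minus fossil age). The log-mean is chosen so that the
#' analytic mean exceedance, exp(mu + sigma^2/2), equals
#' `expected_fraction * fossil_age`: by default the node is expected to be 5%
#' older than its fossil minimum, with log-sd 0.75.
#'
#' @param fossil_age hard minimum age (Ma), typically from [fossil_min_age()].
#' @param sigma log-scale standard deviation of the exceedance (default 0.75).
#' @param expected_fraction expected exceedance as a fraction of the fossil
#'   age (default 0.05).
#' @return an object of class `c("lognormal_offset_prior", "calibration_prior")`
#'   with fields `offset`, `mu`, `sigma`, `expected_fraction`.
#' @examples
#' p <- make_lognormal_prior(404.2)
#' p$mu                       # log(0.05 * 404.2) - 0.75^2 / 2
#' exp(p$mu + p$sigma^2 / 2)  # 20.21 = 5% of 404.2
#' @export
make_lognormal_prior <- function(fossil_age, sigma = 0.75, expected_fraction = 0.05) {
  if (!is.numeric(fossil_age) || fossil_age <= 0) halt("`fossil_age` must be positive")
  if (!is.numeric(sigma) || sigma <= 0) halt("`sigma` must be positive")
  if (!is.numeric(expected_fraction) || expected_fraction <= 0) {
    halt("`expected_fraction` must be positive")
  }
  structure(list(offset = fossil_age,
                 mu = log(expected_fraction * fossil_age) - sigma^2 / 2,
                 sigma = sigma,
                 expected_fraction = expected_fraction),
            class = c("lognormal_offset_prior", "calibration_prior"))
}

#' Truncated-normal calibration prior
#'
#' A normal distribution on node age combined with a hard minimum: the density
#' is zero below `min_age` and renormalized by the normal upper-tail mass
#' above it.
#'
#' @param mean mean of the underlying normal (Ma).
#' @param sd standard deviation (My), positive.
#' @param min_age hard minimum age (Ma).
#' @return an object of class `c("truncated_normal_prior", "calibration_prior")`.
#' @export
make_truncated_normal_prior <- function(mean, sd, min_age) {
  stopifnot(is.numeric(mean), is.numeric(sd), is.numeric(min_age))
  if (sd <= 0) halt("`sd` must be positive")
  tail_mass <- stats::pnorm(min_age, mean, sd, lower.tail = FALSE)
  if (tail_mass <= 0) halt("no normal mass above `min_age`")
  structure(list(mean = mean, sd = sd, min_age = min_age, tail_mass = tail_mass),
            class = c("truncated_normal_prior", "calibration_prior"))
}

#' Uniform calibration prior
#'
#' @param young_bound younger bound (Ma).
#' @param old_bound older bound (Ma), strictly greater.
#' @return an object of class `c("uniform_prior", "calibration_prior")`.
#' @examples
#' make_uniform_prior(443.8, 485)  # embryophyte-style crown calibration
#' @export
make_uniform_prior <- function(young_bound, old_bound) {
  stopifnot(is.numeric(young_bound), is.numeric(old_bound))
  if (young_bound >= old_bound) halt("`young_bound` must be < `old_bound`")
  structure(list(young_bound = young_bound, old_bound = old_bound),
            class = c("uniform_prior", "calibration_prior"))
}

#' @export
print.calibration_prior <- function(x, ...) {
  desc <- switch(class(x)[1],
    lognormal_offset_prior = sprintf("offset-lognormal: offset %.4g Ma, mu %.5f, sigma %.3g",
                                     x$offset, x$mu, x$sigma),
    truncated_normal_prior = sprintf("truncated normal: mean %.4g, sd %.4g, min %.4g Ma",
                                     x$mean, x$sd, x$min_age),
    uniform_prior = sprintf("uniform on [%.4g, %.4g] Ma", x$young_bound, x$old_bound))
  cat("<calibration prior - ", desc, ">\n", sep = "")
  invisible(x)
}

#' Prior density of a calibration prior at given ages
#'
#' @param prior a calibration prior object.
#' @param age numeric vector of ages (Ma).
#' @return density per My, vectorized over `age`; zero outside the support.
#' @export
prior_density <- function(prior, age) UseMethod("prior_density")

#' @export
prior_density.lognormal_offset_prior <- function(prior, age) {
  d <- numeric(length(age))
  pos <- age > prior$offset
  d[pos] <- stats::dlnorm(age[pos] - prior$offset, prior$mu, prior$sigma)
  d
}

#' @export
prior_density.truncated_normal_prior <- function(prior, age) {
  d <- numeric(length(age))
  ok <- age >= prior$min_age
  d[ok] <- stats::dnorm(age[ok], prior$mean, prior$sd) / prior$tail_mass
  d
}

#' @export
prior_density.uniform_prior <- function(prior, age) {
  stats::dunif(age, prior$young_bound, prior$old_bound)
}

#' Draw node ages from a calibration prior
#'
#' Reproducible i.i.d. draws: the truncated normal is sampled by inverse-CDF
#' restricted to the upper tail (no rejection), so the draw count per prior is
#' fixed and seeds map one-to-one onto outputs.
#'
#' @param prior a calibration prior object.
#' @param n number of draws.
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @return numeric vector of ages (Ma), length `n`.
#' @export
sample_prior <- function(prior, n, seed = NULL) {
  stopifnot(is.numeric(n), n >= 1)
  UseMethod("sample_prior")
}

#' @export
sample_prior.lognormal_offset_prior <- function(prior, n, seed = NULL) {
  with_seed(seed, prior$offset + stats::rlnorm(n, prior$mu, prior$sigma))
}

#' @export
sample_prior.truncated_normal_prior <- function(prior, n, seed = NULL) {
  lo <- stats::pnorm(prior$min_age, prior$mean, prior$sd)
  with_seed(seed, stats::qnorm(stats::runif(n, lo, 1), prior$mean, prior$sd))
}

#' @export
sample_prior.uniform_prior <- function(prior, n, seed = NULL) {
  with_seed(seed, stats::runif(n, prior$young_bound, prior$old_bound))
}

#' Place a calibration on the shallowest sufficiently supported node
#'
#' Starting from the MRCA of the clade's taxa, walks rootward and returns the
#' first node whose Bayesian posterior probability and ML bootstrap proportion
#' both meet their thresholds (defaults: PP >= 0.95 and bootstrap >= 0.70).
#' The MRCA itself is returned when it qualifies. Tip "nodes" (singleton taxa)
#' are treated as fully supported.
#'
#' @param tree a rooted `phylo`.
#' @param taxa taxon set or [clade_definition()].
#' @param pp named or positional numeric vector of posterior probabilities for
#'   internal nodes (length `tree$Nnode`, indexed in ape internal-node order:
#'   entry `i` is node `Ntip + i`). `NA` entries are treated as unsupported.
#' @param bootstrap ML bootstrap proportions, same layout as `pp`. Values may
#'   be given on 0-1 or 0-100 scales; values > 1 are divided by 100.
#' @param pp_min,bs_min support thresholds.
#' @return integer node id of the calibrated node.
#' @export
place_calibration <- function(tree, taxa, pp, bootstrap,
                              pp_min = 0.95, bs_min = 0.70) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- ape::Ntip(tree)
  if (length(pp) != tree$Nnode || length(bootstrap) != tree$Nnode) {
    halt("`pp` and `bootstrap` must have one entry per internal node (%d)", tree$Nnode)
  }
  bootstrap <- ifelse(!is.na(bootstrap) & bootstrap > 1, bootstrap / 100, bootstrap)
  supported <- function(node) {
    if (node <= ntip) return(TRUE)
    i <- node - ntip
    !is.na(pp[i]) && !is.na(bootstrap[i]) && pp[i] >= pp_min && bootstrap[i] >= bs_min
  }
  node <- mrca_node(tree, taxa)
  repeat {
    if (supported(node)) return(node)
    parent <- parent_node(tree, node)
    if (is.na(parent)) {
      halt("no node from the MRCA to the root meets PP >= %g and bootstrap >= %g",
           pp_min, bs_min)
    }
    node <- parent
  }
}

#' Read a fossil calibration table and build priors
#'
#' TSV with columns `fossil_name`, `clade_name`, `stage_lower_bound_ma`,
#' `margin_my`, `prior_family`, `param1`, `param2`. Family semantics:
#' \describe{
#'   \item{lognormal}{`param1` = sigma (default 0.75 if NA), `param2` =
#'     expected fraction (default 0.05 if NA); offset = boundary minus margin.}
#'   \item{truncated_normal}{`param1` = mean, `param2` = sd; minimum age =
#'     boundary minus margin. NA mean/sd are left unresolved (`prior = NULL`):
#'     the normal components are user configuration, only the minimum is
#'     derived from the table.}
#'   \item{uniform}{`param1` = young bound, `param2` = old bound.}
#' }
#'
#' @param path TSV path; lines starting with `#` are ignored.
#' @return a data.frame with one row per fossil, plus a `min_age_ma` column
#'   and a `prior` list-column of calibration prior objects (or NULL).
#' @export
read_calibration_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("fossil_name", "clade_name", "stage_lower_bound_ma", "margin_my",
            "prior_family", "param1", "param2")
  if (!all(need %in% names(df))) {
    halt("calibration table must have columns %s", paste(need, collapse = ", "))
  }
  df$min_age_ma <- fossil_min_age(df$stage_lower_bound_ma, df$margin_my)
  df$prior <- lapply(seq_len(nrow(df)), function(i) {
    fam <- df$prior_family[i]
    p1 <- df$param1[i]; p2 <- df$param2[i]
    switch(fam,
      lognormal = make_lognormal_prior(df$min_age_ma[i],
                                       sigma = if (is.na(p1)) 0.75 else p1,
                                       expected_fraction = if (is.na(p2)) 0.05 else p2),
      truncated_normal = if (is.na(p1) || is.na(p2)) NULL else
        make_truncated_normal_prior(p1, p2, df$min_age_ma[i]),
      uniform = make_uniform_prior(p1, p2),
      halt("unknown prior_family '%s' (row %d)", fam, i))
  })
  df
}
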