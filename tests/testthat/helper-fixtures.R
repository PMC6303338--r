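# Shared fixtures and independent oracles used across test files.

with_seed_local <- function(seed, code) {
  set.seed(seed)
  code
}

# the canonical 3-tip chronogram: ((A:1,B:1):1,C:2);
tree3 <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

write_newick_sample <- function(newicks, path = tempfile(fileext = ".nwk")) {
  writeLines(newicks, path)
  path
}

# Exhaustive shortest-interval oracle for the HPD: scans every window length
# >= ceiling(mass * n) over the sorted draws, not just the minimal one.
hpd_bruteforce <- function(draws, mass = 0.95) {
  x <- sort(draws)
  n <- length(x)
  m <- ceiling(mass * n)
  best <- c(-Inf, Inf)
  for (k in m:n) {
    widths <- x[k:n] - x[seq_len(n - k + 1L)]
    i <- which.min(widths)
    if (widths[i] < best[2] - best[1]) best <- c(x[i], x[i + k - 1L])
  }
  best
}

# Numeric integral of a calibration prior's density over its support.
prior_mass <- function(prior, lower, upper) {
  stats::integrate(function(a) prior_density(prior, a), lower, upper,
                   rel.tol = 1e-9, subdivisions = 1000L)$value
}
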