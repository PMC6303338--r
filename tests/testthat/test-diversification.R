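# Birth-death likelihoods, richness terms, AICc, fitting, and the shift search.

test_that("clade richness log-probability matches its closed forms", {
  # pure birth with e^{rt} = 2: geometric with beta = 0.5
  p <- bd_params(log(2))
  expect_equal(exp(clade_richness_logprob(1, 1, p)), 0.5, tolerance = 1e-12)
  expect_equal(exp(clade_richness_logprob(2, 1, p)), 0.25, tolerance = 1e-12)
  # pure birth n = 1 is the no-speciation probability e^{-lambda t}
  expect_equal(clade_richness_logprob(1, 2.5, bd_params(0.3)), -0.3 * 2.5,
               tolerance = 1e-12)
  # normalization: geometric sums to 1
  for (pars in list(bd_params(log(2)), bd_params(0.2, 0.5), bd_params(1, 0.9))) {
    expect_equal(sum(exp(clade_richness_logprob(1:5000, 1, pars))), 1,
                 tolerance = 1e-9)
  }
  expect_error(clade_richness_logprob(0, 1, p), "n")
})

test_that("richness law matches Monte Carlo clade-size frequencies", {
  # small-scale version of the oracle check (full scale in acceptance)
  n_rep <- 20000
  for (eps in c(0, 0.5)) {
    pars <- bd_params(log(2), eps)  # rt = ln 2 at t = 1
    sizes <- simulate_clade_size(1, pars, n_rep = n_rep, seed = 31 + eps * 10)
    for (n in c(1, 2, 5)) {
      p_hat <- mean(sizes == n)
      p_true <- exp(clade_richness_logprob(n, 1, pars))
      se <- sqrt(p_true * (1 - p_true) / n_rep)
      expect_lt(abs(p_hat - p_true), 3 * se)
    }
  }
})

test_that("backbone likelihood agrees with closed forms on tiny trees", {
  # 2-tip Yule tree of depth t: P(no further split) = e^{-2 lambda t}
  t2 <- ape::read.tree(text = "(A:3,B:3);")
  expect_equal(backbone_loglik(t2, bd_params(0.5)), -2 * 0.5 * 3,
               tolerance = 1e-12)
  # 3-tip Yule: density lambda * e^{-2 lambda T - lambda x}
  t3 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  lam <- 0.7
  expect_equal(backbone_loglik(t3, bd_params(lam)),
               log(lam) - 2 * lam * 2 - lam * 1, tolerance = 1e-12)
  # with extinction, survival conditioning keeps the 2-tip value a probability
  ll <- backbone_loglik(t2, bd_params(0.5, 0.6))
  expect_lt(ll, 0)
})

test_that("2-tip Yule backbone probability matches simulation frequency", {
  # fraction of pure-birth trees (depth 1.2, lambda 0.6) still with 2 tips
  lam <- 0.6; depth <- 1.2; n_rep <- 4000
  two <- 0
  for (i in seq_len(n_rep)) {
    tr <- simulate_bd_tree(lam, 0, time = depth, seed = 5000 + i)
    two <- two + (ape::Ntip(tr) == 2L)
  }
  p_true <- exp(-2 * lam * depth)
  expect_lt(abs(two / n_rep - p_true), 3 * sqrt(p_true * (1 - p_true) / n_rep))
})

test_that("likelihood is maximized at the MLE and invariant to relabeling", {
  tr <- simulate_bd_tree(0.8, 0.2, n_tips = 40, seed = 17)
  rt <- richness_tree(tr, setNames(rep(1L, 40), tr$tip.label))
  fit <- fit_bd(rt, seed = 2)
  best <- fit$classes[[1]]
  pars_hat <- bd_params(best$r, best$eps)
  ll_hat <- backbone_loglik(tr, pars_hat)
  set.seed(19)
  for (i in 1:20) {
    r_p <- best$r * exp(rnorm(1, 0, 0.3))
    e_p <- plogis(qlogis(max(best$eps, 1e-6)) + rnorm(1, 0, 0.5))
    expect_lte(backbone_loglik(tr, bd_params(r_p, e_p)), ll_hat + 1e-6)
  }
  # relabeling tips leaves the likelihood unchanged
  tr2 <- tr
  tr2$tip.label <- paste0("sp_", rev(seq_len(40)))
  expect_equal(backbone_loglik(tr2, pars_hat), ll_hat, tolerance = 1e-12)
  # edge reordering too
  tr3 <- ape::reorder.phylo(tr, "postorder")
  expect_equal(backbone_loglik(tr3, pars_hat), ll_hat, tolerance = 1e-10)
})

test_that("with unit richness the joint fit reduces to the backbone fit", {
  tr <- simulate_bd_tree(1, 0.3, n_tips = 25, seed = 23)
  rt <- richness_tree(tr, setNames(rep(1L, 25), tr$tip.label))
  pars <- bd_params(0.7, 0.3)
  joint <- backbone_loglik(tr, pars, pendant = "survival") +
    sum(clade_richness_logprob(
      rep(1L, 25),
      phylochron:::node_ages(tr)[tr$edge[, 1]][match(1:25, tr$edge[, 2])],
      pars))
  expect_equal(joint, backbone_loglik(tr, pars, pendant = "exact1"),
               tolerance = 1e-10)
})

test_that("Yule rate is recovered from a 200-tip simulated tree", {
  tr <- simulate_bd_tree(1, 0, n_tips = 200, seed = 42)
  rt <- richness_tree(tr, setNames(rep(1L, 200), tr$tip.label))
  fit <- fit_bd(rt, seed = 1)
  expect_gt(fit$classes[[1]]$r, 0.85)
  expect_lt(fit$classes[[1]]$r, 1.15)
  expect_true(all(vapply(fit$classes, function(cl) cl$eps >= 0 && cl$eps < 1,
                         logical(1))))
})

test_that("aicc arithmetic and the small-sample guard are right", {
  expect_identical(aicc(-100, 2, 1e6), 204 + 12 / (1e6 - 3))
  expect_equal(aicc(-100, 2, 10), 204 + 12 / 7, tolerance = 1e-12)
  expect_warning(out <- aicc(-100, 2, 3), "AIC")
  expect_identical(out, 204)
})

test_that("adding a shift never decreases the maximized log-likelihood", {
  sc <- simulate_shift_scenario(3)
  fit0 <- fit_bd(sc$rtree, seed = 5)
  fit1 <- fit_bd(sc$rtree, sc$target_edge, seed = 5)
  expect_gte(fit1$logL, fit0$logL - 1e-6)
  # search trace is monotone in logL
  fit <- stepwise_shift_search(sc$rtree, max_shifts = 2, seed = 5)
  expect_true(all(diff(fit$trace$logL) >= -1e-6))
})

test_that("threshold Inf returns the constant-rate model", {
  sc <- simulate_shift_scenario(4)
  fit <- stepwise_shift_search(sc$rtree, threshold = Inf, seed = 1)
  expect_identical(length(fit$shift_edges), 0L)
  expect_identical(nrow(fit$trace), 1L)
})

test_that("an engineered 10-fold shift is recovered on or next to its edge", {
  sc <- simulate_shift_scenario(1)
  fit <- stepwise_shift_search(sc$rtree, max_shifts = 2, seed = 1)
  parent_edge <- match(sc$rtree$tree$edge[sc$target_edge, 1],
                       sc$rtree$tree$edge[, 2])
  expect_true(any(fit$shift_edges %in% c(sc$target_edge, parent_edge)))
  # the shifted class has the faster net rate
  shifted_class <- fit$assignment[fit$shift_edges[1]]
  expect_gt(fit$classes[[shifted_class]]$r, fit$classes[[1]]$r)
})

test_that("shift results serialize to TSV and annotated Newick", {
  sc <- simulate_shift_scenario(2)
  fit <- stepwise_shift_search(sc$rtree, max_shifts = 1, seed = 2)
  tsv <- tempfile(fileext = ".tsv")
  nwk <- tempfile(fileext = ".nwk")
  write_shift_results(fit, sc$rtree, tsv, nwk)
  tab <- utils::read.table(tsv, sep = "\t", header = TRUE)
  expect_identical(nrow(tab), nrow(fit$trace))
  expect_true(all(c("edge_id", "r", "eps", "aicc") %in% names(tab)))
  txt <- readLines(nwk)
  expect_match(txt, "\\[&class=1\\]")
  # the annotated tree parses once comments are stripped
  tr <- ape::read.tree(text = gsub("\\[&class=\\d+\\]", "", txt))
  expect_identical(sort(tr$tip.label), sort(sc$rtree$tree$tip.label))
})

test_that("richness_tree validates its inputs", {
  tr <- tree3()
  expect_error(richness_tree(tr, c(A = 1, B = 2)), "missing")
  expect_error(richness_tree(tr, c(A = 1, B = 0, C = 2)), ">= 1")
  rt <- richness_tree(tr, c(A = 1, B = 5, C = 10))
  expect_identical(rt$total_richness, 16L)
  bad <- ape::read.tree(text = "((A:1,B:1.5):1,C:2);")
  expect_error(richness_tree(bad, c(A = 1, B = 1, C = 1)), "ultrametric")
})
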