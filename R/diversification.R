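# Richness-aware birth-death diversification-shift detection.
#
# The backbone (resolved) part of the tree is scored with the constant-rate
# birth-death likelihood of the reconstructed process conditioned on survival
# of the two root lineages; each terminal clade of known extant richness n and
# stem age t contributes the conditional geometric probability
# P(n | t, r, eps) with beta = (exp(rt) - 1) / (exp(rt) - eps).
# Rate shifts partition the edges into classes; each class has its own
# (r, eps) and the likelihood factorizes over classes, so classes are fitted
# independently. Model selection is stepwise by AICc.

#' Birth-death parameters in (net rate, relative extinction) form
#'
#' @param r net diversification rate per My, `> 0` (`r = lambda - mu`).
#' @param eps relative extinction `mu / lambda`, in `[0, 1)`.
#' @return object of class `bd_params` with derived `lambda` and `mu`.
#' @examples
#' bd_params(0.1, 0.5)  # lambda = 0.2, mu = 0.1
#' @export
bd_params <- function(r, eps = 0) {
  if (!is.numeric(r) || r <= 0) halt("`r` must be positive")
  if (!is.numeric(eps) || eps < 0 || eps >= 1) halt("`eps` must be in [0, 1)")
  structure(list(r = r, eps = eps, lambda = r / (1 - eps),
                 mu = r * eps / (1 - eps)),
            class = "bd_params")
}

#' @export
print.bd_params <- function(x, ...) {
  cat(sprintf("<bd_params: r = %.4g, eps = %.4g (lambda = %.4g, mu = %.4g)>\n",
              x$r, x$eps, x$lambda, x$mu))
  invisible(x)
}

# Stable log-space building blocks, vectorized over t.
#   beta(t)  = (e^{rt} - 1) / (e^{rt} - eps)   geometric parameter
#   Ps(t)    = (1 - eps) e^{rt} / (e^{rt} - eps)   survival to the present
#   p1(t)    = Ps(t) (1 - beta(t))   exactly one surviving descendant lineage
bd_log_beta <- function(t, r, eps) {
  log1p(-exp(-r * t)) - log1p(-eps * exp(-r * t))
}
bd_log_one_minus_beta <- function(t, r, eps) {
  log1p(-eps) - r * t - log1p(-eps * exp(-r * t))
}
bd_log_surv <- function(t, r, eps) {
  log1p(-eps) - log1p(-eps * exp(-r * t))
}
bd_log_p1 <- function(t, r, eps) {
  2 * (log1p(-eps) - log1p(-eps * exp(-r * t))) - r * t
}

#' Log-probability of a clade's extant richness given its stem age
#'
#' `log P(N(t) = n | survival)` for one lineage of stem age `t` under a
#' constant-rate birth-death process: the conditional geometric law
#' `(1 - beta) beta^(n-1)` with `beta = (exp(rt) - 1) / (exp(rt) - eps)`.
#'
#' @param n extant species count, `>= 1` (the law conditions on survival).
#' @param t stem age in My, `> 0`.
#' @param params a [bd_params()].
#' @return log-probability; vectorized over `n` and `t`.
#' @examples
#' p <- bd_params(log(2))            # pure birth, e^{rt} = 2 at t = 1
#' exp(clade_richness_logprob(1:2, 1, p))  # 0.5, 0.25
#' @export
clade_richness_logprob <- function(n, t, params) {
  stopifnot(inherits(params, "bd_params"))
  if (any(n < 1) || any(n != round(n))) halt("`n` must be integer >= 1 (conditioned on survival)")
  if (any(t <= 0)) halt("`t` must be positive")
  bd_log_one_minus_beta(t, params$r, params$eps) +
    (n - 1) * bd_log_beta(t, params$r, params$eps)
}

#' Constant-rate birth-death log-likelihood of a chronogram backbone
#'
#' Likelihood of the reconstructed tree under a constant-rate birth-death
#' process, conditioned on survival of the two lineages descending from the
#' root (Nee-style crown conditioning). It factorizes over edges: an edge from
#' age `t_b` down to `t_e` contributes the log-probability that one lineage
#' with surviving descendants stays a single reconstructed lineage over that
#' interval, and each non-root internal node contributes `log(lambda)` per
#' speciation event.
#'
#' Pendant edges are scored per `pendant`: `"exact1"` (default) requires the
#' tip lineage to leave exactly one extant species, giving the likelihood of a
#' fully resolved, complete tree; `"survival"` only requires survival, which
#' is the backbone part used with terminal-richness terms (the conditional
#' geometric then supplies the `N = n` statement).
#'
#' @param tree rooted ultrametric `phylo`.
#' @param params a [bd_params()].
#' @param pendant `"exact1"` or `"survival"`.
#' @param rtol ultrametricity tolerance.
#' @return log-likelihood (a log-density over node times).
#' @export
backbone_loglik <- function(tree, params, pendant = c("exact1", "survival"),
                            rtol = 1e-6) {
  pendant <- match.arg(pendant)
  stopifnot(inherits(tree, "phylo"), inherits(params, "bd_params"))
  if (ape::Ntip(tree) < 2L) halt("need at least 2 tips")
  parts <- bd_likelihood_parts(tree, rtol = rtol)
  class_loglik(parts_subset(parts, rep(1L, nrow(tree$edge)), 1L, root_class = TRUE),
               params$r, params$eps,
               richness = if (pendant == "exact1") rep(1L, ape::Ntip(tree)) else NULL,
               pendant_survival_only = (pendant == "survival"))
}

# Precompute the per-edge quantities the likelihood needs.
# Returns parent age t_b, child age t_e, child-is-tip flag, tip index for
# pendant edges, number of speciation events at each edge's child node
# (n_children - 1 for internal children, polytomies allowed), root age.
bd_likelihood_parts <- function(tree, rtol = 1e-6) {
  ages <- node_ages(tree, rtol = rtol)
  ntip <- ape::Ntip(tree)
  edge <- tree$edge
  child <- edge[, 2]
  n_kids <- tabulate(edge[, 1], nbins = ntip + tree$Nnode)
  list(t_b = ages[edge[, 1]],
       t_e = ages[child],
       is_tip = child <= ntip,
       tip_id = ifelse(child <= ntip, child, NA_integer_),
       events = ifelse(child > ntip, n_kids[child] - 1L, 0L),
       root_age = ages[ntip + 1L],
       ntip = ntip)
}

# Restrict precomputed parts to the edges of one rate class.
parts_subset <- function(parts, assignment, cls, root_class) {
  sel <- assignment == cls
  list(t_b = parts$t_b[sel], t_e = parts$t_e[sel],
       is_tip = parts$is_tip[sel], tip_id = parts$tip_id[sel],
       events = parts$events[sel],
       root_age = parts$root_age, root_class = root_class)
}

# Log-likelihood of one rate class given its edge subset.
# richness: per-tip counts (full-tree indexing) or NULL for survival-only
# pendants. Root-class subsets additionally carry the -2 log Ps(root age)
# survival conditioning.
class_loglik <- function(sub, r, eps, richness = NULL,
                         pendant_survival_only = FALSE) {
  if (r <= 0 || eps < 0 || eps >= 1) return(-Inf)
  log_lambda <- log(r) - log1p(-eps)
  ll <- sum(sub$events) * log_lambda
  internal <- !sub$is_tip
  if (any(internal)) {
    ll <- ll + sum(bd_log_p1(sub$t_b[internal], r, eps) -
                   bd_log_p1(sub$t_e[internal], r, eps))
  }
  if (any(sub$is_tip)) {
    tb <- sub$t_b[sub$is_tip]
    if (pendant_survival_only || is.null(richness)) {
      ll <- ll + sum(bd_log_surv(tb, r, eps))
    } else {
      n <- richness[sub$tip_id[sub$is_tip]]
      ll <- ll + sum(bd_log_surv(tb, r, eps) +
                     bd_log_one_minus_beta(tb, r, eps) +
                     (n - 1) * bd_log_beta(tb, r, eps))
    }
  }
  if (isTRUE(sub$root_class)) {
    ll <- ll - 2 * bd_log_surv(sub$root_age, r, eps)
  }
  if (!is.finite(ll)) -Inf else ll
}

#' Richness-annotated backbone tree
#'
#' A chronogram whose tips stand for terminally unresolved clades of known
#' extant species richness, making the tree complete in taxa while
#' incompletely resolved.
#'
#' @param tree rooted ultrametric `phylo`.
#' @param richness named integer vector: extant species count (`>= 1`) for
#'   every tip label. Unnamed vectors are matched positionally to
#'   `tree$tip.label`.
#' @param rtol ultrametricity tolerance.
#' @return object of class `richness_tree` with `tree`, `richness` (named, in
#'   tip order), `total_richness`.
#' @export
richness_tree <- function(tree, richness, rtol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  if (!check_ultrametric(tree, rtol)) halt("backbone must be ultrametric")
  if (is.null(names(richness))) {
    if (length(richness) != ape::Ntip(tree)) {
      halt("unnamed `richness` must have one entry per tip")
    }
    names(richness) <- tree$tip.label
  }
  missing <- setdiff(tree$tip.label, names(richness))
  if (length(missing) > 0L) {
    halt("richness missing for tips: %s", paste(missing, collapse = ", "))
  }
  richness <- richness[tree$tip.label]
  if (any(richness < 1) || any(richness != round(richness))) {
    halt("richness must be integer >= 1 for every tip")
  }
  structure(list(tree = tree, richness = as.integer(richness),
                 total_richness = as.integer(sum(richness))),
            class = "richness_tree")
}

#' @export
print.richness_tree <- function(x, ...) {
  cat(sprintf("<richness_tree: %d tips, %d species total, root age %.3g>\n",
              ape::Ntip(x$tree), x$total_richness, root_age(x$tree)))
  invisible(x)
}

#' Read a tip-richness table
#'
#' TSV with columns `tip_label` and `n_species`; `#` lines ignored.
#'
#' @param path file path.
#' @return named integer vector.
#' @export
read_richness_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("tip_label", "n_species") %in% names(df))) {
    halt("richness table must have columns tip_label, n_species")
  }
  if (anyNA(df$n_species) || any(df$n_species < 1)) halt("n_species must be >= 1")
  stats::setNames(as.integer(df$n_species), df$tip_label)
}

# Map each edge to a rate class: class 1 at the root, and a shift on edge e
# reassigns e and everything tipward of it until overridden by a more tipward
# shift. shift_edges is an integer vector of edge indices; class of
# shift_edges[i] is i + 1.
edge_class_assignment <- function(tree, shift_edges) {
  edge <- tree$edge
  n_edge <- nrow(edge)
  assignment <- integer(n_edge)
  ord <- reorder_preorder(tree)
  class_of_node <- integer(ape::Ntip(tree) + tree$Nnode)
  class_of_node[ape::Ntip(tree) + 1L] <- 1L  # root in the base class
  for (i in ord) {
    cls <- class_of_node[edge[i, 1]]
    hit <- match(i, shift_edges)
    if (!is.na(hit)) cls <- hit + 1L
    assignment[i] <- cls
    class_of_node[edge[i, 2]] <- cls
  }
  assignment
}

# Edge indices in an order that visits every parent edge before its children.
reorder_preorder <- function(tree) {
  edge <- tree$edge
  order(ape::node.depth.edgelength(tree)[edge[, 1]],
        method = "radix")
}

# Maximize one class's log-likelihood over (log r, logit eps).
# Multi-start bounded quasi-Newton; also fits the Yule submodel (eps = 0).
fit_one_class <- function(sub, richness, n_starts = 5, seed = 1,
                          r_init = 0.05) {
  negll <- function(par) {
    r <- exp(par[1])
    eps <- stats::plogis(par[2])
    -class_loglik(sub, r, eps, richness = richness)
  }
  negll_yule <- function(lr) -class_loglik(sub, exp(lr), 0, richness = richness)
  lower <- c(log(1e-8), -30)
  upper <- c(log(1e4), stats::qlogis(1 - 1e-6))
  starts <- with_seed(seed, {
    cbind(log(r_init) + stats::rnorm(n_starts, 0, 1),
          stats::qlogis(stats::runif(n_starts, 0.02, 0.9)))
  })
  starts[1, ] <- c(log(r_init), stats::qlogis(0.1))  # deterministic anchor
  best <- NULL
  for (s in seq_len(n_starts)) {
    fit <- tryCatch(
      stats::optim(starts[s, ], negll, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 1e5, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    best <- list(par = c(log(r_init), 0), value = negll(c(log(r_init), 0)),
                 convergence = 99L)
  }
  yule <- stats::optimize(negll_yule, interval = c(log(1e-8), log(1e4)),
                          tol = 1e-10)
  bd <- list(r = exp(best$par[1]), eps = stats::plogis(best$par[2]),
             logL = -best$value, k = 2L, model = "bd",
             converged = identical(best$convergence, 0L))
  yu <- list(r = exp(yule$minimum), eps = 0, logL = -yule$objective,
             k = 1L, model = "yule", converged = TRUE)
  # choose the variant by its local AIC contribution
  if (2 * yu$k - 2 * yu$logL <= 2 * bd$k - 2 * bd$logL) yu else bd
}

#' Akaike Information Criterion with small-sample correction
#'
#' `AIC = 2k - 2 logL`; `AICc = AIC + 2k(k+1)/(n_obs - k - 1)`. When
#' `n_obs <= k + 1` the correction is undefined and plain AIC is returned with
#' a warning.
#'
#' @param logL log-likelihood.
#' @param k number of free parameters.
#' @param n_obs number of observations.
#' @return the AICc (or AIC fallback) score.
#' @export
aicc <- function(logL, k, n_obs) {
  aic <- 2 * k - 2 * logL
  if (n_obs <= k + 1) {
    warning("n_obs <= k + 1: falling back to uncorrected AIC")
    return(aic)
  }
  aic + 2 * k * (k + 1) / (n_obs - k - 1)
}

#' Fit a (possibly shifted) birth-death model to a richness tree
#'
#' Maximum-likelihood fit of per-class `(r, eps)` for the edge partition
#' induced by `shift_edges`. Each class's likelihood is the sum of its
#' backbone edge terms and the conditional geometric richness terms of its
#' pendant edges; classes are independent and fitted separately. Per class,
#' both the full birth-death model and the Yule submodel (`eps = 0`) are
#' fitted and the better local AIC wins.
#'
#' Parameter counting for AICc: each class contributes its own `k` (2 for BD,
#' 1 for Yule) and each shift adds one placement parameter;
#' `n_obs` = number of internal nodes + number of terminal clades.
#'
#' @param rtree a [richness_tree()].
#' @param shift_edges integer vector of edge indices (rows of
#'   `rtree$tree$edge`) carrying rate shifts; empty for the constant-rate
#'   model.
#' @param n_starts optimizer multi-starts per class (default 5).
#' @param seed integer seed for the start jitter.
#' @param reuse optional previous `bd_shift_fit` for the same tree whose shift
#'   list is a prefix of `shift_edges`: classes whose edge sets are unchanged
#'   are copied instead of refitted (identical result, the per-class seeds
#'   depend only on the class index).
#' @return object of class `bd_shift_fit`: list with `classes` (per-class
#'   fits), `shift_edges`, `assignment` (class per edge), `class_edges`,
#'   `logL`, `k`, `n_obs`, `aicc`.
#' @export
fit_bd <- function(rtree, shift_edges = integer(0), n_starts = 5, seed = 1,
                   reuse = NULL) {
  stopifnot(inherits(rtree, "richness_tree"))
  tree <- rtree$tree
  n_edge <- nrow(tree$edge)
  shift_edges <- as.integer(shift_edges)
  if (anyDuplicated(shift_edges) || any(shift_edges < 1 | shift_edges > n_edge)) {
    halt("`shift_edges` must be distinct edge indices in 1..%d", n_edge)
  }
  assignment <- edge_class_assignment(tree, shift_edges)
  parts <- bd_likelihood_parts(tree)
  r_init <- (tree$Nnode - 1L + 1L) / sum(tree$edge.length)  # crude Yule start
  class_edges <- lapply(seq_len(length(shift_edges) + 1L),
                        function(cls) which(assignment == cls))
  classes <- lapply(seq_len(length(shift_edges) + 1L), function(cls) {
    if (!is.null(reuse) && cls <= length(reuse$classes) &&
        identical(class_edges[[cls]], reuse$class_edges[[cls]])) {
      return(reuse$classes[[cls]])
    }
    sub <- parts_subset(parts, assignment, cls, root_class = (cls == 1L))
    fit_one_class(sub, rtree$richness, n_starts = n_starts,
                  seed = derive_seed(seed, "class", as.character(cls)),
                  r_init = max(r_init, 1e-6))
  })
  logL <- sum(vapply(classes, `[[`, numeric(1), "logL"))
  k <- sum(vapply(classes, `[[`, integer(1), "k")) + length(shift_edges)
  n_obs <- tree$Nnode + ape::Ntip(tree)
  structure(list(classes = classes, shift_edges = shift_edges,
                 assignment = assignment, class_edges = class_edges,
                 logL = logL, k = k, n_obs = n_obs,
                 aicc = aicc(logL, k, n_obs)),
            class = "bd_shift_fit")
}

#' @export
print.bd_shift_fit <- function(x, ...) {
  cat(sprintf("<bd_shift_fit: %d shift(s), logL = %.3f, k = %d, AICc = %.3f>\n",
              length(x$shift_edges), x$logL, x$k, x$aicc))
  for (i in seq_along(x$classes)) {
    cl <- x$classes[[i]]
    cat(sprintf("  class %d (%s): r = %.4g, eps = %.4g, logL = %.3f\n",
                i, cl$model, cl$r, cl$eps, cl$logL))
  }
  invisible(x)
}

#' Stepwise search for diversification-rate shifts
#'
#' Greedy forward selection: starting from the constant-rate model, every
#' eligible edge is tried as the location of one additional shift, the
#' classes affected by the candidate are refitted, and the best-scoring
#' candidate is accepted while it improves AICc by at least `threshold`
#' (default 4, a conventional strong-evidence cutoff). Edges descending
#' directly from the root are eligible; edges already carrying a shift are
#' not.
#'
#' @param rtree a [richness_tree()].
#' @param max_shifts maximum number of shifts to add (default 5).
#' @param threshold minimum AICc improvement to accept a shift.
#' @param n_starts,seed optimizer settings, see [fit_bd()].
#' @return the accepted `bd_shift_fit`, with a `trace` data.frame attached
#'   (one row per accepted step: step, edge, logL, k, aicc).
#' @export
stepwise_shift_search <- function(rtree, max_shifts = 5, threshold = 4,
                                  n_starts = 5, seed = 1) {
  stopifnot(inherits(rtree, "richness_tree"), max_shifts >= 0)
  current <- fit_bd(rtree, integer(0), n_starts = n_starts, seed = seed)
  trace <- data.frame(step = 0L, edge = NA_integer_, logL = current$logL,
                      k = current$k, aicc = current$aicc)
  n_edge <- nrow(rtree$tree$edge)
  step <- 0L
  while (step < max_shifts && is.finite(threshold)) {
    step <- step + 1L
    candidates <- setdiff(seq_len(n_edge), current$shift_edges)
    best <- NULL
    for (e in candidates) {
      cand <- fit_bd(rtree, c(current$shift_edges, e),
                     n_starts = n_starts, seed = seed, reuse = current)
      if (is.null(best) || cand$aicc < best$aicc) best <- cand
    }
    if (is.null(best) || best$aicc > current$aicc - threshold) break
    current <- best
    trace <- rbind(trace, data.frame(
      step = step, edge = current$shift_edges[length(current$shift_edges)],
      logL = current$logL, k = current$k, aicc = current$aicc))
  }
  current$trace <- trace
  current
}

# Stable identifier for an edge: a hash of the sorted tip labels it subtends.
edge_signature <- function(tree, edge_index) {
  tips <- tree$tip.label[descendant_tips(tree, tree$edge[edge_index, 2])]
  sprintf("%dtips-%08x", length(tips),
          derive_seed(0, sort(tips)))
}

#' Write stepwise shift-search results
#'
#' Writes the search trace as a TSV (columns `step`, `edge`, `edge_id`, `r`,
#' `eps`, `model`, `logL`, `k`, `aicc`) and, optionally, the backbone as a
#' Newick string in which every node carries a `[&class=k]` comment giving its
#' rate class.
#'
#' @param fit a `bd_shift_fit` from [stepwise_shift_search()].
#' @param rtree the fitted [richness_tree()].
#' @param table_path TSV output path.
#' @param tree_path optional annotated-Newick output path.
#' @return `table_path`, invisibly.
#' @export
write_shift_results <- function(fit, rtree, table_path, tree_path = NULL) {
  stopifnot(inherits(fit, "bd_shift_fit"), inherits(rtree, "richness_tree"))
  tr <- fit$trace
  cls <- fit$classes
  # class of the model after each accepted step: step i added class i + 1
  rows <- lapply(seq_len(nrow(tr)), function(i) {
    cl <- cls[[min(i, length(cls))]]
    data.frame(step = tr$step[i], edge = tr$edge[i],
               edge_id = if (is.na(tr$edge[i])) "root" else
                 edge_signature(rtree$tree, tr$edge[i]),
               r = cl$r, eps = cl$eps, model = cl$model,
               logL = tr$logL[i], k = tr$k[i], aicc = tr$aicc[i],
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), table_path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(tree_path)) {
    writeLines(annotated_newick(rtree$tree, fit$assignment), tree_path)
  }
  invisible(table_path)
}

# Newick with [&class=k] comments on every node (class of its parent edge;
# the root gets the base class).
annotated_newick <- function(tree, assignment) {
  ntip <- ape::Ntip(tree)
  edge <- tree$edge
  children <- split(seq_len(nrow(edge)), edge[, 1])
  rec <- function(node, edge_in) {
    cls <- if (is.na(edge_in)) 1L else assignment[edge_in]
    len <- if (is.na(edge_in)) NULL else edge[edge_in, , drop = FALSE]
    blen <- if (is.na(edge_in)) "" else
      sprintf(":%.10g", tree$edge.length[edge_in])
    if (node <= ntip) {
      sprintf("%s[&class=%d]%s", tree$tip.label[node], cls, blen)
    } else {
      kids <- children[[as.character(node)]]
      inner <- paste(vapply(kids, function(e) rec(edge[e, 2], e), character(1)),
                     collapse = ",")
      sprintf("(%s)[&class=%d]%s", inner, cls, blen)
    }
  }
  paste0(rec(ntip + 1L, NA_integer_), ";")
}
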