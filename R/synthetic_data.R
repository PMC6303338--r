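# Simulators that generate every input the other modules consume:
# birth-death chronograms, clade sizes (a Monte Carlo oracle for the richness
# likelihood), richness-annotated backbones, pseudo-posterior tree samples,
# and Gaussian age posteriors with known truth. All are deterministic under a
# fixed seed; the simulators stay independent of the likelihood formulas they
# are used to test (direct event-by-event simulation, never the closed form).

#' Simulate a birth-death chronogram
#'
#' Gillespie simulation started from the two lineages descending from the
#' root. Extinct lineages are pruned from the returned tree. The simulation is
#' conditioned on reaching the stop state by rejection: attempts in which the
#' process dies out (or, under `n_tips` stopping, goes extinct before reaching
#' `n_tips` extant lineages) are discarded, up to `max_attempts`.
#'
#' With `n_tips` stopping, the present is placed uniformly at random inside
#' the interval during which exactly `n_tips` lineages exist, so pendant
#' branches have positive length.
#'
#' @param birth_rate speciation rate per My.
#' @param death_rate extinction rate per My (`< birth_rate` for `n_tips`
#'   stopping).
#' @param n_tips stop when this many extant lineages exist (exclusive with
#'   `time`).
#' @param time stop at this elapsed time in My (exclusive with `n_tips`).
#' @param seed integer seed.
#' @param max_attempts rejection cap (default 10000).
#' @return a rooted ultrametric `phylo` with tips `t1, t2, ...`.
#' @examples
#' tr <- simulate_bd_tree(1, 0, n_tips = 50, seed = 1)
#' @export
simulate_bd_tree <- function(birth_rate, death_rate = 0, n_tips = NULL,
                             time = NULL, seed = NULL, max_attempts = 10000) {
  if (birth_rate <= 0 || death_rate < 0) halt("rates must be positive / non-negative")
  if (is.null(n_tips) == is.null(time)) halt("give exactly one of `n_tips` or `time`")
  if (!is.null(n_tips)) {
    if (n_tips < 2) halt("`n_tips` must be >= 2")
    if (birth_rate <= death_rate) halt("n-tip stopping needs birth_rate > death_rate")
  }
  with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      tr <- bd_sim_attempt(birth_rate, death_rate, n_tips, time)
      if (!is.null(tr)) return(tr)
    }
    halt("no attempt reached the stop state in %d tries", max_attempts)
  })
}

# One simulation attempt; NULL on failure (extinction before the stop state).
bd_sim_attempt <- function(lambda, mu, n_tips, time_stop) {
  # per-lineage records, grown as vectors
  parent <- c(0L, 0L)          # 0 = root
  t_birth <- c(0, 0)
  t_end <- c(NA_real_, NA_real_)
  is_split <- c(FALSE, FALSE)
  alive <- c(1L, 2L)
  t <- 0
  total_rate <- lambda + mu
  repeat {
    k <- length(alive)
    if (k == 0L) return(NULL)
    if (!is.null(n_tips) && k == n_tips) {
      # present placed uniformly within the k == n_tips interval
      present <- t + stats::rexp(1, k * total_rate) * stats::runif(1)
      break
    }
    dt <- stats::rexp(1, k * total_rate)
    if (!is.null(time_stop) && t + dt > time_stop) {
      present <- time_stop
      break
    }
    t <- t + dt
    i <- alive[sample.int(k, 1L)]
    if (stats::runif(1) < lambda / total_rate) {
      t_end[i] <- t; is_split[i] <- TRUE
      parent <- c(parent, i, i)
      t_birth <- c(t_birth, t, t)
      t_end <- c(t_end, NA_real_, NA_real_)
      is_split <- c(is_split, FALSE, FALSE)
      alive <- c(alive[alive != i], length(parent) - 1L, length(parent))
    } else {
      t_end[i] <- t
      alive <- alive[alive != i]
    }
  }
  extinct <- which(!is_split & !is.na(t_end))
  t_end[is.na(t_end)] <- present
  children <- split(seq_along(parent), parent)
  tip_counter <- 0L
  nwk <- function(i) {
    len <- t_end[i] - t_birth[i]
    if (is_split[i]) {
      kids <- children[[as.character(i)]]
      sprintf("(%s,%s):%.12g", nwk(kids[1]), nwk(kids[2]), len)
    } else {
      tip_counter <<- tip_counter + 1L
      sprintf("%s%d:%.12g", if (i %in% extinct) "x" else "t", tip_counter, len)
    }
  }
  tr <- ape::read.tree(text = sprintf("(%s,%s);", nwk(1L), nwk(2L)))
  dead <- grep("^x", tr$tip.label, value = TRUE)
  if (length(dead) > 0L) {
    if (ape::Ntip(tr) - length(dead) < 2L) return(NULL)
    tr <- ape::drop.tip(tr, dead)
  }
  if (!is.null(n_tips) && ape::Ntip(tr) != n_tips) return(NULL)
  tr$tip.label <- sprintf("t%d", seq_len(ape::Ntip(tr)))  # contiguous labels
  tr
}

#' Simulate extant clade sizes conditioned on survival
#'
#' Direct event-by-event simulation of the number of extant descendants of a
#' single lineage after `t` My; attempts ending in extinction are resimulated,
#' so the result is conditioned on at least one survivor. Serves as the
#' independent Monte Carlo oracle for [clade_richness_logprob()].
#'
#' @param t elapsed time in My, `> 0`.
#' @param params a [bd_params()].
#' @param n_rep number of replicate clades (default 1).
#' @param seed integer seed.
#' @return integer vector of length `n_rep`, all `>= 1`.
#' @export
simulate_clade_size <- function(t, params, n_rep = 1, seed = NULL) {
  stopifnot(inherits(params, "bd_params"), t > 0, n_rep >= 1)
  lambda <- params$lambda
  mu <- params$mu
  total <- lambda + mu
  p_birth <- lambda / total
  with_seed(seed, {
    out <- integer(n_rep)
    todo <- seq_len(n_rep)
    while (length(todo) > 0L) {
      m <- length(todo)
      cnt <- rep(1L, m)
      tm <- numeric(m)
      active <- rep(TRUE, m)
      while (any(active)) {
        idx <- which(active)
        dt <- stats::rexp(length(idx)) / (cnt[idx] * total)
        tm[idx] <- tm[idx] + dt
        past <- tm[idx] > t
        delta <- ifelse(stats::runif(length(idx)) < p_birth, 1L, -1L)
        delta[past] <- 0L
        cnt[idx] <- cnt[idx] + delta
        active[idx] <- !past & cnt[idx] > 0L
      }
      ok <- cnt > 0L
      out[todo[ok]] <- cnt[ok]
      todo <- todo[!ok]  # extinct: resimulate (condition on survival)
    }
    out
  })
}

#' Collapse clades of a resolved tree into a richness-annotated backbone
#'
#' Each mapped clade is collapsed to its representative tip, which inherits
#' the clade's species count; unmapped tips keep richness 1. Total species
#' count is conserved, and because only whole monophyletic clades are
#' collapsed, every collapsed tip's stem age equals the original clade's stem
#' age.
#'
#' @param full_tree rooted ultrametric `phylo`.
#' @param clade_map named list: representative tip label -> character vector
#'   of the clade's tip labels (must include the representative, be
#'   monophyletic in `full_tree`, and be disjoint from other entries).
#' @return a [richness_tree()].
#' @examples
#' tr <- simulate_bd_tree(1, 0, n_tips = 20, seed = 7)
#' taxa <- tr$tip.label[descendant_tips(tr, mrca_node(tr, c("t1", "t2")))]
#' \dontrun{rt <- make_richness_tree(tr, setNames(list(taxa), taxa[1]))}
#' @export
make_richness_tree <- function(full_tree, clade_map = list()) {
  stopifnot(inherits(full_tree, "phylo"))
  all_mapped <- unlist(clade_map, use.names = FALSE)
  if (anyDuplicated(all_mapped)) halt("clade_map sets must be disjoint")
  reps <- names(clade_map)
  if (length(clade_map) > 0L && (is.null(reps) || any(reps == ""))) {
    halt("clade_map must be named by representative tips")
  }
  tree <- full_tree
  richness <- stats::setNames(rep(1L, ape::Ntip(full_tree)), full_tree$tip.label)
  drop <- character(0)
  for (rep_tip in reps) {
    taxa <- clade_map[[rep_tip]]
    if (!rep_tip %in% taxa) halt("representative '%s' must be in its own set", rep_tip)
    clade_taxa(full_tree, taxa)  # validates presence
    if (!is_monophyletic(full_tree, taxa)) {
      halt("clade for '%s' is not monophyletic; stem ages would not be preserved",
           rep_tip)
    }
    richness[rep_tip] <- length(taxa)
    drop <- c(drop, setdiff(taxa, rep_tip))
  }
  if (length(drop) > 0L) {
    tree <- ape::drop.tip(tree, drop)
    richness <- richness[tree$tip.label]
  }
  richness_tree(tree, richness)
}

#' Simulate a pseudo-posterior sample of chronograms
#'
#' A stand-in for MCMC output with known truth: each replicate applies one
#' tree-wide scale factor `s ~ LogNormal(-cv^2/2, cv)` (unit mean) and then
#' perturbs internal node ages root-to-tip, resampling each age uniformly in a
#' symmetric window of half-width `min(cv * age, parent_age - age,
#' age - oldest_child_age)`. Symmetry keeps each node age conditionally
#' unbiased; the clipping guarantees parent-older-than-child throughout.
#' Topology and tip set are unchanged; tips stay at age 0.
#'
#' This emulates the correlated uncertainty of a posterior tree sample but is
#' not an MCMC: draws are independent across replicates.
#'
#' @param base_tree rooted ultrametric `phylo` (the "true" chronogram).
#' @param age_cv coefficient of variation of the perturbations, `>= 0`
#'   (0 returns identical copies).
#' @param n_trees number of replicate trees.
#' @param seed integer seed.
#' @return a `tree_sample` (see [read_trees()]).
#' @export
simulate_pseudo_posterior <- function(base_tree, age_cv, n_trees, seed = NULL) {
  stopifnot(inherits(base_tree, "phylo"), age_cv >= 0, n_trees >= 1)
  if (!check_ultrametric(base_tree)) halt("`base_tree` must be ultrametric")
  ntip <- ape::Ntip(base_tree)
  base_ages <- node_ages(base_tree)
  edge <- base_tree$edge
  ord <- reorder_preorder(base_tree)
  with_seed(seed, {
    trees <- lapply(seq_len(n_trees), function(i) {
      if (age_cv == 0) return(base_tree)
      s <- stats::rlnorm(1, -age_cv^2 / 2, age_cv)
      ages <- base_ages * s
      for (e in ord) {
        node <- edge[e, 2]
        if (node <= ntip) next
        a <- ages[node]
        kids <- edge[edge[, 1] == node, 2]
        oldest_kid <- max(ages[kids])
        w <- min(age_cv * a, ages[edge[e, 1]] - a, a - oldest_kid)
        if (w > 0) ages[node] <- stats::runif(1, a - w, a + w)
      }
      # root: clipped only by its oldest child
      root <- ntip + 1L
      a <- ages[root]
      w <- min(age_cv * a, a - max(ages[edge[edge[, 1] == root, 2]]))
      if (w > 0) ages[root] <- stats::runif(1, a - w, a + w)
      tr <- base_tree
      tr$edge.length <- ages[edge[, 1]] - ages[edge[, 2]]
      tr
    })
    structure(list(trees = trees, source = "pseudo_posterior",
                   burnin_fraction = 0, n_input = as.integer(n_trees),
                   n_retained = as.integer(n_trees)),
              class = "tree_sample")
  })
}

#' Simulate a richness tree with (optionally) one engineered rate shift
#'
#' Builds the test bed for shift-detection operating characteristics by
#' simulating the shifted birth-death process itself: a two-class Gillespie
#' run over `duration` My in which, at a stem age `t_s` drawn so that the
#' shifted clade's expected size lies in `[min_clade, max_clade]`, one lineage
#' alive at that moment (chosen uniformly) switches to net rate
#' `fold * base$r`; all its descendants inherit the shifted rates. Extinct
#' lineages are pruned and the full tree is then collapsed into a terminally
#' unresolved richness tree: every maximal clade younger than a cutoff age
#' becomes one tip carrying the clade's species count ([make_richness_tree()]).
#' Both the node times and the tip richness of the result are therefore
#' realizations of the one-shift model.
#'
#' An attempt is accepted when the collapsed backbone has 3-8 tips inside the
#' shifted clade and 8-40 tips outside it (so the search problem stays
#' desk-sized); up to `max_attempts` attempts are made per seed and `NULL` is
#' returned if none qualifies, in which case the caller moves to the next
#' seed. With `fold = 1` no shift is introduced and the same collapse is
#' applied to a constant-rate tree (10-40 backbone tips required).
#'
#' @param seed integer seed (drives the whole scenario).
#' @param base [bd_params()] of the background class (default r = 0.4, pure
#'   birth).
#' @param fold net-rate fold change of the shifted class; 1 means no shift.
#' @param duration total tree depth in My (default 6).
#' @param contrast_band range of the expected shifted-to-background
#'   tip-richness ratio (default 10 to 300: the lower end of the
#'   10-10,000-fold design band, upper end capped to keep clade simulation
#'   desk-sized).
#' @param max_attempts rejection cap per seed (default 50).
#' @return `NULL` if no attempt qualifies, else a list with `rtree`
#'   (a [richness_tree()]), `target_edge` (index of the collapsed-tree edge
#'   ending at the shifted clade's crown, `NA` when `fold = 1`), and
#'   `shifted_tips` (tip indices of the collapsed tree).
#' @export
simulate_shift_scenario <- function(seed, base = bd_params(0.4, 0), fold = 10,
                                    duration = 6, contrast_band = c(10, 300),
                                    max_attempts = 50) {
  stopifnot(inherits(base, "bd_params"), fold >= 1)
  r_hi <- base$r * fold
  with_seed(derive_seed(seed, "shift_scenario"), {
    for (attempt in seq_len(max_attempts)) {
      if (fold > 1) {
        contrast <- exp(stats::runif(1, log(contrast_band[1]), log(contrast_band[2])))
        cutoff <- log(contrast) / (r_hi - base$r)
        t_s <- cutoff + log(5) / r_hi  # ~5 backbone tips in the shifted clade
      } else {
        t_s <- NA_real_
        cutoff <- 0.65
      }
      sim <- bd_shift_sim_attempt(base, fold, duration, t_s)
      if (is.null(sim)) next
      sc <- collapse_shift_sim(sim, cutoff, fold)
      if (is.null(sc)) next
      return(sc)
    }
    NULL
  })
}

# Two-class Gillespie simulation: base rates everywhere, switching one random
# lineage (and its descendants) to fold * rates at age t_s before the present.
# Uses the caller's RNG stream. Returns the pruned extant tree plus the
# shifted tip labels, or NULL (extinction / no lineage alive at the shift).
bd_shift_sim_attempt <- function(base, fold, duration, t_s) {
  lb <- base$lambda; db <- base$mu
  lh <- lb * fold; dh <- db * fold
  shift_time <- if (is.na(t_s)) Inf else duration - t_s
  cap <- 50000L  # hard safety cap on lineage records
  parent <- integer(cap); t_birth <- numeric(cap); t_end <- rep(NA_real_, cap)
  is_split <- logical(cap); hi <- logical(cap)
  parent[1:2] <- 0L; n_rec <- 2L
  alive <- c(1L, 2L)
  t <- 0
  shifted <- FALSE
  repeat {
    k <- length(alive)
    if (k == 0L) return(NULL)
    n_hi <- sum(hi[alive])
    rate <- (k - n_hi) * (lb + db) + n_hi * (lh + dh)
    dt <- stats::rexp(1, rate)
    if (!shifted && t + dt > shift_time) {
      # shift first: tag one lineage alive at the shift time
      i <- alive[sample.int(k, 1L)]
      hi[i] <- TRUE
      shifted <- TRUE
      t <- shift_time
      next
    }
    if (t + dt > duration) break
    t <- t + dt
    # pick a lineage proportional to its class total rate
    w <- ifelse(hi[alive], lh + dh, lb + db)
    i <- alive[sample.int(k, 1L, prob = w)]
    p_birth <- if (hi[i]) lh / (lh + dh) else lb / (lb + db)
    if (stats::runif(1) < p_birth) {
      if (n_rec + 2L > cap) return(NULL)
      t_end[i] <- t; is_split[i] <- TRUE
      kid <- n_rec + 1:2
      parent[kid] <- i; t_birth[kid] <- t; hi[kid] <- hi[i]
      n_rec <- n_rec + 2L
      alive <- c(alive[alive != i], kid)
    } else {
      t_end[i] <- t
      alive <- alive[alive != i]
    }
  }
  if (!is.na(t_s) && !shifted) return(NULL)
  idx <- seq_len(n_rec)
  extinct <- idx[!is_split[idx] & !is.na(t_end[idx])]
  t_end[idx][is.na(t_end[idx])] <- duration
  children <- split(idx, parent[idx])
  tip_counter <- 0L
  shifted_labels <- character(0)
  nwk <- function(i) {
    len <- t_end[i] - t_birth[i]
    if (is_split[i]) {
      kids <- children[[as.character(i)]]
      sprintf("(%s,%s):%.12g", nwk(kids[1]), nwk(kids[2]), len)
    } else {
      tip_counter <<- tip_counter + 1L
      lab <- sprintf("%s%d", if (i %in% extinct) "x" else "t", tip_counter)
      if (hi[i] && !(i %in% extinct)) shifted_labels <<- c(shifted_labels, lab)
      sprintf("%s:%.12g", lab, len)
    }
  }
  txt <- sprintf("(%s,%s);", nwk(1L), nwk(2L))
  tr <- ape::read.tree(text = txt)
  dead <- grep("^x", tr$tip.label, value = TRUE)
  if (ape::Ntip(tr) - length(dead) < 2L) return(NULL)
  if (length(dead) > 0L) tr <- ape::drop.tip(tr, dead)
  list(tree = tr, shifted_labels = shifted_labels)
}

# Collapse a full simulated tree at `cutoff`: every maximal clade younger
# than the cutoff becomes one richness tip. Enforces the backbone-size
# acceptance rules and locates the collapsed-tree edge of the shifted crown.
collapse_shift_sim <- function(sim, cutoff, fold) {
  tree <- sim$tree
  ntip <- ape::Ntip(tree)
  ages <- node_ages(tree)
  clade_map <- list()
  for (node in ntip + seq_len(tree$Nnode)) {
    parent <- parent_node(tree, node)
    if (ages[node] < cutoff && (is.na(parent) || ages[parent] >= cutoff)) {
      tips <- tree$tip.label[descendant_tips(tree, node)]
      clade_map[[tips[1]]] <- tips
    }
  }
  rtree <- make_richness_tree(tree, clade_map)
  bt <- rtree$tree
  if (fold > 1) {
    kept_shifted <- intersect(bt$tip.label, sim$shifted_labels)
    # a collapsed tip is shifted iff its representative is (clades are
    # class-pure: the shift predates the cutoff)
    n_in <- length(kept_shifted)
    n_out <- ape::Ntip(bt) - n_in
    if (n_in < 3L || n_in > 8L || n_out < 8L || n_out > 40L) return(NULL)
    crown <- mrca_node(bt, kept_shifted)
    if (!is_monophyletic(bt, kept_shifted)) return(NULL)
    target <- match(crown, bt$edge[, 2])
    if (is.na(target)) return(NULL)  # shifted crown is the root
    list(rtree = rtree, target_edge = target,
         shifted_tips = match(kept_shifted, bt$tip.label))
  } else {
    if (ape::Ntip(bt) < 10L || ape::Ntip(bt) > 40L) return(NULL)
    list(rtree = rtree, target_edge = NA_integer_, shifted_tips = integer(0))
  }
}

#' Gaussian age posteriors with known truth
#'
#' Direct fixtures for the comparison machinery: i.i.d. normal draws truncated
#' at 0 (negatives resampled), one posterior per spec row.
#'
#' @param specs a data.frame with columns `label`, `mean` (Ma), `sd` (My,
#'   `>= 0`), `n` (`>= 2`), and optionally `mode` (default "crown").
#' @param seed integer root seed; each row gets a label-derived sub-seed.
#' @return named list of `age_posterior` objects.
#' @examples
#' make_gaussian_age_posteriors(
#'   data.frame(label = c("a", "b"), mean = c(484, 482), sd = c(23, 3), n = 1000),
#'   seed = 1)
#' @export
make_gaussian_age_posteriors <- function(specs, seed = 1) {
  need <- c("label", "mean", "sd", "n")
  if (!is.data.frame(specs) || !all(need %in% names(specs))) {
    halt("`specs` must be a data.frame with columns %s", paste(need, collapse = ", "))
  }
  if (any(specs$sd < 0) || any(specs$n < 2)) halt("need sd >= 0 and n >= 2")
  if (is.null(specs$mode)) specs$mode <- "crown"
  out <- lapply(seq_len(nrow(specs)), function(i) {
    ages <- with_seed(derive_seed(seed, "gaussian_posterior", specs$label[i]), {
      x <- stats::rnorm(specs$n[i], specs$mean[i], specs$sd[i])
      while (any(x < 0)) {
        x[x < 0] <- stats::rnorm(sum(x < 0), specs$mean[i], specs$sd[i])
      }
      x
    })
    age_posterior(specs$label[i], ages, mode = specs$mode[i])
  })
  stats::setNames(out, specs$label)
}
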