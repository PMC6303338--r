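# Pipeline orchestration: validated run configuration, the compare stage
# (tree samples -> age posteriors -> pairwise difference summaries), and the
# shifts stage (backbone + richness -> stepwise shift search). A single root
# seed drives everything; each (stage, pair) derives its own sub-seed, so
# outputs are byte-identical across reruns of the same configuration.

#' Build and validate a run configuration
#'
#' Inputs may be given either as tree files plus clade definitions (the
#' posteriors are then extracted per pair) or as pre-extracted age tables from
#' [write_age_table()]. Defaults mirror the comparison settings used
#' throughout: 100000 paired draws, 95% HPD, difference ranges of 1, 5, 10,
#' 20, 40, 60 My, symmetric-about-zero range semantics.
#'
#' @param pairs data.frame with columns `clade_a`, `clade_b` (and optionally
#'   `mode_a`, `mode_b`, defaulting to "crown") naming the posteriors to
#'   compare; by convention `a` is the fungal and `b` the plant side, so
#'   positive differences mean the `a` event is older.
#' @param trees_a,trees_b character vectors of tree-sample paths (side a / b).
#' @param clades_a,clades_b named lists: clade name -> character vector of tip
#'   labels, for extraction from `trees_a` / `trees_b`.
#' @param age_table_a,age_table_b alternative inputs: age-table TSV paths.
#' @param burnin_a,burnin_b per-file burn-in fractions.
#' @param n_draws paired Monte Carlo draws per comparison.
#' @param hpd_mass HPD interval mass.
#' @param ranges difference ranges in My.
#' @param range_semantics `"width_centered"`, `"one_sided"`, or `"half_width"`.
#' @param monophyly_policy `"mrca"` or `"strict"` for extraction.
#' @param seed root seed.
#' @param out_dir output directory (created if needed).
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(pairs,
                       trees_a = NULL, trees_b = NULL,
                       clades_a = NULL, clades_b = NULL,
                       age_table_a = NULL, age_table_b = NULL,
                       burnin_a = 0, burnin_b = 0,
                       n_draws = 100000, hpd_mass = 0.95,
                       ranges = c(1, 5, 10, 20, 40, 60),
                       range_semantics = c("width_centered", "one_sided", "half_width"),
                       monophyly_policy = "mrca",
                       seed = 1, out_dir = ".") {
  range_semantics <- match.arg(range_semantics)
  if (!is.data.frame(pairs) || !all(c("clade_a", "clade_b") %in% names(pairs))) {
    halt("`pairs` must be a data.frame with columns clade_a, clade_b")
  }
  if (is.null(pairs$mode_a)) pairs$mode_a <- "crown"
  if (is.null(pairs$mode_b)) pairs$mode_b <- "crown"
  for (side in c("a", "b")) {
    tab <- get(paste0("age_table_", side))
    trs <- get(paste0("trees_", side))
    if (is.null(tab) && is.null(trs)) {
      halt("side %s needs either tree files or an age table", side)
    }
    for (f in c(tab, trs)) {
      if (!file.exists(f)) halt("input file does not exist: %s", f)
    }
  }
  stopifnot(n_draws >= 1, hpd_mass > 0, hpd_mass < 1, all(ranges > 0))
  structure(list(pairs = pairs, trees_a = trees_a, trees_b = trees_b,
                 clades_a = clades_a, clades_b = clades_b,
                 age_table_a = age_table_a, age_table_b = age_table_b,
                 burnin_a = burnin_a, burnin_b = burnin_b,
                 n_draws = n_draws, hpd_mass = hpd_mass, ranges = ranges,
                 range_semantics = range_semantics,
                 monophyly_policy = monophyly_policy,
                 seed = seed, out_dir = out_dir),
            class = "run_config")
}

# Serialize a config into "#"-prefixed provenance header lines.
config_header <- function(config) {
  keep <- config[!vapply(config, is.null, logical(1))]
  keep$pairs <- NULL
  json <- jsonlite::toJSON(keep, auto_unbox = TRUE, digits = NA)
  c(sprintf("# phylochron %s", as.character(utils::packageVersion("phylochron"))),
    sprintf("# config %s", json))
}

# Posteriors for one side: named "<clade>.<mode>" like posterior_label().
side_posteriors <- function(config, side) {
  tab <- config[[paste0("age_table_", side)]]
  if (!is.null(tab)) return(read_age_table(tab))
  sample <- read_trees(config[[paste0("trees_", side)]],
                       burnin_fraction = config[[paste0("burnin_", side)]])
  clades <- config[[paste0("clades_", side)]]
  names_needed <- unique(config$pairs[[paste0("clade_", side)]])
  out <- list()
  for (nm in names_needed) {
    if (!nm %in% names(clades)) halt("no clade definition for '%s' (side %s)", nm, side)
    modes <- unique(config$pairs[[paste0("mode_", side)]][
      config$pairs[[paste0("clade_", side)]] == nm])
    for (mode in modes) {
      cd <- clade_definition(nm, clades[[nm]], mode = mode)
      out[[paste(nm, mode, sep = ".")]] <-
        extract_age_posterior(sample, cd, policy = config$monophyly_policy)
    }
  }
  out
}

#' Run the full comparison stage
#'
#' Extracts (or loads) the age posteriors named in `config$pairs`, runs
#' [summarize_comparison()] for every pair with a pair-specific derived seed,
#' and writes a comparison TSV (one row per pair, `#`-prefixed provenance
#' header embedding the configuration) plus a log. Identical configuration and
#' seed give byte-identical TSV output.
#'
#' @param config a [run_config()].
#' @return the comparison data.frame, invisibly; files
#'   `comparison.tsv` and `compare.log` are written under `config$out_dir`.
#' @export
run_compare <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("phylochron %s | R %s",
                         as.character(utils::packageVersion("phylochron")),
                         paste(R.version$major, R.version$minor, sep = ".")),
                 sprintf("root seed %d", config$seed))
  post_a <- tryCatch(side_posteriors(config, "a"),
                     error = function(e) halt("stage tree_io (side a): %s", conditionMessage(e)))
  post_b <- tryCatch(side_posteriors(config, "b"),
                     error = function(e) halt("stage tree_io (side b): %s", conditionMessage(e)))
  rows <- vector("list", nrow(config$pairs))
  for (i in seq_len(nrow(config$pairs))) {
    p <- config$pairs[i, ]
    key_a <- paste(p$clade_a, p$mode_a, sep = ".")
    key_b <- paste(p$clade_b, p$mode_b, sep = ".")
    pair_label <- paste(key_a, key_b, sep = "_vs_")
    if (is.null(post_a[[key_a]])) halt("stage age_compare (%s): no posterior '%s'", pair_label, key_a)
    if (is.null(post_b[[key_b]])) halt("stage age_compare (%s): no posterior '%s'", pair_label, key_b)
    t0 <- proc.time()[["elapsed"]]
    rec <- tryCatch(
      summarize_comparison(post_a[[key_a]], post_b[[key_b]],
                           n = config$n_draws,
                           seed = derive_seed(config$seed, "compare", pair_label),
                           hpd_mass = config$hpd_mass, ranges = config$ranges,
                           semantics = config$range_semantics),
      error = function(e) halt("stage age_compare (%s): %s", pair_label, conditionMessage(e)))
    rows[[i]] <- as.data.frame(rec)
    log_lines <- c(log_lines, sprintf("pair %s: %.2f s", pair_label,
                                      proc.time()[["elapsed"]] - t0))
  }
  result <- do.call(rbind, rows)
  tsv <- file.path(config$out_dir, "comparison.tsv")
  con <- file(tsv, "w", encoding = "UTF-8")
  writeLines(config_header(config), con)
  utils::write.table(result, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  writeLines(log_lines, file.path(config$out_dir, "compare.log"))
  invisible(result)
}

#' Run the diversification-shift stage
#'
#' Reads a backbone chronogram and a tip-richness TSV, runs
#' [stepwise_shift_search()], and writes the shift table, the class-annotated
#' Newick, and a log under `out_dir`.
#'
#' @param tree_path backbone tree file (Newick or NEXUS; first tree used).
#' @param richness_path richness TSV (`tip_label`, `n_species`).
#' @param out_dir output directory.
#' @param max_shifts,threshold,n_starts,seed search settings, see
#'   [stepwise_shift_search()].
#' @return the `bd_shift_fit`, invisibly; files `shifts.tsv`,
#'   `shifts_annotated.nwk` and `shifts.log` are written.
#' @export
run_shifts <- function(tree_path, richness_path, out_dir = ".",
                       max_shifts = 5, threshold = 4, n_starts = 5, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tree <- read_trees(tree_path)$trees[[1]]
  richness <- read_richness_table(richness_path)
  rtree <- richness_tree(tree, richness)
  t0 <- proc.time()[["elapsed"]]
  fit <- stepwise_shift_search(rtree, max_shifts = max_shifts,
                               threshold = threshold, n_starts = n_starts,
                               seed = seed)
  write_shift_results(fit, rtree, file.path(out_dir, "shifts.tsv"),
                      file.path(out_dir, "shifts_annotated.nwk"))
  writeLines(c(sprintf("phylochron %s | seed %d | threshold %g",
                       as.character(utils::packageVersion("phylochron")), seed, threshold),
               sprintf("%d shift(s) accepted in %.2f s",
                       length(fit$shift_edges), proc.time()[["elapsed"]] - t0)),
             file.path(out_dir, "shifts.log"))
  invisible(fit)
}
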