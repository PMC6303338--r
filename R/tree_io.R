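# Reading posterior tree samples and extracting per-clade node-age posteriors.
#
# A chronogram is represented as an ape "phylo" object: rooted, with branch
# lengths in millions of years (My), tips at the present (age 0). Node ages
# are measured backward from the present, so the root carries the largest age.

#' Define a clade by a taxon set
#'
#' A clade definition names a set of tip labels and says whether ages should
#' be read at the crown node (MRCA of the taxa) or at its stem (the parent of
#' the MRCA, i.e. the divergence from the sister lineage).
#'
#' @param name short label for the clade.
#' @param taxa non-empty character vector of tip labels.
#' @param mode `"crown"` or `"stem"`.
#' @return an object of class `clade_definition`.
#' @examples
#' clade_definition("glomeromycotina", c("t1", "t2", "t3"), mode = "crown")
#' @export
clade_definition <- function(name, taxa, mode = c("crown", "stem")) {
  mode <- match.arg(mode)
  if (!is_string(name)) halt("`name` must be a single string")
  taxa <- unique(as.character(taxa))
  if (length(taxa) == 0L || anyNA(taxa)) halt("`taxa` must be a non-empty character vector")
  structure(list(name = name, taxa = taxa, mode = mode),
            class = "clade_definition")
}

#' @export
print.clade_definition <- function(x, ...) {
  cat(sprintf("<clade '%s' (%s): %d taxa>\n", x$name, x$mode, length(x$taxa)))
  invisible(x)
}

# Coerce taxa / clade_definition inputs to a validated taxon vector.
clade_taxa <- function(tree, x) {
  taxa <- if (inherits(x, "clade_definition")) x$taxa else unique(as.character(x))
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing) > 0L) {
    halt("taxa not found in tree: %s", paste(missing, collapse = ", "))
  }
  taxa
}

#' Test whether a tree is ultrametric within a relative tolerance
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param rtol relative tolerance: the max and min root-to-tip path lengths
#'   may differ by at most `rtol * root_age`.
#' @return `TRUE` or `FALSE`.
#' @export
check_ultrametric <- function(tree, rtol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  if (ape::Ntip(tree) < 2L) return(TRUE)
  if (is.null(tree$edge.length)) halt("tree has no branch lengths")
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  span <- max(depths) - min(depths)
  span <= rtol * max(depths)
}

# Ages of every node (tips then internals, ape numbering), backward from the
# present. Strict mode requires ultrametricity within rtol and uses the
# deepest tip as the root age; relaxed mode normalizes by the mean
# root-to-tip path instead of rejecting.
node_ages <- function(tree, relax = FALSE, rtol = 1e-6) {
  if (is.null(tree$edge.length)) halt("tree has no branch lengths")
  ntip <- ape::Ntip(tree)
  depths <- ape::node.depth.edgelength(tree)
  tip_depths <- depths[seq_len(ntip)]
  if (!relax && ntip >= 2L) {
    span <- max(tip_depths) - min(tip_depths)
    if (span > rtol * max(tip_depths)) {
      halt(paste0("tree is not ultrametric within rtol = %g ",
                  "(root-to-tip span %g on root age %g); ",
                  "use relax = TRUE to normalize by the mean path"),
           rtol, span, max(tip_depths))
    }
  }
  root_age <- if (relax) mean(tip_depths) else max(tip_depths)
  ages <- pmax(root_age - depths, 0)
  ages[seq_len(ntip)] <- 0  # tips are the present by definition
  ages
}

#' Root age of a chronogram
#'
#' @inheritParams check_ultrametric
#' @param relax if `TRUE`, use the mean root-to-tip path length instead of
#'   requiring ultrametricity.
#' @return age of the root in My.
#' @export
root_age <- function(tree, relax = FALSE, rtol = 1e-6) {
  ntip <- ape::Ntip(tree)
  ages <- node_ages(tree, relax = relax, rtol = rtol)
  ages[ntip + 1L]
}

#' Most recent common ancestor of a taxon set
#'
#' For a single taxon the tip itself is returned, so crown ages of singleton
#' "clades" are 0 and their stem ages are the parent-node age.
#'
#' @param tree a rooted `phylo`.
#' @param taxa character vector of tip labels, or a [clade_definition()].
#' @return integer node id (ape numbering: tips `1..Ntip`, root `Ntip + 1`).
#' @export
mrca_node <- function(tree, taxa) {
  stopifnot(inherits(tree, "phylo"))
  taxa <- clade_taxa(tree, taxa)
  if (length(taxa) == 1L) return(match(taxa, tree$tip.label))
  ape::getMRCA(tree, taxa)
}

#' Is a taxon set monophyletic in a tree?
#'
#' `TRUE` iff the descendant tip set of `mrca_node(tree, taxa)` equals `taxa`.
#'
#' @inheritParams mrca_node
#' @return logical.
#' @export
is_monophyletic <- function(tree, taxa) {
  taxa <- clade_taxa(tree, taxa)
  node <- mrca_node(tree, taxa)
  if (node <= ape::Ntip(tree)) return(TRUE)  # single tip
  desc <- tree$tip.label[descendant_tips(tree, node)]
  setequal(desc, taxa)
}

#' Tip indices descending from a node
#'
#' @param tree a rooted `phylo`.
#' @param node internal node or tip id (a tip returns itself).
#' @return sorted integer vector of tip indices; labels via
#'   `tree$tip.label[...]`.
#' @export
descendant_tips <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(node)
  # iterative stack walk; trees here are small-to-moderate
  out <- integer(0)
  stack <- node
  children <- split(tree$edge[, 2], tree$edge[, 1])
  while (length(stack) > 0L) {
    cur <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    kids <- children[[as.character(cur)]]
    tips <- kids[kids <= ntip]
    out <- c(out, tips)
    stack <- c(stack, kids[kids > ntip])
  }
  sort(out)
}

# Parent node id, or NA for the root.
parent_node <- function(tree, node) {
  i <- match(node, tree$edge[, 2])
  if (is.na(i)) NA_integer_ else tree$edge[i, 1]
}

#' Crown age of a clade in one tree
#'
#' Age of the MRCA of the clade's taxa, measured back from the present.
#' Singleton clades have crown age 0.
#'
#' @inheritParams mrca_node
#' @inheritParams root_age
#' @return age in My.
#' @export
crown_age <- function(tree, taxa, relax = FALSE, rtol = 1e-6) {
  node <- mrca_node(tree, taxa)
  node_ages(tree, relax = relax, rtol = rtol)[node]
}

#' Stem age of a clade in one tree
#'
#' Age of the parent of the clade's MRCA: the divergence of the clade's
#' lineage from its sister. Undefined when the MRCA is the root.
#'
#' @inheritParams crown_age
#' @return age in My.
#' @export
stem_age <- function(tree, taxa, relax = FALSE, rtol = 1e-6) {
  node <- mrca_node(tree, taxa)
  parent <- parent_node(tree, node)
  if (is.na(parent)) halt("stem age undefined for root")
  node_ages(tree, relax = relax, rtol = rtol)[parent]
}

# ---------------------------------------------------------------------------
# Tree samples

strip_nexus_metadata <- function(lines) {
  # Drop BEAST-style [&...] annotation comments; translate tables and quoted
  # labels are left for ape::read.nexus. Metadata is ignored, never parsed.
  gsub("\\[&[^]]*\\]", "", lines, perl = TRUE)
}

read_trees_one_file <- function(path, format) {
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    format <- if (any(grepl("#NEXUS", lines, ignore.case = TRUE))) "nexus" else "newick"
  }
  if (format == "nexus") {
    tmp <- tempfile(fileext = ".nex")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(strip_nexus_metadata(lines), tmp)
    trees <- ape::read.nexus(tmp)
  } else {
    trees <- ape::read.tree(text = paste(lines, collapse = "\n"))
  }
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!is.null(attr(trees, "TipLabel"))) {
    trees <- ape::.uncompressTipLabel(trees)  # read.nexus shares tip labels
  }
  if (length(trees) == 0L) halt("no trees parsed from %s", path)
  unclass(trees)
}

#' Read a posterior sample of chronograms with per-file burn-in
#'
#' Reads one or more Newick (one tree per line) or NEXUS (TREES block with
#' optional TRANSLATE) files. The first `floor(burnin_fraction * n)` trees of
#' each file are discarded *before* files are concatenated, mirroring per-run
#' MCMC burn-in followed by run combination. BEAST-style `[&...]` metadata
#' comments in NEXUS files are stripped, not parsed.
#'
#' @param paths character vector of file paths.
#' @param format `"auto"` (default; NEXUS detected by a `#NEXUS` header),
#'   `"newick"`, or `"nexus"`.
#' @param burnin_fraction proportion in `[0, 1)` discarded from the start of
#'   each file.
#' @return an object of class `tree_sample`: a list with elements `trees`
#'   (list of `phylo`), `source`, `burnin_fraction`, `n_input`, `n_retained`.
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines(rep("((A:1,B:1):1,C:2);", 10), tf)
#' ts <- read_trees(tf, burnin_fraction = 0.2)
#' ts$n_retained  # 8
#' @export
read_trees <- function(paths, format = c("auto", "newick", "nexus"),
                       burnin_fraction = 0) {
  format <- match.arg(format)
  stopifnot(is.character(paths), length(paths) >= 1L)
  if (!is.numeric(burnin_fraction) || burnin_fraction < 0 || burnin_fraction >= 1) {
    halt("`burnin_fraction` must be in [0, 1)")
  }
  all_trees <- list()
  n_input <- 0L
  for (p in paths) {
    trees <- read_trees_one_file(p, format)
    n_input <- n_input + length(trees)
    drop <- floor(burnin_fraction * length(trees))
    if (drop > 0L) trees <- trees[-seq_len(drop)]
    all_trees <- c(all_trees, trees)
  }
  ref_taxa <- sort(all_trees[[1]]$tip.label)
  for (i in seq_along(all_trees)) {
    tr <- all_trees[[i]]
    if (!ape::is.rooted(tr)) halt("tree %d is unrooted", i)
    if (is.null(tr$edge.length)) halt("tree %d has no branch lengths", i)
    if (!identical(sort(tr$tip.label), ref_taxa)) {
      halt("tree %d has a different taxon set than tree 1", i)
    }
  }
  structure(list(trees = all_trees,
                 source = paste(paths, collapse = ";"),
                 burnin_fraction = burnin_fraction,
                 n_input = n_input,
                 n_retained = length(all_trees)),
            class = "tree_sample")
}

#' @export
print.tree_sample <- function(x, ...) {
  cat(sprintf("<tree_sample: %d trees retained of %d (burn-in %.0f%%), %d taxa>\n",
              x$n_retained, x$n_input, 100 * x$burnin_fraction,
              ape::Ntip(x$trees[[1]])))
  invisible(x)
}

#' Extract the node-age posterior of a clade from a tree sample
#'
#' Records the crown or stem age (per `clade$mode`) of the clade's MRCA in
#' every retained tree. Under `policy = "mrca"` the MRCA age is recorded even
#' when the taxa are not monophyletic (the MRCA then subtends extra tips);
#' under `policy = "strict"` such trees are skipped and the skip count kept.
#'
#' @param sample a `tree_sample` from [read_trees()].
#' @param clade a [clade_definition()].
#' @param policy `"mrca"` (default) or `"strict"`.
#' @param relax,rtol ultrametricity handling, see [crown_age()].
#' @return an object of class `age_posterior`: list with `clade`, `ages`
#'   (numeric, My), `n`, `n_skipped`, `policy`.
#' @export
extract_age_posterior <- function(sample, clade, policy = c("mrca", "strict"),
                                  relax = FALSE, rtol = 1e-6) {
  policy <- match.arg(policy)
  stopifnot(inherits(sample, "tree_sample"), inherits(clade, "clade_definition"))
  age_fun <- if (clade$mode == "crown") crown_age else stem_age
  ages <- numeric(0)
  n_skipped <- 0L
  for (tr in sample$trees) {
    if (policy == "strict" && !is_monophyletic(tr, clade$taxa)) {
      n_skipped <- n_skipped + 1L
      next
    }
    ages <- c(ages, age_fun(tr, clade$taxa, relax = relax, rtol = rtol))
  }
  if (length(ages) == 0L) {
    halt("clade '%s' monophyletic in no retained tree under strict policy", clade$name)
  }
  structure(list(clade = clade, ages = ages, n = length(ages),
                 n_skipped = n_skipped, policy = policy),
            class = "age_posterior")
}

#' Construct an age posterior directly from a numeric vector
#'
#' Used for externally computed or simulated age samples.
#'
#' @param name clade label.
#' @param ages numeric vector of ages (Ma), all finite and non-negative.
#' @param mode `"crown"` or `"stem"`.
#' @return an `age_posterior` object.
#' @export
age_posterior <- function(name, ages, mode = "crown") {
  ages <- as.numeric(ages)
  if (length(ages) == 0L || any(!is.finite(ages)) || any(ages < 0)) {
    halt("`ages` must be non-empty, finite and non-negative")
  }
  structure(list(clade = clade_definition(name, name, mode = mode),
                 ages = ages, n = length(ages), n_skipped = 0L,
                 policy = "mrca"),
            class = "age_posterior")
}

#' @export
print.age_posterior <- function(x, ...) {
  cat(sprintf("<age_posterior '%s' (%s): n = %d, median = %.2f Ma>\n",
              x$clade$name, x$clade$mode, x$n, stats::median(x$ages)))
  invisible(x)
}

#' Write age posteriors to a TSV table
#'
#' Long format with columns `clade`, `mode`, `draw_index`, `age_ma`;
#' UTF-8, tab-delimited, header row. Round-trips losslessly through
#' [read_age_table()] (ages written at full precision).
#'
#' @param posteriors a list of `age_posterior` objects (or a single one).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_age_table <- function(posteriors, path) {
  if (inherits(posteriors, "age_posterior")) posteriors <- list(posteriors)
  if (length(posteriors) == 0L) halt("empty posterior list")
  stopifnot(all(vapply(posteriors, inherits, logical(1), "age_posterior")))
  rows <- do.call(rbind, lapply(posteriors, function(p) {
    data.frame(clade = p$clade$name, mode = p$clade$mode,
               draw_index = seq_len(p$n),
               age_ma = format(p$ages, digits = 17, scientific = FALSE, trim = TRUE),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an age table written by [write_age_table()]
#'
#' @param path TSV path.
#' @return named list of `age_posterior`, one per (clade, mode) pair, named
#'   `"<clade>.<mode>"`.
#' @export
read_age_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("clade", "mode", "draw_index", "age_ma")
  if (!all(need %in% names(df))) {
    halt("age table must have columns %s", paste(need, collapse = ", "))
  }
  keys <- paste(df$clade, df$mode, sep = ".")
  out <- lapply(split(df, keys), function(d) {
    d <- d[order(d$draw_index), ]
    age_posterior(d$clade[1], as.numeric(d$age_ma), mode = d$mode[1])
  })
  out
}
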