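# Tree reading, burn-in, node ages, monophyly, and age-table round trips.

test_that("burn-in is applied per file before concatenation", {
  cases <- list(list(n = 100L, burnin = 0.10, retained = 90L),
                list(n = 100L, burnin = 0.15, retained = 85L),
                list(n = 10L, burnin = 0.0, retained = 10L))
  for (cs in cases) {
    path <- write_newick_sample(rep("((A:1,B:1):1,C:2);", cs$n))
    ts <- read_trees(path, burnin_fraction = cs$burnin)
    expect_identical(ts$n_retained, cs$retained)
    expect_identical(ts$n_input, cs$n)
  }
  # two files: burn-in per file, then concatenation
  p1 <- write_newick_sample(rep("((A:1,B:1):1,C:2);", 10))
  p2 <- write_newick_sample(rep("((A:1,C:1):1,B:2);", 10))
  ts <- read_trees(c(p1, p2), burnin_fraction = 0.25)
  expect_identical(ts$n_retained, 16L)  # 8 + 8, not floor(0.25 * 20) semantics
})

test_that("read_trees validates taxa, rooting and burn-in range", {
  p <- write_newick_sample(c("((A:1,B:1):1,C:2);", "((A:1,D:1):1,C:2);"))
  expect_error(read_trees(p), "tree 2")
  p2 <- write_newick_sample("(A:1,B:1,C:1);")  # unrooted basal trichotomy
  expect_error(read_trees(p2), "unrooted")
  p3 <- write_newick_sample("((A:1,B:1):1,C:2);")
  expect_error(read_trees(p3, burnin_fraction = 1), "burnin_fraction")
})

test_that("NEXUS translate tables and [&...] metadata are handled", {
  nex <- c("#NEXUS", "BEGIN TREES;",
           "TRANSLATE", "1 Homo_sapiens,", "2 Pan_troglodytes,", "3 Gorilla_gorilla;",
           "TREE STATE_0 [&lnP=-1] = [&R] ((1:5.0[&rate=1],2:5.0):3.0,3:8.0);",
           "TREE STATE_1 = [&R] ((1:5.5,2:5.5):2.5,3:8.0);",
           "END;")
  path <- tempfile(fileext = ".nex")
  writeLines(nex, path)
  ts <- read_trees(path)
  expect_identical(ts$n_retained, 2L)
  expect_setequal(ts$trees[[1]]$tip.label,
                  c("Homo_sapiens", "Pan_troglodytes", "Gorilla_gorilla"))
  expect_equal(crown_age(ts$trees[[1]], c("Homo_sapiens", "Pan_troglodytes")), 5)
})

test_that("mrca, crown and stem ages follow the worked 3-tip examples", {
  tr <- tree3()
  expect_identical(mrca_node(tr, c("A", "B")), ape::getMRCA(tr, c("A", "B")))
  expect_identical(mrca_node(tr, c("A", "C")), ape::Ntip(tr) + 1L)  # root
  expect_identical(mrca_node(tr, "A"), match("A", tr$tip.label))
  expect_equal(crown_age(tr, c("A", "B")), 1)
  expect_equal(crown_age(tr, c("A", "B", "C")), 2)
  expect_equal(crown_age(tr, "A"), 0)
  expect_equal(stem_age(tr, c("A", "B")), 2)
  expect_equal(stem_age(tr, "A"), 1)
  expect_error(stem_age(tr, c("A", "B", "C")), "stem age undefined for root")
  expect_error(mrca_node(tr, c("A", "Z")), "Z")
})

test_that("monophyly test matches descendant tip sets", {
  tr <- tree3()
  expect_true(is_monophyletic(tr, c("A", "B")))
  expect_false(is_monophyletic(tr, c("A", "C")))
  expect_true(is_monophyletic(tr, c("A", "B", "C")))
  expect_true(is_monophyletic(tr, "B"))
})

test_that("ultrametricity check and relaxed mode behave as specified", {
  expect_true(check_ultrametric(tree3(), 1e-6))
  bad <- ape::read.tree(text = "((A:1,B:1.5):1,C:2);")
  expect_false(check_ultrametric(bad, 1e-6))
  expect_error(crown_age(bad, c("A", "B")), "not ultrametric")
  # relaxed mode: root age is the mean path; ages remain non-negative
  expect_gt(crown_age(bad, c("A", "B"), relax = TRUE), 0)
  single <- ape::read.tree(text = "(A:1,B:1);")
  single <- ape::drop.tip(single, "B")
  expect_true(check_ultrametric(single))
})

test_that("crown age of the full taxon set equals the root age", {
  for (seed in 1:5) {
    tr <- simulate_bd_tree(1, 0.3, n_tips = 12, seed = seed)
    expect_equal(crown_age(tr, tr$tip.label), root_age(tr), tolerance = 1e-12)
    # crown < stem for every proper subclade
    node <- mrca_node(tr, c("t1", "t2"))
    if (node != ape::Ntip(tr) + 1L) {
      taxa <- tr$tip.label[phylochron:::descendant_tips(tr, node)]
      expect_lt(crown_age(tr, taxa), stem_age(tr, taxa))
    }
  }
})

test_that("extract_age_posterior honors the monophyly policy", {
  good <- "((A:1,B:1):1,C:2);"
  bad <- "((A:1,C:1):1,B:2);"  # AB not monophyletic here
  path <- write_newick_sample(c(good, good, bad))
  ts <- read_trees(path)
  cd <- clade_definition("ab", c("A", "B"))
  mrca <- extract_age_posterior(ts, cd, policy = "mrca")
  expect_identical(mrca$n, 3L)
  expect_equal(mrca$ages, c(1, 1, 2))  # MRCA of A,B in the bad tree is the root
  strict <- extract_age_posterior(ts, cd, policy = "strict")
  expect_identical(strict$n, 2L)
  expect_identical(strict$n_skipped, 1L)
  expect_equal(strict$ages, c(1, 1))
  # stem mode
  cd_stem <- clade_definition("ab", c("A", "B"), mode = "stem")
  expect_equal(extract_age_posterior(ts, cd_stem, policy = "strict")$ages, c(2, 2))
  # strict with zero retained trees errors
  cd_ac <- clade_definition("ac", c("A", "C"))
  only_good <- read_trees(write_newick_sample(c(good, good)))
  expect_error(extract_age_posterior(only_good, cd_ac, policy = "strict"),
               "no retained tree")
})

test_that("tree write/read round trip preserves topology and ages", {
  for (seed in 1:3) {
    tr <- simulate_bd_tree(1, 0.2, n_tips = 15, seed = seed)
    path <- write_newick_sample(ape::write.tree(tr))
    back <- read_trees(path)$trees[[1]]
    expect_identical(sort(back$tip.label), sort(tr$tip.label))
    expect_equal(root_age(back), root_age(tr), tolerance = 1e-9)
    expect_true(ape::all.equal.phylo(tr, back, use.edge.length = FALSE))
    for (pair in list(c("t1", "t5"), c("t2", "t3"))) {
      expect_equal(crown_age(back, pair), crown_age(tr, pair), tolerance = 1e-9)
    }
  }
})

test_that("age tables round-trip losslessly and count rows correctly", {
  p1 <- age_posterior("x", c(1.25, 2.5, 3.75))
  p2 <- age_posterior("y", c(400.123456789, 410.987654321), mode = "stem")
  path <- tempfile(fileext = ".tsv")
  write_age_table(list(p1, p2), path)
  lines <- readLines(path)
  expect_identical(length(lines), 1L + 3L + 2L)  # header + rows
  back <- read_age_table(path)
  expect_equal(back[["x.crown"]]$ages, p1$ages)
  expect_equal(back[["y.stem"]]$ages, p2$ages, tolerance = 1e-15)
  expect_error(write_age_table(list(), tempfile()), "empty")
})
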