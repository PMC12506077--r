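test_that("Newick reading validates leaf labels and flags absent lengths", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines(c(
    "((Op_me_Hsap_c1_OG6_000001:0.1,Op_fu_Scer_c1_OG6_000001:0.2):0.1,Ba_pr_Ecol_c1_OG6_000001:0.3);",
    "((Op_me_Hsap_c1_OG6_000002,Sr_ci_Tthe_c1_OG6_000002),Ba_pr_Ecol_c1_OG6_000002);"), f)
  trees <- read_gene_trees(f)
  expect_length(trees, 2L)
  expect_equal(attr(trees[[1]], "gf"), "OG6_000001")
  expect_false(attr(trees[[1]], "lengths_absent"))
  expect_true(attr(trees[[2]], "lengths_absent"))
  expect_equal(sum(trees[[2]]$edge.length), 0)

  writeLines("((Op_me_Hsap_c1_OG6_000001:1,Op_me_Hsap_c1_OG6_000001:1):1,Ba_pr_Ecol_c1_OG6_000001:1);", f)
  expect_error(read_gene_trees(f), "duplicate leaf label")
  writeLines("((not_an_id:1,Op_me_Hsap_c1_OG6_000001:1):1,Ba_pr_Ecol_c1_OG6_000001:1);", f)
  expect_error(read_gene_trees(f), "not_an_id")
})

test_that("read/write round-trip preserves the bipartition set and lengths", {
  set.seed(11)
  f <- withr::local_tempfile(fileext = ".nwk")
  for (i in 1:5) {
    t <- random_gene_tree(8)
    write_gene_trees(t, f)
    t2 <- read_gene_trees(f)[[1]]
    expect_equal(phangorn::RF.dist(t, t2), 0)
    expect_equal(sort(t2$tip.label), sort(t$tip.label))
    expect_equal(sum(t2$edge.length), sum(t$edge.length), tolerance = 1e-6)
  }
})

test_that("outgroup rooting picks the largest prokaryote clade, with midpoint fallback", {
  # 4-leaf tree with a 2-leaf bacterial clade: root sits above it
  t <- gtree(paste0("((Ba_pr_S001_c1_OG6_000001:0.1,Ba_pr_S002_c1_OG6_000001:0.1):0.2,",
                    "(Op_me_S001_c1_OG6_000001:0.1,Sr_ci_S001_c1_OG6_000001:0.1):0.2);"))
  r <- root_gene_tree(t)
  expect_true(ape::is.rooted(r))
  expect_true(ape::is.monophyletic(r, c("Ba_pr_S001_c1_OG6_000001",
                                        "Ba_pr_S002_c1_OG6_000001")))
  # all-eukaryote tree falls back to midpoint
  t2 <- gtree(paste0("((Op_me_S001_c1_OG6_000001:0.1,Op_me_S002_c1_OG6_000001:0.1):0.1,",
                     "Sr_ci_S001_c1_OG6_000001:0.5);"))
  r2 <- root_gene_tree(t2)
  expect_true(ape::is.rooted(r2))
  mp <- phangorn::midpoint(t2)
  expect_equal(phangorn::RF.dist(r2, mp), 0)
  # fewer than 3 leaves is an error
  t3 <- ape::read.tree(text = "(Op_me_S001_c1_OG6_000001:1,Ba_pr_S001_c1_OG6_000001:1);")
  expect_error(root_gene_tree(validate_gene_tree(t3)), "at least 3 leaves")
})

test_that("rooting is deterministic across repeated calls", {
  set.seed(23)
  t <- random_gene_tree(10)
  r1 <- root_gene_tree(t)
  r2 <- root_gene_tree(t)
  expect_identical(ape::write.tree(r1), ape::write.tree(r2))
})

test_that("average node-to-tip distance is the mean terminal branch", {
  t <- gtree("((Sr_ci_S001_c1_OG6_000001:1.0,Sr_ci_S002_c1_OG6_000001:1.0):0.5,Ba_pr_S001_c1_OG6_000001:1.0);")
  expect_equal(avg_node_to_tip(t), 1.0)
  t2 <- gtree("((Sr_ci_S001_c1_OG6_000001:0.1,Sr_ci_S002_c1_OG6_000001:0.2):0.5,Ba_pr_S001_c1_OG6_000001:0.3);")
  expect_equal(avg_node_to_tip(t2), 0.2)
  # absent lengths give 0
  t3 <- gtree("((Sr_ci_S001_c1_OG6_000001,Sr_ci_S002_c1_OG6_000001),Ba_pr_S001_c1_OG6_000001);")
  expect_equal(avg_node_to_tip(t3), 0)
  # root-to-tip variant is the mean leaf depth
  expect_equal(avg_node_to_tip(t2, mode = "root_to_tip"),
               mean(c(0.6, 0.7, 0.3)))
})

test_that("sister groups pool multifurcation siblings and never contain the query", {
  t <- gtree("((Sr_ci_S001_c1_OG6_000001:1,EE_ha_S001_c1_OG6_000001:1):1,Ba_pr_S001_c1_OG6_000001:1);")
  expect_equal(sister_group(t, "Sr_ci_S001_c1_OG6_000001"),
               "EE_ha_S001_c1_OG6_000001")
  tm <- gtree("((Sr_ci_S001_c1_OG6_000001:1,EE_ha_S001_c1_OG6_000001:1,EE_ha_S002_c1_OG6_000001:1):1,Ba_pr_S001_c1_OG6_000001:1);")
  expect_setequal(sister_group(tm, "Sr_ci_S001_c1_OG6_000001"),
                  c("EE_ha_S001_c1_OG6_000001", "EE_ha_S002_c1_OG6_000001"))
  expect_error(sister_group(t, "missing_leaf"), "not found")

  # property: x never in sister_group(t, x); cherries are symmetric
  set.seed(5)
  for (i in 1:10) {
    rt <- random_gene_tree(7)
    for (leaf in rt$tip.label) {
      sg <- sister_group(rt, leaf)
      expect_false(leaf %in% sg)
      if (length(sg) == 1 && !is.null(cherry_partner(rt, leaf)))
        expect_equal(sister_group(rt, sg), leaf)
    }
  }
})

test_that("cherry partners exist exactly for two-leaf sibling pairs", {
  t <- gtree("((Op_ap_S001_c1_OG6_000001:1,Op_ap_S002_c1_OG6_000001:1):1,(Ba_pr_S001_c1_OG6_000001:1,(Sr_ci_S001_c1_OG6_000001:1,Sr_ci_S002_c1_OG6_000001:1):1):1);")
  expect_equal(cherry_partner(t, "Op_ap_S001_c1_OG6_000001"),
               "Op_ap_S002_c1_OG6_000001")
  expect_null(cherry_partner(t, "Ba_pr_S001_c1_OG6_000001"))
  two <- ape::read.tree(text = "(Op_me_S001_c1_OG6_000001:1,Op_me_S002_c1_OG6_000001:1);")
  two <- validate_gene_tree(two)
  expect_equal(cherry_partner(two, "Op_me_S001_c1_OG6_000001"),
               "Op_me_S002_c1_OG6_000001")
})

test_that("clade enumeration matches the worked metazoan allowance example", {
  # 12 metazoan codes plus 1 excavate under one node, 10% allowance of the
  # 13 codes present tolerates the single interloper
  inner <- paste(sprintf("Op_me_S%03d_c1_OG6_000001:0.1", 1:12), collapse = ",")
  txt <- sprintf("((%s,Ex_pa_S001_c1_OG6_000001:0.1):0.2,Ba_pr_S001_c1_OG6_000001:0.3);", inner)
  t <- gtree(txt)
  hits <- enumerate_clades(t, "Op_me", "10%")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$target_count, 12L)
  expect_equal(hits$nontarget_count, 1L)
  # zero allowance splits off the pure metazoan sub-clades only
  hits0 <- enumerate_clades(t, "Op_me", 0)
  expect_true(all(hits0$nontarget_count == 0L))
  expect_equal(sum(hits0$target_count), 12L)
})

test_that("clade enumeration counts distinct codes, not sequences", {
  # two sequences of one taxon inside a clade count once
  t <- gtree(paste0("((Sr_ci_S001_c1_OG6_000001:1,(Sr_ci_S001_c2_OG6_000001:1,",
                    "Sr_ci_S002_c1_OG6_000001:1):1):1,Ba_pr_S001_c1_OG6_000001:1);"))
  hits <- enumerate_clades(t, "Sr_ci", 0)
  expect_equal(hits$target_count, 2L)
  expect_equal(hits$n_leaves, 3L)
})

test_that("enumerate_clades equals exhaustive evaluation on random trees", {
  set.seed(101)
  for (i in 1:40) {
    t <- random_gene_tree(sample(4:12, 1))
    target <- sample(c("Sr_ci", "Op", "Op_me", "EE_ha"), 1)
    if (!any(matches_prefix(substr(t$tip.label, 1, 10), target))) next
    allowance <- sample(list(0, 1, "25%"), 1)[[1]]
    got <- lapply(enumerate_clades(t, target, allowance)$leaf_set,
                  function(s) sort(s))
    want <- oracle_enumerate_clades(t, target, allowance)
    expect_setequal(vapply(got, paste, character(1), collapse = "|"),
                    vapply(want, paste, character(1), collapse = "|"))
  }
})

test_that("monophyly honours the interloper allowance and ignores rooting", {
  t <- gtree("((Op_me_S001_c1_OG6_000001:1,Op_me_S002_c1_OG6_000001:1):1,Ex_pa_S001_c1_OG6_000001:1);")
  expect_true(is_monophyletic(t, "Op_me"))
  # on >= 4 leaves an interloper inside the target group breaks monophyly
  # in the unrooted sense; the allowance restores it
  t2 <- gtree(paste0("(Op_me_S001_c1_OG6_000001:1,(Ex_pa_S001_c1_OG6_000001:1,",
                     "(Op_me_S002_c1_OG6_000001:1,Ba_pr_S001_c1_OG6_000001:1):1):1);"))
  expect_false(is_monophyletic(t2, "Op_me", 0))
  expect_true(is_monophyletic(t2, "Op_me", 1))
  # a 3-leaf tree is unrooted-compatible with any 2-leaf grouping
  t3 <- gtree("(Op_me_S001_c1_OG6_000001:1,(Ex_pa_S001_c1_OG6_000001:1,Op_me_S002_c1_OG6_000001:1):1);")
  expect_true(is_monophyletic(t3, "Op_me", 0))
  expect_error(is_monophyletic(t, "Pl_gr"), "no leaf matches")

  # invariance under re-rooting at every edge, zero interlopers
  set.seed(31)
  for (i in 1:8) {
    t <- random_gene_tree(8)
    target <- sample(c("Sr_ci", "Op_me"), 1)
    if (!any(matches_prefix(substr(t$tip.label, 1, 10), target))) next
    base <- is_monophyletic(t, target, 0)
    for (leaf in t$tip.label) {
      rt <- ape::root(t, outgroup = leaf, resolve.root = TRUE)
      expect_equal(is_monophyletic(rt, target, 0), base)
    }
  }
})
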