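test_that("a blanket sister rule removes the lone target next to a forbidden clade", {
  t <- favella_tree()
  rule <- sister_rule("r1", "Sr_ci_Fehr", "EE_ha")
  rem <- apply_sister_rules(t, list(rule))
  expect_equal(rem$seq_id, "Sr_ci_Fehr_c1_OG6_000001")
  expect_equal(rem$mode, "sister")
  expect_equal(rem$rule_id, "r1")
  # the context records the observed sister taxa
  expect_match(rem$observed_context, "EE_ha_Ehux")
})

test_that("short-branch sister rules gate on multiplier x mean terminal branch", {
  # terminal branches 0.01, 0.01, 0.1 -> mean 0.04, threshold 0.02
  t <- favella_tree(fehr_branch = 0.01)
  rule <- sister_rule("r1", "Sr_ci_Fehr", "EE_ha", branch_mode = "short",
                      multiplier = 0.5)
  rem <- apply_sister_rules(t, list(rule))
  expect_equal(nrow(rem), 1L)
  expect_equal(rem$threshold_applied, 0.5 * mean(c(0.01, 0.01, 0.1)))
  expect_equal(rem$terminal_branch_length, 0.01)
  # a longer branch (0.05 >= threshold) is kept
  t2 <- favella_tree(fehr_branch = 0.05)
  expect_equal(nrow(apply_sister_rules(t2, list(rule))), 0L)
})

test_that("sister rules demand an all-forbidden sister group and a sole target", {
  # mixed sister group: rule does not fire
  t <- gtree(paste0("((Sr_ci_Fehr_c1_OG6_000001:0.01,(EE_ha_S001_c1_OG6_000001:0.01,",
                    "Sr_ci_Tthe_c1_OG6_000001:0.01):0.01):0.1,Ba_pr_S001_c1_OG6_000001:0.1);"))
  rule <- sister_rule("r1", "Sr_ci_Fehr", "EE_ha")
  expect_equal(nrow(apply_sister_rules(t, list(rule))), 0L)
  # two target leaves forming the cherry: subsister territory, no firing
  t2 <- gtree(paste0("((Sr_ci_Fehr_c1_OG6_000001:0.01,Sr_ci_Fehr_c2_OG6_000001:0.01):0.1,",
                     "EE_ha_S001_c1_OG6_000001:0.1);"))
  expect_equal(nrow(apply_sister_rules(t2, list(rule))), 0L)
  # rules with no matching target are no-ops
  expect_equal(nrow(apply_sister_rules(t, list(sister_rule("rx", "Am_tu", "Ba")))), 0L)
})

test_that("subsister rules remove co-contaminant cherries sister to non-target groups", {
  t <- gtree(paste0("((Op_ap_Ains_c1_OG6_000001:0.1,Op_ap_Atri_c1_OG6_000001:0.1):0.1,",
                    "(Am_tu_Hp01_c1_OG6_000001:0.1,Sr_ci_S001_c1_OG6_000001:0.1):0.1);"))
  rule <- subsister_rule("ss1", c("Op_ap_Ains", "Op_ap_Atri"), "non-Op")
  rem <- apply_subsister_rules(t, list(rule))
  expect_setequal(rem$seq_id, c("Op_ap_Ains_c1_OG6_000001", "Op_ap_Atri_c1_OG6_000001"))
  # cherry sister to an opisthokont: complement condition fails, both kept
  t2 <- gtree(paste0("((Op_ap_Ains_c1_OG6_000001:0.1,Op_ap_Atri_c1_OG6_000001:0.1):0.1,",
                     "Op_fu_Scer_c1_OG6_000001:0.1);"))
  expect_equal(nrow(apply_subsister_rules(t2, list(rule))), 0L)
  # the pair not forming a cherry: no firing
  t3 <- gtree(paste0("((Op_ap_Ains_c1_OG6_000001:0.1,(Op_ap_Atri_c1_OG6_000001:0.1,",
                     "Am_tu_Hp01_c1_OG6_000001:0.1):0.1):0.1,Sr_ci_S001_c1_OG6_000001:0.1);"))
  expect_equal(nrow(apply_subsister_rules(t3, list(rule))), 0L)
})

test_that("positive forbidden prefixes on subsisters require an all-match sister group", {
  t <- gtree(paste0("((Op_ap_Ains_c1_OG6_000001:0.1,Op_ap_Atri_c1_OG6_000001:0.1):0.1,",
                    "(Ba_pr_S001_c1_OG6_000001:0.1,Ba_pr_S002_c1_OG6_000001:0.1):0.1);"))
  rule <- subsister_rule("ss2", c("Op_ap_Ains", "Op_ap_Atri"), "Ba")
  expect_equal(nrow(apply_subsister_rules(t, list(rule))), 2L)
  rule2 <- subsister_rule("ss3", c("Op_ap_Ains", "Op_ap_Atri"), "Za")
  expect_equal(nrow(apply_subsister_rules(t, list(rule2))), 0L)
})

test_that("clade grabbing keeps qualifying clades and removes strays", {
  # a 12-ciliate clade plus 3 stray ciliate leaves elsewhere
  inner <- paste(sprintf("Sr_ci_S%03d_c1_OG6_000001:0.1", 1:12), collapse = ",")
  txt <- sprintf(paste0("(((%s):0.2,(Sr_ci_S013_c1_OG6_000001:0.1,Ex_pa_S001_c1_OG6_000001:0.1):0.1):0.1,",
                        "((Sr_ci_S014_c1_OG6_000001:0.1,EE_he_S001_c1_OG6_000001:0.1):0.1,",
                        "(Sr_ci_S015_c1_OG6_000001:0.1,Ba_pr_S001_c1_OG6_000001:0.1):0.1):0.1);"),
                 inner)
  t <- gtree(txt)
  res <- clade_grab(t, list(clade_rule("c1", "Sr_ci", min_target = 12)))
  expect_setequal(res$removals$seq_id,
                  c("Sr_ci_S013_c1_OG6_000001", "Sr_ci_S014_c1_OG6_000001",
                    "Sr_ci_S015_c1_OG6_000001"))
  # non-target leaves are never removed
  expect_true(all(startsWith(res$removals$seq_id, "Sr_ci")))
  expect_setequal(c(res$kept, res$removals$seq_id), t$tip.label)

  # a stray matching an exception prefix is spared
  res2 <- clade_grab(t, list(clade_rule("c2", "Sr", min_target = 12,
                                        exceptions = "Sr_ci_S014")))
  expect_false("Sr_ci_S014_c1_OG6_000001" %in% res2$removals$seq_id)

  # min_target above every clade size removes all non-exception targets
  res3 <- clade_grab(t, list(clade_rule("c3", "Sr_ci", min_target = 50)))
  expect_equal(nrow(res3$removals), 15L)
})

test_that("clade grabbing matches the exhaustive oracle on random trees", {
  set.seed(202)
  for (i in 1:25) {
    t <- random_gene_tree(sample(5:12, 1))
    target <- sample(c("Sr_ci", "Op_me"), 1)
    if (!any(matches_prefix(substr(t$tip.label, 1, 10), target))) next
    min_t <- sample(1:3, 1)
    res <- clade_grab(t, list(clade_rule("c", target, min_t)))
    expect_equal(sort(res$removals$seq_id),
                 oracle_clade_grab(t, target, min_t, 0))
  }
})

test_that("clade-grab kept sets shrink with min_target and grow with allowance", {
  set.seed(303)
  for (i in 1:10) {
    t <- random_gene_tree(10)
    if (!any(matches_prefix(substr(t$tip.label, 1, 10), "Sr_ci"))) next
    kept_sizes <- vapply(1:4, function(m)
      length(clade_grab(t, list(clade_rule("c", "Sr_ci", m)))$kept), integer(1))
    expect_true(all(diff(kept_sizes) <= 0))
    kept_allow <- vapply(0:2, function(a)
      length(clade_grab(t, list(clade_rule("c", "Sr_ci", 2, a)))$kept), integer(1))
    expect_true(all(diff(kept_allow) >= 0))
  }
})

test_that("the loop iterates until contaminant chains are exhausted", {
  # chain: removing the innermost contaminant exposes the next one as
  # sister to a forbidden haptophyte; a clean bacterial cherry anchors the
  # root away from the nest
  txt <- paste0("(((((Sr_ci_S001_c1_OG6_000001:0.01,EE_ha_S001_c1_OG6_000001:0.1):0.05,",
                "Sr_ci_S002_c1_OG6_000001:0.01):0.05,EE_ha_S002_c1_OG6_000001:0.1):0.1,",
                "Op_me_S001_c1_OG6_000001:0.1):0.1,",
                "(Ba_pr_S001_c1_OG6_000001:0.1,Ba_pr_S002_c1_OG6_000001:0.1):0.2);")
  t0 <- gtree(txt)
  rules <- list(sister_rule("r1", "Sr_ci", "EE_ha"))
  res <- run_loop(list(OG6_000001 = t0$tip.label),
                  prune_rebuild(list(OG6_000001 = t0)),
                  list(loop_phase("sister", rules, 10)))
  expect_setequal(res$ledger$seq_id,
                  c("Sr_ci_S001_c1_OG6_000001", "Sr_ci_S002_c1_OG6_000001"))
  expect_equal(sort(unique(res$ledger$iteration)), c(1L, 2L))
  # convergence: one extra pass on the converged set removes nothing
  res2 <- run_loop(res$kept, prune_rebuild(list(OG6_000001 = t0)),
                   list(loop_phase("sister", rules, 10)))
  expect_equal(nrow(res2$ledger), 0L)
  expect_equal(res2$kept, res$kept)
})

test_that("empty rules leave the input untouched with an empty ledger", {
  set.seed(9)
  t <- random_gene_tree(8)
  res <- run_loop(list(OG6_000001 = t$tip.label),
                  prune_rebuild(list(OG6_000001 = t)),
                  list(loop_phase("sister", list(), 10)))
  expect_equal(res$kept$OG6_000001, t$tip.label)
  expect_equal(nrow(res$ledger), 0L)
})

test_that("ledger rows biject with removed sequences and conserve the input", {
  sp <- simulate_species_tree(c(Sr_ci = 8L, Op_me = 4L, EE_ha = 3L, Ba_pr = 3L),
                              seed = 4)
  sim <- simulate_gene_trees(sp, 6, list(
    contamination_event("Sr_ci_S001", "EE_ha", "sister_single",
                        n_gfs_affected = 4L)), seed = 5)
  seqs <- lapply(sim$gene_trees, function(t) t$tip.label)
  res <- run_loop(seqs, prune_rebuild(sim$gene_trees),
                  list(loop_phase("sister",
                                  list(sister_rule("r", "Sr_ci_S001", "EE_ha")), 10)))
  for (gf in names(seqs)) {
    removed <- res$ledger$seq_id[res$ledger$gf == gf]
    expect_setequal(c(res$kept[[gf]], removed), seqs[[gf]])
    expect_equal(length(intersect(res$kept[[gf]], removed)), 0L)
  }
  expect_equal(anyDuplicated(paste(res$ledger$gf, res$ledger$seq_id)), 0L)
})

test_that("a failing rebuild skips the gene family and the run continues", {
  set.seed(17)
  t1 <- random_gene_tree(6, gf = "OG6_000001")
  t2 <- random_gene_tree(6, gf = "OG6_000002")
  rebuild <- function(ids, gf) {
    if (gf == "OG6_000001") stop("inference failed")
    prune_rebuild(list(OG6_000002 = t2))(ids, gf)
  }
  res <- run_loop(list(OG6_000001 = t1$tip.label, OG6_000002 = t2$tip.label),
                  rebuild,
                  list(loop_phase("sister", list(sister_rule("r", "Sr_ci", "Ba")), 2)))
  expect_named(res$skipped, "OG6_000001")
  expect_match(res$skipped[["OG6_000001"]], "inference failed")
  expect_equal(res$kept$OG6_000001, t1$tip.label)
})

test_that("rules files round-trip through TSV", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rule_id\tmode\ttarget\tforbidden\tbranch_mode\tmultiplier",
               "# a comment",
               "r1\tsister\tSr_ci_Fehr\tEE_ha\tshort\t0.5",
               "r2\tsister\tSr_ci\tBa,Za\tany\t",
               "ss1\tsubsister\tOp_ap_Ains;Op_ap_Atri\tnon-Op\t\t"), f)
  rules <- read_sister_rules(f)
  expect_length(rules, 3L)
  expect_s3_class(rules[[1]], "sister_rule")
  expect_equal(rules[[1]]$branch_mode, "short")
  expect_equal(rules[[2]]$forbidden_sisters[[2]]$text, "Za")
  expect_s3_class(rules[[3]], "subsister_rule")
  expect_equal(rules[[3]]$complement[[1]]$text, "Op")

  fc <- withr::local_tempfile(fileext = ".tsv")
  fe <- withr::local_tempfile(fileext = ".txt")
  writeLines("EE_he", fe)
  writeLines(c("rule_id\ttarget\tmin_target\tallowance\texceptions_file",
               sprintf("c1\tSr_ci\t12\t10%%\t%s", fe)), fc)
  crules <- read_clade_rules(fc)
  expect_equal(crules[[1]]$min_target, 12L)
  expect_equal(crules[[1]]$nontarget_allowance, "10%")
  expect_equal(crules[[1]]$exceptions[[1]]$text, "EE_he")
})
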