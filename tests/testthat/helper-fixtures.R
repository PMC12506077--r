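# Fixture builders shared across the suite. Everything is generated in code
# under fixed seeds; no stored data files.

# a small pool of valid taxon codes spanning several major/minor clades
code_pool <- function() {
  c(sprintf("Sr_ci_S%03d", 1:6), sprintf("Op_me_S%03d", 1:4),
    sprintf("Ba_pr_S%03d", 1:2), sprintf("EE_ha_S%03d", 1:2),
    sprintf("Ex_pa_S%03d", 1:2), sprintf("Pl_gr_S%03d", 1:2))
}

# random rooted gene tree with n leaves labelled as sequence ids; codes drawn
# with replacement (so one taxon can contribute several sequences)
random_gene_tree <- function(n, gf = "OG6_000001", pool = code_pool()) {
  t <- ape::rtree(n)
  codes <- sample(pool, n, replace = TRUE)
  t$tip.label <- paste0(codes, "_c", seq_len(n), "_", gf)
  attr(t, "gf") <- gf
  t
}

# parse a tree from Newick text and validate it
gtree <- function(text) validate_gene_tree(ape::read.tree(text = text))

# the worked 3-leaf sister-rule tree: a Favella-like ciliate on a short
# branch sister to a haptophyte
favella_tree <- function(fehr_branch = 0.01) {
  gtree(sprintf(
    "((Sr_ci_Fehr_c1_OG6_000001:%g,EE_ha_Ehux_c1_OG6_000001:0.01):0.1,Sr_ci_Tthe_c1_OG6_000001:0.1);",
    fehr_branch))
}
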