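# random bifurcating topology over a set of subtree Newick fragments,
# exponential internal branch lengths; deterministic under the active seed
random_join <- function(parts, rate = 10) {
  while (length(parts) > 1L) {
    i <- sample.int(length(parts), 2L)
    joined <- sprintf("(%s:%g,%s:%g)", parts[[i[1]]], stats::rexp(1, rate),
                      parts[[i[2]]], stats::rexp(1, rate))
    parts <- c(parts[-i], joined)
  }
  parts[[1]]
}

#' Simulate a species tree over valid taxon codes
#'
#' Generates a random bifurcating species tree whose leaves are valid
#' 10-character taxon codes, with species grouped so that every minor clade
#' (and every major clade) is monophyletic in truth. Branch lengths are
#' exponential (mean 0.1). Byte-identical output for the same inputs and
#' seed.
#'
#' @param n_taxa Named integer vector: minor-clade prefix (e.g. `"Sr_ci"`)
#'   -> number of taxa to generate in it.
#' @param seed Integer seed.
#' @return A `phylo` species tree; tip labels are taxon codes.
#' @export
simulate_species_tree <- function(n_taxa, seed = 1L) {
  stopifnot(!is.null(names(n_taxa)), all(n_taxa >= 1))
  if (sum(n_taxa) < 3L) stop("need at least 3 taxa in total", call. = FALSE)
  invisible(lapply(names(n_taxa), clade_prefix))
  set.seed(seed)
  minors <- names(n_taxa)
  majors <- unique(substr(minors, 1, 2))
  major_parts <- lapply(majors, function(mj) {
    minor_parts <- lapply(minors[substr(minors, 1, 2) == mj], function(mn) {
      labs <- sprintf("%s_S%03d", mn, seq_len(n_taxa[[mn]]))
      leafs <- lapply(labs, identity)
      random_join(leafs)
    })
    random_join(minor_parts)
  })
  txt <- paste0(random_join(major_parts), ";")
  ape::read.tree(text = txt)
}

# attach a new tip as sister to an existing tip, new terminal branch `blen`,
# splitting the host tip's terminal edge in half
graft_tip <- function(t, host, label, blen) {
  i <- match(host, t$tip.label)
  if (is.na(i)) stop("graft host '", host, "' not in tree", call. = FALSE)
  host_edge <- t$edge.length[t$edge[, 2] == i]
  phytools::bind.tip(t, label, edge.length = blen, where = i,
                     position = host_edge / 2)
}

#' Specify a planted contamination event
#'
#' @param recipient_taxon Taxon code whose name the contaminant sequences
#'   carry (the mislabelled sample).
#' @param donor_prefix Clade prefix of the true source lineage; contaminant
#'   leaves are grafted inside this clade.
#' @param mode `"sister_single"` (one leaf, sole sister to a donor leaf),
#'   `"cherry_pair"` (two recipient leaves forming a cherry inside the donor
#'   clade; second taxon via `recipient2`), or `"misassigned_clade"` (a
#'   block of `block_size` recipient leaves forming their own clade inside
#'   the donor clade, emulating wholesale sample misassignment).
#' @param terminal_branch_scale Planted terminal branch length as a fraction
#'   of the tree's mean terminal branch (default 0.2, i.e. well under a
#'   0.5-multiplier short-branch threshold).
#' @param n_gfs_affected How many gene families the event touches.
#' @param recipient2 Second recipient taxon code (cherry_pair only).
#' @param block_size Number of leaves planted (misassigned_clade only).
#' @return A `contamination_event` object.
#' @export
contamination_event <- function(recipient_taxon, donor_prefix,
                                mode = c("sister_single", "cherry_pair",
                                         "misassigned_clade"),
                                terminal_branch_scale = 0.2,
                                n_gfs_affected = 1L,
                                recipient2 = NULL, block_size = 6L) {
  mode <- match.arg(mode)
  parse_taxon_code(recipient_taxon)
  donor <- clade_prefix(donor_prefix)
  if (matches_prefix(recipient_taxon, donor_prefix))
    stop("recipient must not match the donor prefix", call. = FALSE)
  if (terminal_branch_scale <= 0)
    stop("terminal_branch_scale must be positive", call. = FALSE)
  if (mode == "cherry_pair") {
    if (is.null(recipient2)) stop("cherry_pair needs recipient2", call. = FALSE)
    parse_taxon_code(recipient2)
  }
  structure(list(recipient_taxon = recipient_taxon, donor_prefix = donor,
                 mode = mode, terminal_branch_scale = terminal_branch_scale,
                 n_gfs_affected = as.integer(n_gfs_affected),
                 recipient2 = recipient2, block_size = as.integer(block_size)),
            class = "contamination_event")
}

#' Simulate gene trees with planted contaminants
#'
#' Each gene tree is the species tree with multiplicative log-normal branch
#' noise, Bernoulli taxon dropout, optional paralog duplications, and
#' contaminant leaves grafted per the event list. Dropout never touches
#' leaves of a donor clade or of a recipient's minor clade, so the planted
#' signal is cleanly separated from sampling noise. Leaf labels are full
#' sequence ids (`<code>_c<k>_OG6_<gf>`); planted leaves carry contig tokens
#' `x<event><k>`. The single seed fans out to per-gene-family seeds so any
#' subset of gene families is reproducible on its own.
#'
#' @param species_tree A species tree from [simulate_species_tree()].
#' @param n_gfs Number of gene families to simulate.
#' @param events List of [contamination_event()] objects.
#' @param paralog_rate Per-tip probability of a within-taxon duplication.
#' @param dropout Per-tip probability of absence from a gene family.
#' @param bl_noise_sd SD of the log-normal branch-length multiplier.
#' @param seed Integer seed.
#' @return List with `gene_trees` (named by GF token), `truth` (data.frame
#'   `gf`, `seq_id`, `is_contaminant`, `event_id`), and `species_tree`.
#' @export
simulate_gene_trees <- function(species_tree, n_gfs, events = list(),
                                paralog_rate = 0, dropout = 0.1,
                                bl_noise_sd = 0.25, seed = 1L) {
  stopifnot(inherits(species_tree, "phylo"))
  set.seed(seed)
  gf_tokens <- sprintf("OG6_%06d", seq_len(n_gfs))
  gf_seeds <- sample.int(.Machine$integer.max - 1L, n_gfs)
  # which GFs each event touches, drawn once up front
  affected <- lapply(events, function(e)
    sort(sample.int(n_gfs, min(e$n_gfs_affected, n_gfs))))
  protected_prefixes <- unique(unlist(lapply(events, function(e)
    c(e$donor_prefix$text, substr(e$recipient_taxon, 1, 5),
      if (!is.null(e$recipient2)) substr(e$recipient2, 1, 5)))))
  trees <- stats::setNames(vector("list", n_gfs), gf_tokens)
  truth <- list()
  for (g in seq_len(n_gfs)) {
    set.seed(gf_seeds[g])
    gf <- gf_tokens[g]
    t <- species_tree
    t$edge.length <- t$edge.length *
      stats::rlnorm(length(t$edge.length), 0, bl_noise_sd)
    # dropout, sparing protected lineages and keeping >= 4 leaves
    droppable <- t$tip.label[!matches_any_prefix(substr(t$tip.label, 1, 10),
                                                 protected_prefixes)]
    drop <- droppable[stats::runif(length(droppable)) < dropout]
    if (length(drop) > ape::Ntip(t) - 4L)
      drop <- drop[seq_len(max(0L, ape::Ntip(t) - 4L))]
    if (length(drop)) t <- ape::drop.tip(t, drop)
    # relabel species-tree tips as sequence ids
    t$tip.label <- paste0(t$tip.label, "_c1_", gf)
    # paralogs: duplicate a tip as its own sister
    if (paralog_rate > 0) {
      for (lab in t$tip.label[stats::runif(ape::Ntip(t)) < paralog_rate]) {
        dup <- sub("_c1_", "_c2_", lab, fixed = TRUE)
        blen <- t$edge.length[t$edge[, 2] == match(lab, t$tip.label)]
        t <- graft_tip(t, lab, dup, blen / 2)
      }
    }
    planted <- character(); planted_event <- character()
    used_hosts <- character()
    for (ei in seq_along(events)) {
      e <- events[[ei]]
      if (!g %in% affected[[ei]]) next
      # hosts are genuine donor-clade leaves, one per event: leaves planted
      # by earlier events, and hosts already carrying a graft, are never
      # re-used, so planted patterns stay cleanly separated
      donor_tips <- t$tip.label[matches_prefix(substr(t$tip.label, 1, 10),
                                               e$donor_prefix)]
      donor_tips <- setdiff(donor_tips, c(planted, used_hosts))
      if (length(donor_tips) == 0L) next
      host <- sample(donor_tips, 1L)
      used_hosts <- c(used_hosts, host)
      blen <- e$terminal_branch_scale * avg_node_to_tip(t)
      ev_id <- paste0("e", ei)
      if (e$mode == "sister_single") {
        lab <- paste0(e$recipient_taxon, "_x", ei, "a_", gf)
        t <- graft_tip(t, host, lab, blen)
        planted <- c(planted, lab); planted_event <- c(planted_event, ev_id)
      } else if (e$mode == "cherry_pair") {
        lab1 <- paste0(e$recipient_taxon, "_x", ei, "a_", gf)
        lab2 <- paste0(e$recipient2, "_x", ei, "b_", gf)
        t <- graft_tip(t, host, lab1, blen)
        t <- graft_tip(t, lab1, lab2, blen / 2)
        planted <- c(planted, lab1, lab2)
        planted_event <- c(planted_event, ev_id, ev_id)
      } else {  # misassigned_clade: caterpillar block of recipient leaves
        labs <- paste0(e$recipient_taxon, "_x", ei, letters[seq_len(e$block_size)],
                       "_", gf)
        t <- graft_tip(t, host, labs[1], blen)
        for (k in seq_len(e$block_size - 1L))
          t <- graft_tip(t, labs[k], labs[k + 1L], blen / 2)
        planted <- c(planted, labs)
        planted_event <- c(planted_event, rep(ev_id, length(labs)))
      }
    }
    attr(t, "gf") <- gf
    trees[[gf]] <- t
    truth[[g]] <- data.frame(
      gf = gf, seq_id = t$tip.label,
      is_contaminant = t$tip.label %in% planted,
      event_id = planted_event[match(t$tip.label, planted)],
      stringsAsFactors = FALSE)
  }
  list(gene_trees = trees, truth = do.call(rbind, truth),
       species_tree = species_tree)
}

#' Simulate coding sequences with controlled silent-site GC
#'
#' Draws stop-free coding sequences whose third-position GC fraction at
#' synonymously variable sites hits a per-gene target: the number of
#' GC-ending codons is fixed at `round(target * n_codons)` and assigned to
#' random positions, so the realised GC3S differs from the target only by
#' rounding. A `skew` in \[0,1\] concentrates usage on one preferred codon
#' per family half (0 = uniform within the GC/AT halves, high values push
#' the effective number of codons down).
#'
#' @param profiles Data.frame with columns `taxon` (code), `gc3s` (target),
#'   and optionally `skew` (default 0).
#' @param n_genes Genes per taxon.
#' @param n_codons Codons per gene.
#' @param seed Integer seed.
#' @param genetic_code Genetic code table (standard by default).
#' @return List with `seqs` (named character vector; ids
#'   `<taxon>_g<k>_OG6_<k>`) and `truth` (data.frame `seq_id`, `taxon`,
#'   `target_gc3s`, `skew`).
#' @export
simulate_cds <- function(profiles, n_genes = 5L, n_codons = 300L, seed = 1L,
                         genetic_code = Biostrings::GENETIC_CODE) {
  stopifnot(all(c("taxon", "gc3s") %in% names(profiles)),
            all(profiles$gc3s >= 0 & profiles$gc3s <= 1))
  if (!"skew" %in% names(profiles)) profiles$skew <- 0
  set.seed(seed)
  fams <- codon_families(genetic_code)
  fams <- fams[vapply(fams, length, integer(1)) > 1L]
  third_gc <- function(codons) substr(codons, 3, 3) %in% c("G", "C")
  # only families offering both a GC-ending and an AT-ending codon can
  # realise an arbitrary target
  eligible <- fams[vapply(fams, function(f) any(third_gc(f)) && !all(third_gc(f)),
                          logical(1))]
  seqs <- character(); truth <- list(); gene_no <- 0L
  for (r in seq_len(nrow(profiles))) {
    tax <- profiles$taxon[r]; target <- profiles$gc3s[r]; skew <- profiles$skew[r]
    for (k in seq_len(n_genes)) {
      gene_no <- gene_no + 1L
      fam_idx <- sample.int(length(eligible), n_codons, replace = TRUE)
      n_gc <- round(target * n_codons)
      gc_pos <- logical(n_codons)
      gc_pos[sample.int(n_codons, n_gc)] <- TRUE
      codons <- vapply(seq_len(n_codons), function(i) {
        f <- eligible[[fam_idx[i]]]
        pool <- f[third_gc(f) == gc_pos[i]]
        if (length(pool) > 1L && stats::runif(1) < skew) pool[1]
        else sample(pool, 1L)
      }, character(1))
      id <- sprintf("%s_g%d_OG6_%06d", tax, gene_no, gene_no)
      seqs[[id]] <- paste(codons, collapse = "")
      truth[[length(truth) + 1L]] <- data.frame(
        seq_id = id, taxon = tax, target_gc3s = target, skew = skew,
        stringsAsFactors = FALSE)
    }
  }
  list(seqs = seqs, truth = do.call(rbind, truth))
}
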