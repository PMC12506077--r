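# shared helper: prefix of a pooled sister group at a given code width
# (2 = major, 5 = minor); "mixed" when the group spans prefixes
group_prefix_at <- function(codes, width) {
  pre <- unique(substr(codes, 1, width))
  if (length(pre) == 1L) pre else "mixed"
}

#' Tabulate sister relationships of focal taxa across gene trees
#'
#' For every leaf matching a focal prefix in every tree, the prefix
#' composition of its sister group is tallied at the major and minor level:
#' a pure sister group counts under its prefix, a mixed one under
#' `"mixed"`. The tables drive sister-rule design (which lineages does a
#' suspect taxon repeatedly sit next to?).
#'
#' @param trees List of rooted gene trees.
#' @param focal Character vector of clade prefixes (any level).
#' @return Data.frame with columns `focal`, `level` (major/minor),
#'   `sister_prefix`, `n_trees`, `n_sequences`,
#'   `mean_terminal_branch` — plus an all-zero row per focal prefix absent
#'   from every tree.
#' @export
contamination_by_sisters <- function(trees, focal) {
  recs <- list()
  for (ti in seq_along(trees)) {
    t <- trees[[ti]]
    tips <- t$tip.label
    codes <- substr(tips, 1, 10)
    tbl <- terminal_branch_lengths(t)
    for (fp in focal) {
      for (i in which(matches_prefix(codes, fp))) {
        sis <- sister_group(t, tips[i])
        if (length(sis) == 0L) next
        sis_codes <- unique(substr(sis, 1, 10))
        for (level in c("major", "minor")) {
          w <- if (level == "major") 2L else 5L
          recs[[length(recs) + 1L]] <- data.frame(
            focal = fp, level = level,
            sister_prefix = group_prefix_at(sis_codes, w),
            tree = ti, branch = tbl[[tips[i]]],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(recs) == 0L) {
    recs_df <- data.frame(focal = character(), level = character(),
                          sister_prefix = character(), tree = integer(),
                          branch = numeric(), stringsAsFactors = FALSE)
  } else {
    recs_df <- do.call(rbind, recs)
  }
  agg <- if (nrow(recs_df)) {
    do.call(rbind, lapply(
      split(recs_df, list(recs_df$focal, recs_df$level, recs_df$sister_prefix),
            drop = TRUE),
      function(g) data.frame(
        focal = g$focal[1], level = g$level[1], sister_prefix = g$sister_prefix[1],
        n_trees = length(unique(g$tree)), n_sequences = nrow(g),
        mean_terminal_branch = mean(g$branch), stringsAsFactors = FALSE)))
  } else NULL
  # zero-count rows for focal prefixes never observed
  seen <- unique(recs_df$focal)
  zero <- lapply(setdiff(focal, seen), function(fp)
    data.frame(focal = fp, level = "major", sister_prefix = NA_character_,
               n_trees = 0L, n_sequences = 0L, mean_terminal_branch = NA_real_,
               stringsAsFactors = FALSE))
  out <- do.call(rbind, c(list(agg), zero))
  rownames(out) <- NULL
  out[order(out$focal, out$level, -out$n_trees), , drop = FALSE]
}

#' Sizes of maximal pure clades per prefix per tree
#'
#' For each prefix, reports the distinct-taxon-code size of every maximal
#' pure clade (zero non-target allowance) in each tree, plus max/median
#' summaries across trees. Used to parameterise clade-grabbing minimum
#' sizes empirically.
#'
#' @param trees List of rooted gene trees.
#' @param prefixes Character vector of clade prefixes.
#' @return List with `sizes` (data.frame `tree`, `prefix`, `size`) and
#'   `summary` (data.frame `prefix`, `n_clades`, `max_size`, `median_size`).
#' @export
clade_sizes <- function(trees, prefixes) {
  rows <- list()
  for (ti in seq_along(trees)) {
    t <- trees[[ti]]
    for (p in prefixes) {
      if (!any(matches_prefix(substr(t$tip.label, 1, 10), p))) next
      hits <- enumerate_clades(t, p, max_nontarget = 0)
      for (i in seq_len(nrow(hits))) {
        rows[[length(rows) + 1L]] <- data.frame(
          tree = ti, prefix = p, size = hits$target_count[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  sizes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tree = integer(), prefix = character(), size = integer())
  summary <- do.call(rbind, lapply(prefixes, function(p) {
    s <- sizes$size[sizes$prefix == p]
    data.frame(prefix = p, n_clades = length(s),
               max_size = if (length(s)) max(s) else 0L,
               median_size = if (length(s)) stats::median(s) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(sizes = sizes, summary = summary)
}

#' Count taxon occurrence across gene trees
#'
#' @param trees List of gene trees.
#' @param taxa Optional character vector of taxon codes to report (zero rows
#'   included); defaults to every taxon observed.
#' @return Data.frame `taxon`, `n_gfs_present`, `n_sequences`.
#' @export
count_taxon_occurrence <- function(trees, taxa = NULL) {
  per_tree <- lapply(trees, function(t) substr(t$tip.label, 1, 10))
  all_codes <- unlist(per_tree, use.names = FALSE)
  if (is.null(taxa)) taxa <- sort(unique(all_codes))
  data.frame(
    taxon = taxa,
    n_gfs_present = vapply(taxa, function(x)
      sum(vapply(per_tree, function(cs) x %in% cs, logical(1))), integer(1)),
    n_sequences = vapply(taxa, function(x) sum(all_codes == x), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank gene families by sharedness and paralogy
#'
#' Sharedness of a gene family is the fraction of focal taxa with at least
#' one sequence; paralogy is the mean number of sequences per present
#' taxon. Gene families are ranked by sharedness descending, then paralogy
#' ascending, then GF token, giving a total order. The top-ranked GFs are
#' the natural candidates for concatenated analyses.
#'
#' @param presence Either a character vector of sequence ids (ReadyToGo-style
#'   headers) or a named list (taxon code -> character vector of GF tokens,
#'   one entry per sequence).
#' @param focal_taxa Character vector of taxon codes over which sharedness
#'   is computed.
#' @param top_n Optional; return only the first `top_n` rows.
#' @return Data.frame `gf`, `sharedness`, `paralogy`, `n_taxa_present`,
#'   sorted by rank.
#' @export
shared_gfs <- function(presence, focal_taxa, top_n = NULL) {
  if (length(focal_taxa) == 0L) stop("focal taxon set is empty", call. = FALSE)
  if (is.character(presence)) {
    sids <- lapply(presence, parse_seq_id)
    df <- data.frame(taxon = vapply(sids, function(s) s$taxon$full, character(1)),
                     gf = vapply(sids, function(s) s$gf, character(1)),
                     stringsAsFactors = FALSE)
  } else {
    df <- do.call(rbind, lapply(names(presence), function(tax)
      if (length(presence[[tax]]))
        data.frame(taxon = tax, gf = presence[[tax]], stringsAsFactors = FALSE)))
  }
  df <- df[df$taxon %in% focal_taxa, , drop = FALSE]
  gfs <- sort(unique(df$gf))
  out <- do.call(rbind, lapply(gfs, function(g) {
    sub <- df[df$gf == g, , drop = FALSE]
    counts <- table(sub$taxon)
    data.frame(gf = g,
               sharedness = length(counts) / length(focal_taxa),
               paralogy = mean(as.numeric(counts)),
               n_taxa_present = length(counts),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) out <- data.frame(gf = character(), sharedness = numeric(),
                                      paralogy = numeric(), n_taxa_present = integer())
  out <- out[order(-out$sharedness, out$paralogy, out$gf), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(top_n)) out <- utils::head(out, top_n)
  out
}

#' Flag gene families with putative endosymbiotic-gene-transfer signal
#'
#' A gene family is flagged `"primary"` when some clade of at least
#' `min_clade_leaves` leaves consists solely of photosynthetic eukaryotes
#' and prokaryotes with at least one of each — the pattern expected of
#' plastid-to-nucleus transfers. It is flagged `"secondary"` when some such
#' clade contains at least `min_photo_minors` distinct photosynthetic minor
#' clades interdigitated without any non-photosynthetic eukaryote. Output is
#' a candidate list for manual review, not an adjudication.
#'
#' @param trees Named list (by GF token) of gene trees.
#' @param photosynthetic_prefixes Character vector of clade prefixes
#'   regarded as photosynthetic eukaryotes (user-supplied biology).
#' @param prokaryote_prefixes Prefixes regarded as prokaryotes (default
#'   `Ba`, `Za`).
#' @param min_clade_leaves Minimum clade size considered (default 4).
#' @param min_photo_minors Minimum distinct photosynthetic minor clades for
#'   a secondary flag (default 3).
#' @return Data.frame `gf`, `flag` (`primary`/`secondary`), `n_leaves`,
#'   `context`; zero rows when nothing is flagged.
#' @export
flag_egt <- function(trees, photosynthetic_prefixes,
                     prokaryote_prefixes = c("Ba", "Za"),
                     min_clade_leaves = 4L, min_photo_minors = 3L) {
  if (length(photosynthetic_prefixes) == 0L || length(prokaryote_prefixes) == 0L)
    stop("photosynthetic and prokaryote prefix lists must be non-empty", call. = FALSE)
  if (is.null(names(trees)))
    names(trees) <- vapply(trees, function(t) attr(t, "gf") %||%
                             parse_seq_id(t$tip.label[1])$gf, character(1))
  rows <- list()
  for (gf in names(trees)) {
    t <- trees[[gf]]
    codes_all <- substr(t$tip.label, 1, 10)
    if (!any(matches_any_prefix(codes_all, photosynthetic_prefixes))) next
    # evaluate over unrooted splits (plus the whole leaf set) so the flag
    # does not depend on where the tree was rooted
    sets <- c(unrooted_splits(t), list(t$tip.label))
    primary <- NULL; secondary <- NULL
    for (leaves in sets) {
      if (is.null(leaves) || length(leaves) < min_clade_leaves) next
      codes <- substr(leaves, 1, 10)
      photo <- matches_any_prefix(codes, photosynthetic_prefixes)
      prok <- matches_any_prefix(codes, prokaryote_prefixes)
      if (is.null(primary) && all(photo | prok) && any(photo) && any(prok)) {
        primary <- sprintf("clade of %d leaves: photosynthetic+prokaryote only",
                           length(leaves))
        rows[[length(rows) + 1L]] <- data.frame(
          gf = gf, flag = "primary", n_leaves = length(leaves),
          context = primary, stringsAsFactors = FALSE)
      }
      photo_minors <- unique(substr(codes[photo], 1, 5))
      if (is.null(secondary) && all(photo | prok) &&
          length(photo_minors) >= min_photo_minors) {
        secondary <- sprintf("clade of %d leaves: %d photosynthetic minor clades interdigitated",
                             length(leaves), length(photo_minors))
        rows[[length(rows) + 1L]] <- data.frame(
          gf = gf, flag = "secondary", n_leaves = length(leaves),
          context = secondary, stringsAsFactors = FALSE)
      }
      if (!is.null(primary) && !is.null(secondary)) break
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(gf = character(), flag = character(), n_leaves = integer(),
               context = character(), stringsAsFactors = FALSE)
}

#' Monophyly of named clades across curation stages
#'
#' Evaluates [is_monophyletic()] for each clade prefix on one species tree
#' per curation stage, mirroring the filled/empty-triangle summaries used
#' to compare topologies before and after contamination removal.
#'
#' @param stage_trees Named list (stage label -> `phylo`); leaf labels are
#'   taxon codes or sequence ids.
#' @param clades Character vector of clade prefixes.
#' @param allowed_interlopers Interloper allowance passed through.
#' @return Data.frame `stage`, `clade`, `status`
#'   (`monophyletic` / `non-monophyletic` / `absent`).
#' @export
monophyly_table <- function(stage_trees, clades, allowed_interlopers = 0L) {
  stopifnot(!is.null(names(stage_trees)))
  out <- expand.grid(stage = names(stage_trees), clade = clades,
                     stringsAsFactors = FALSE)
  out$status <- vapply(seq_len(nrow(out)), function(i) {
    t <- stage_trees[[out$stage[i]]]
    if (!any(matches_prefix(substr(t$tip.label, 1, 10), out$clade[i])))
      return("absent")
    if (is_monophyletic(t, out$clade[i], allowed_interlopers))
      "monophyletic" else "non-monophyletic"
  }, character(1))
  out
}
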