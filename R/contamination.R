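empty_ledger <- function() {
  data.frame(gf = character(), seq_id = character(), iteration = integer(),
             mode = character(), rule_id = character(),
             observed_context = character(),
             terminal_branch_length = numeric(),
             threshold_applied = numeric(),
             stringsAsFactors = FALSE)
}

ledger_row <- function(gf, seq_id, mode, rule_id, context, tbl, threshold) {
  data.frame(gf = gf, seq_id = seq_id, iteration = NA_integer_,
             mode = mode, rule_id = rule_id,
             observed_context = context,
             terminal_branch_length = tbl,
             threshold_applied = threshold,
             stringsAsFactors = FALSE)
}

#' Apply sister rules to one gene tree
#'
#' For each leaf matching a rule's target prefix, the rule fires when (i)
#' the leaf is the sole target-matching leaf among its parent's leaf
#' children ("single sequences" — a target cherry pair is subsister
#' territory), (ii) every member of its pooled sister group matches one of
#' the rule's forbidden prefixes, and (iii) under `branch_mode = "short"`,
#' the leaf's terminal branch length is below `multiplier` times the tree's
#' average node-to-tip distance. All firings are evaluated against the input
#' topology and returned together; nothing is re-evaluated after a removal
#' within the call.
#'
#' @param t A rooted gene tree.
#' @param rules List of [sister_rule()] objects.
#' @param branch_stat Mode passed to [avg_node_to_tip()].
#' @return A removal-ledger data.frame (zero rows when nothing fires).
#' @export
apply_sister_rules <- function(t, rules, branch_stat = "terminal") {
  out <- empty_ledger()
  if (length(rules) == 0L) return(out)
  gf <- attr(t, "gf") %||% parse_seq_id(t$tip.label[1])$gf
  tips <- t$tip.label
  codes <- substr(tips, 1, 10)
  tbl <- terminal_branch_lengths(t)
  avg <- avg_node_to_tip(t, branch_stat)
  par <- parent_of(t)
  n_tip <- ape::Ntip(t)
  removed <- character()
  for (rule in rules) {
    is_target <- matches_prefix(codes, rule$target)
    for (i in which(is_target)) {
      leaf <- tips[i]
      # sole target-matching leaf among the parent's leaf children
      kids <- t$edge[t$edge[, 1] == par[i], 2]
      leaf_kids <- kids[kids <= n_tip]
      if (sum(matches_prefix(codes[leaf_kids], rule$target)) != 1L) next
      sis <- sister_group(t, leaf)
      if (length(sis) == 0L) next
      sis_codes <- unique(substr(sis, 1, 10))
      if (!all(matches_any_prefix(sis_codes, rule$forbidden_sisters))) next
      threshold <- NA_real_
      if (rule$branch_mode == "short") {
        threshold <- rule$multiplier * avg
        if (!(tbl[[leaf]] < threshold)) next
      }
      if (leaf %in% removed) next  # first matching rule wins
      removed <- c(removed, leaf)
      out <- rbind(out, ledger_row(
        gf, leaf, "sister", rule$rule_id,
        paste0("sisters=", paste(sort(sis_codes), collapse = ",")),
        tbl[[leaf]], threshold))
    }
  }
  out
}

#' Apply subsister rules to one gene tree
#'
#' For each cherry whose two leaves match a rule's pair (one leaf per pair
#' member), both leaves are removed when the cherry's joint sister group
#' satisfies the forbidden specification: every joint-sister leaf matches a
#' positive forbidden prefix, and/or (for `non-X` entries) no joint-sister
#' leaf matches `X`.
#'
#' @param t A rooted gene tree.
#' @param rules List of [subsister_rule()] objects.
#' @return A removal-ledger data.frame.
#' @export
apply_subsister_rules <- function(t, rules) {
  out <- empty_ledger()
  if (length(rules) == 0L) return(out)
  gf <- attr(t, "gf") %||% parse_seq_id(t$tip.label[1])$gf
  tips <- t$tip.label
  codes <- substr(tips, 1, 10)
  tbl <- terminal_branch_lengths(t)
  n_tip <- ape::Ntip(t)
  removed <- character()
  # cherries: internal nodes with exactly two children, both tips
  parents <- unique(t$edge[, 1])
  for (rule in rules) {
    for (v in parents) {
      kids <- t$edge[t$edge[, 1] == v, 2]
      if (length(kids) != 2L || !all(kids <= n_tip)) next
      a <- tips[kids[1]]; b <- tips[kids[2]]
      ok <- (matches_prefix(codes[kids[1]], rule$pair[[1]]) &&
               matches_prefix(codes[kids[2]], rule$pair[[2]])) ||
            (matches_prefix(codes[kids[1]], rule$pair[[2]]) &&
               matches_prefix(codes[kids[2]], rule$pair[[1]]))
      if (!ok) next
      # joint sister group: leaves of the cherry node's siblings
      sis <- node_sister_leaves(t, v)
      if (length(sis) == 0L) next
      sis_codes <- unique(substr(sis, 1, 10))
      cond <- TRUE
      if (length(rule$positive))
        cond <- cond && all(matches_any_prefix(sis_codes, rule$positive))
      for (cp in rule$complement)
        cond <- cond && !any(matches_prefix(sis_codes, cp))
      if (!cond) next
      for (leaf in setdiff(c(a, b), removed)) {
        removed <- c(removed, leaf)
        out <- rbind(out, ledger_row(
          gf, leaf, "subsister", rule$rule_id,
          paste0("cherry=", paste(sort(c(a, b)), collapse = "+"),
                 ";joint_sisters=", paste(sort(sis_codes), collapse = ",")),
          tbl[[leaf]], NA_real_))
      }
    }
  }
  out
}

# leaves of the sibling subtree(s) of an internal node
node_sister_leaves <- function(t, v) {
  par <- parent_of(t)[v]
  if (par == 0L) return(character())
  sets <- clade_leafsets(t)
  sibs <- t$edge[t$edge[, 1] == par, 2]
  sibs <- sibs[sibs != v]
  unlist(lapply(sibs, function(s) sets[[s]]), use.names = FALSE)
}

#' Clade grabbing on one gene tree
#'
#' For each rule, qualifying clades are the maximal clades from
#' [enumerate_clades()] whose distinct target-code count reaches
#' `min_target`. Every target-matching leaf outside all qualifying clades is
#' removed unless its taxon matches an exception prefix. Non-target leaves
#' are never removed.
#'
#' @param t A rooted gene tree.
#' @param rules List of [clade_rule()] objects.
#' @return List with `kept` (character vector of retained leaf labels) and
#'   `removals` (ledger data.frame).
#' @export
clade_grab <- function(t, rules) {
  out <- empty_ledger()
  gf <- attr(t, "gf") %||% parse_seq_id(t$tip.label[1])$gf
  tips <- t$tip.label
  codes <- substr(tips, 1, 10)
  tbl <- terminal_branch_lengths(t)
  removed <- character()
  for (rule in rules) {
    hits <- enumerate_clades(t, rule$target, rule$nontarget_allowance)
    qual <- hits[hits$target_count >= rule$min_target, , drop = FALSE]
    protected <- unique(unlist(qual$leaf_set, use.names = FALSE))
    is_target <- matches_prefix(codes, rule$target)
    exempt <- matches_any_prefix(codes, rule$exceptions)
    drop <- tips[is_target & !exempt & !(tips %in% protected)]
    for (leaf in setdiff(drop, removed)) {
      removed <- c(removed, leaf)
      out <- rbind(out, ledger_row(
        gf, leaf, "clade", rule$rule_id,
        sprintf("qualifying_clades=%d;min_target=%d", nrow(qual), rule$min_target),
        tbl[[leaf]], NA_real_))
    }
  }
  list(kept = setdiff(tips, removed), removals = out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Contamination-loop phase descriptor
#'
#' @param mode `"sister"`, `"subsister"` or `"clade"`.
#' @param rules List of rule objects of the matching class.
#' @param n_iterations Maximum iterations for this phase; the phase stops
#'   early once an iteration removes nothing.
#' @return A `loop_phase` object.
#' @export
loop_phase <- function(mode = c("sister", "subsister", "clade"), rules,
                       n_iterations = 1L) {
  mode <- match.arg(mode)
  cls <- paste0(if (mode == "clade") "clade" else mode, "_rule")
  if (length(rules) && !all(vapply(rules, inherits, logical(1), cls)))
    stop(sprintf("phase mode '%s' requires rules of class %s", mode, cls),
         call. = FALSE)
  structure(list(mode = mode, rules = rules,
                 n_iterations = as.integer(n_iterations)),
            class = "loop_phase")
}

#' Rebuild callback that prunes a fixed starting tree
#'
#' The contamination loop re-builds each gene tree after every removal
#' round. Full tree re-inference is delegated to a user callback; this
#' built-in fallback instead prunes the removed leaves from the gene
#' family's starting topology, which is deterministic and preserves the
#' relationships among the kept leaves exactly.
#'
#' @param trees Named list (by GF token) of starting `phylo` trees.
#' @return A function `(seq_ids, gf) -> phylo` suitable for [run_loop()].
#' @export
prune_rebuild <- function(trees) {
  force(trees)
  function(seq_ids, gf) {
    t0 <- trees[[gf]]
    if (is.null(t0)) stop("no starting tree for GF ", gf, call. = FALSE)
    if (!all(seq_ids %in% t0$tip.label))
      stop("rebuild requested leaves absent from the starting tree for GF ", gf,
           call. = FALSE)
    out <- ape::keep.tip(t0, seq_ids)
    attr(out, "gf") <- gf
    out
  }
}

#' Run the iterative contamination loop
#'
#' Executes an ordered schedule of phases over per-gene-family sequence
#' sets. Each phase repeats \{rebuild tree, root it, apply the phase's
#' rules, remove the flagged leaves\} up to its iteration budget, stopping
#' early when an iteration removes nothing. The removal ledger accumulates
#' across phases; every removed sequence has exactly one row, and for every
#' gene family kept + removed equals the input set.
#'
#' @param seqs_by_gf Named list (by GF token) of character vectors of
#'   sequence ids, or of named character vectors of sequences (names = ids).
#' @param rebuild Callback `(seq_ids, gf) -> phylo`; see [prune_rebuild()].
#' @param phases List of [loop_phase()] objects, executed in order.
#' @param root_strategy,outgroup_prefixes Passed to [root_gene_tree()].
#' @param branch_stat Passed to [apply_sister_rules()].
#' @param min_leaves Trees are only built (and rules applied) while at least
#'   this many sequences remain (default 3, the rooting minimum).
#' @return List with `kept` (named list of kept sequence id vectors or
#'   sequence vectors, matching the input form), `ledger` (data.frame with
#'   phase and iteration columns filled), and `skipped` (GFs whose rebuild
#'   failed, with the error messages).
#' @export
run_loop <- function(seqs_by_gf, rebuild, phases,
                     root_strategy = "outgroup_prefixes",
                     outgroup_prefixes = c("Ba", "Za"),
                     branch_stat = "terminal",
                     min_leaves = 3L) {
  stopifnot(is.list(seqs_by_gf), !is.null(names(seqs_by_gf)))
  ledger <- empty_ledger()
  ledger$phase <- integer()
  kept <- seqs_by_gf
  skipped <- character()
  for (gf in names(seqs_by_gf)) {
    cur <- kept[[gf]]
    ids <- if (!is.null(names(cur))) names(cur) else cur
    failed <- FALSE
    for (ph_i in seq_along(phases)) {
      ph <- phases[[ph_i]]
      if (length(ph$rules) == 0L) next
      for (iter in seq_len(ph$n_iterations)) {
        if (length(ids) < min_leaves) break
        t <- tryCatch(rebuild(ids, gf), error = function(e) e)
        if (inherits(t, "error")) {
          skipped[gf] <- conditionMessage(t)
          failed <- TRUE
          break
        }
        attr(t, "gf") <- attr(t, "gf") %||% gf
        t <- root_gene_tree(t, root_strategy, outgroup_prefixes)
        rows <- switch(ph$mode,
          sister = apply_sister_rules(t, ph$rules, branch_stat),
          subsister = apply_subsister_rules(t, ph$rules),
          clade = clade_grab(t, ph$rules)$removals)
        if (nrow(rows) == 0L) break
        rows$iteration <- iter
        rows$phase <- ph_i
        ledger <- rbind(ledger, rows)
        ids <- setdiff(ids, rows$seq_id)
      }
      if (failed) break
    }
    if (!failed) {
      kept[[gf]] <- if (!is.null(names(cur))) cur[ids] else ids
    }
  }
  rownames(ledger) <- NULL
  list(kept = kept, ledger = ledger, skipped = skipped)
}

#' Write a removal ledger to TSV
#' @param ledger Ledger data.frame from [run_loop()] or the per-tree rule
#'   appliers.
#' @param path Output TSV path.
#' @export
write_ledger <- function(ledger, path) {
  utils::write.table(ledger, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
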