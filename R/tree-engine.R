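#' Read gene trees from a Newick file
#'
#' Reads one or more Newick trees (one per line or concatenated). Every leaf
#' label must parse as a sequence identifier (see [parse_seq_id()]); trees
#' with duplicate leaf labels are rejected. Trees without branch lengths get
#' all-zero lengths and are flagged via the `"lengths_absent"` attribute.
#'
#' @param path Path to a Newick file.
#' @param gf Optional gene-family token to attach to each tree; by default it
#'   is taken from the first leaf's identifier.
#' @return A list of `phylo` objects (class `multiPhylo` semantics not
#'   required; a plain list), each with attributes `gf` and `lengths_absent`.
#' @export
read_gene_trees <- function(path, gf = NULL) {
  trees <- ape::read.tree(path)
  if (is.null(trees)) stop("no parseable Newick tree in ", path, call. = FALSE)
  if (inherits(trees, "phylo")) trees <- list(trees)
  lapply(trees, validate_gene_tree, gf = gf)
}

#' Validate a phylo object as a gene tree
#'
#' @param t A `phylo` object whose tip labels are sequence identifiers.
#' @param gf Optional gene-family token override.
#' @return The validated tree with `gf` and `lengths_absent` attributes set.
#' @export
validate_gene_tree <- function(t, gf = NULL) {
  stopifnot(inherits(t, "phylo"))
  if (anyDuplicated(t$tip.label)) {
    dup <- t$tip.label[duplicated(t$tip.label)][1]
    stop(sprintf("duplicate leaf label '%s'", dup), call. = FALSE)
  }
  for (lab in t$tip.label) {
    res <- try(parse_seq_id(lab), silent = TRUE)
    if (inherits(res, "try-error"))
      stop(sprintf("leaf label '%s' is not a valid sequence id: %s",
                   lab, attr(res, "condition")$message), call. = FALSE)
  }
  absent <- is.null(t$edge.length)
  if (absent) t$edge.length <- rep(0, nrow(t$edge))
  if (any(t$edge.length < 0)) stop("negative branch length", call. = FALSE)
  if (is.null(gf)) gf <- parse_seq_id(t$tip.label[1])$gf
  attr(t, "gf") <- gf
  attr(t, "lengths_absent") <- absent
  t
}

#' Write gene trees to a Newick file
#'
#' @param trees A `phylo` or list of `phylo` objects.
#' @param path Output path; one tree per line.
#' @export
write_gene_trees <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  txt <- vapply(trees, ape::write.tree, character(1))
  writeLines(txt, path)
  invisible(path)
}

#' Root a gene tree
#'
#' The default strategy roots on the edge subtending the largest clade (at
#' least two leaves) whose leaves all match one of the outgroup prefixes
#' (prokaryotes `Ba`/`Za` by default), evaluated over the unrooted split set
#' so the current orientation does not matter. Ties are broken by the
#' lexicographically smallest leaf label contained in the clade. When no such
#' clade exists — no outgroup leaves at all, or the outgroup is reduced to
#' scattered single leaves (itself a frequent symptom of contamination, and
#' too unreliable to anchor a root) — the tree is midpoint rooted. Midpoint
#' rooting can also be requested directly.
#'
#' @param t A gene tree (`phylo`).
#' @param strategy `"outgroup_prefixes"` (default) or `"midpoint"`.
#' @param outgroup_prefixes Character vector of clade prefixes used as the
#'   rooting outgroup.
#' @return A rooted `phylo` carrying over the `gf` attribute.
#' @export
root_gene_tree <- function(t, strategy = c("outgroup_prefixes", "midpoint"),
                           outgroup_prefixes = c("Ba", "Za")) {
  strategy <- match.arg(strategy)
  if (ape::Ntip(t) < 3L)
    stop("rooting requires at least 3 leaves", call. = FALSE)
  gf <- attr(t, "gf"); absent <- attr(t, "lengths_absent")
  out <- NULL
  if (strategy == "outgroup_prefixes") {
    tips <- t$tip.label
    is_out <- matches_any_prefix(substr(tips, 1, 10), outgroup_prefixes)
    if (any(is_out)) {
      # candidate outgroup clades: each side of each split that is
      # pure-outgroup; singleton sides are not trusted as outgroups
      best <- NULL
      for (side in unrooted_splits(t)) {
        if (length(side) >= 2L && all(is_out[match(side, tips)])) {
          if (is.null(best) ||
              length(side) > length(best) ||
              (length(side) == length(best) && min(side) < min(best))) {
            best <- side
          }
        }
      }
      if (!is.null(best) && length(best) < length(tips))
        out <- ape::root(t, outgroup = best, resolve.root = TRUE)
    }
  }
  if (is.null(out)) out <- phangorn::midpoint(t)
  attr(out, "gf") <- gf
  attr(out, "lengths_absent") <- absent
  out
}

# all splits of an unrooted tree, as leaf-label sets: both orientations of
# every edge (trivial terminal splits included, whole-set excluded)
unrooted_splits <- function(t) {
  tips <- t$tip.label
  n <- length(tips)
  desc <- clade_leafsets(t)
  sides <- list()
  for (s in desc) {
    if (length(s) < n) {
      sides[[length(sides) + 1L]] <- s
      sides[[length(sides) + 1L]] <- setdiff(tips, s)
    }
  }
  unique(sides)
}

# leaf-label set below every node (tips included), indexed by node number
clade_leafsets <- function(t) {
  n_tip <- ape::Ntip(t)
  n_node <- t$Nnode
  total <- n_tip + n_node
  kids <- vector("list", total)
  for (i in seq_len(nrow(t$edge)))
    kids[[t$edge[i, 1]]] <- c(kids[[t$edge[i, 1]]], t$edge[i, 2])
  sets <- vector("list", total)
  sets[seq_len(n_tip)] <- as.list(t$tip.label)
  for (i in ape::postorder(t)) {
    parent <- t$edge[i, 1]; child <- t$edge[i, 2]
    sets[[parent]] <- c(sets[[parent]], sets[[child]])
  }
  sets
}

# parent lookup: named numeric vector child -> parent
parent_of <- function(t) {
  p <- integer(ape::Ntip(t) + t$Nnode)
  p[t$edge[, 2]] <- t$edge[, 1]
  p
}

# terminal branch length of each tip, named by tip label
terminal_branch_lengths <- function(t) {
  term <- t$edge[, 2] <= ape::Ntip(t)
  len <- t$edge.length[term]
  names(len) <- t$tip.label[t$edge[term, 2]]
  len[t$tip.label]
}

#' Average node-to-tip distance of a gene tree
#'
#' The branch-length statistic that parameterises short-branch sister rules.
#' By default this is the mean terminal branch length over all leaves — the
#' comparable quantity when gating removal of an individual leaf by its own
#' terminal branch. A root-to-tip variant (mean path length from the root to
#' each leaf) is available behind `mode`.
#'
#' @param t A rooted gene tree.
#' @param mode `"terminal"` (default) or `"root_to_tip"`.
#' @return A single non-negative number; 0 when lengths are absent.
#' @export
avg_node_to_tip <- function(t, mode = c("terminal", "root_to_tip")) {
  mode <- match.arg(mode)
  if (is.null(t$edge.length)) return(0)
  if (mode == "terminal") {
    mean(terminal_branch_lengths(t))
  } else {
    depths <- ape::node.depth.edgelength(t)
    mean(depths[seq_len(ape::Ntip(t))])
  }
}

#' Sister group of a leaf
#'
#' Returns the leaves of the sibling subtree(s) of the query leaf: all
#' descendants of the other children of its parent, pooled when the parent
#' is a multifurcation.
#'
#' @param t A rooted gene tree.
#' @param leaf A tip label.
#' @return Character vector of sequence ids (never contains the query).
#' @export
sister_group <- function(t, leaf) {
  i <- match(leaf, t$tip.label)
  if (is.na(i)) stop(sprintf("leaf '%s' not found", leaf), call. = FALSE)
  par <- parent_of(t)[i]
  sets <- clade_leafsets(t)
  sibs <- t$edge[t$edge[, 1] == par, 2]
  sibs <- sibs[sibs != i]
  unlist(lapply(sibs, function(s) sets[[s]]), use.names = FALSE)
}

#' Cherry partner of a leaf
#'
#' @param t A rooted gene tree.
#' @param leaf A tip label.
#' @return The other leaf label if the query's parent has exactly two
#'   children, both leaves; otherwise `NULL`.
#' @export
cherry_partner <- function(t, leaf) {
  i <- match(leaf, t$tip.label)
  if (is.na(i)) stop(sprintf("leaf '%s' not found", leaf), call. = FALSE)
  par <- parent_of(t)[i]
  kids <- t$edge[t$edge[, 1] == par, 2]
  if (length(kids) == 2L && all(kids <= ape::Ntip(t)))
    return(t$tip.label[kids[kids != i]])
  NULL
}

resolve_allowance <- function(allowance, total_codes) {
  if (length(allowance) != 1L || is.na(allowance))
    stop("non-target allowance must be a single non-negative value", call. = FALSE)
  if (is.character(allowance)) {
    if (!grepl("%$", allowance)) stop("character allowance must be 'p%'", call. = FALSE)
    allowance <- as.numeric(sub("%$", "", allowance)) / 100
    if (allowance > 1) stop("fractional allowance outside [0,1]", call. = FALSE)
    return(floor(allowance * total_codes + 1e-9))
  }
  if (allowance < 0)
    stop("non-target allowance must be non-negative", call. = FALSE)
  if (allowance < 1 && allowance > 0) {
    return(floor(allowance * total_codes + 1e-9))
  }
  if (allowance != floor(allowance) && allowance > 1)
    stop("allowance must be an integer count, a fraction in [0,1], or 'p%'", call. = FALSE)
  allowance
}

#' Enumerate maximal qualifying clades
#'
#' Finds all maximal nodes (tips included) whose descendant leaf sets contain
#' at least one taxon matching the target prefix and whose number of
#' non-target taxa stays within an allowance. The allowance is an absolute
#' count (integer >= 1 or 0), a fraction in (0,1) of the distinct taxon codes
#' in the clade, or a string `"10%"`. All counts are over distinct
#' 10-character taxon codes, not sequences. Maximal means not contained in
#' another qualifying clade.
#'
#' @param t A rooted gene tree.
#' @param target A clade prefix (string or [clade_prefix()]).
#' @param max_nontarget Non-target allowance (count, fraction, or `"p%"`).
#' @return A data.frame with one row per clade hit: `node`, `target_count`,
#'   `nontarget_count`, `n_leaves`, and a list-column `leaf_set`.
#' @export
enumerate_clades <- function(t, target, max_nontarget = 0) {
  target <- clade_prefix(target)
  sets <- clade_leafsets(t)
  n_tip <- ape::Ntip(t)
  total <- n_tip + t$Nnode
  qual <- logical(total)
  stats <- vector("list", total)
  for (v in seq_len(total)) {
    leaves <- sets[[v]]
    if (is.null(leaves)) next
    codes <- unique(substr(leaves, 1, 10))
    tc <- sum(matches_prefix(codes, target))
    ntc <- length(codes) - tc
    if (tc >= 1L) {
      allow <- resolve_allowance(max_nontarget, length(codes))
      if (ntc <= allow) {
        qual[v] <- TRUE
        stats[[v]] <- list(target_count = tc, nontarget_count = ntc, leaves = leaves)
      }
    }
  }
  # maximality: drop any qualifying node with a qualifying proper ancestor
  par <- parent_of(t)
  maximal <- qual
  for (v in which(qual)) {
    a <- par[v]
    while (a != 0L) {
      if (qual[a]) { maximal[v] <- FALSE; break }
      a <- par[a]
    }
  }
  hits <- which(maximal)
  out <- data.frame(
    node = hits,
    target_count = vapply(hits, function(v) stats[[v]]$target_count, integer(1)),
    nontarget_count = vapply(hits, function(v) stats[[v]]$nontarget_count, integer(1)),
    n_leaves = vapply(hits, function(v) length(stats[[v]]$leaves), integer(1))
  )
  out$leaf_set <- lapply(hits, function(v) stats[[v]]$leaves)
  out
}

#' Monophyly of a clade prefix, with an interloper allowance
#'
#' Evaluated over the unrooted split set: the prefix is monophyletic if some
#' side of some split (or the whole leaf set) contains every target-matching
#' leaf with at most `allowed_interlopers` non-matching distinct taxon codes.
#' With 0 interlopers the answer is therefore invariant under re-rooting.
#'
#' @param t A gene tree (rooted or not).
#' @param target A clade prefix.
#' @param allowed_interlopers Maximum distinct non-target taxon codes
#'   tolerated inside the containing clade.
#' @return `TRUE` or `FALSE`.
#' @export
is_monophyletic <- function(t, target, allowed_interlopers = 0L) {
  target <- clade_prefix(target)
  tips <- t$tip.label
  is_target <- matches_prefix(substr(tips, 1, 10), target)
  if (!any(is_target))
    stop(sprintf("no leaf matches target prefix '%s'", target$text), call. = FALSE)
  n_codes <- function(leaves) length(unique(substr(leaves, 1, 10)))
  interlopers <- function(leaves) {
    codes <- unique(substr(leaves, 1, 10))
    sum(!matches_prefix(codes, target))
  }
  # the whole leaf set always contains all targets
  if (interlopers(tips) <= allowed_interlopers) return(TRUE)
  targets <- tips[is_target]
  for (side in unrooted_splits(t)) {
    if (all(targets %in% side) && interlopers(side) <= allowed_interlopers)
      return(TRUE)
  }
  FALSE
}
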