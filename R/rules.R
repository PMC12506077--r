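#' Sister rule constructor
#'
#' A sister rule removes a single sequence of the target lineage when its
#' entire sister group in a gene tree matches a forbidden lineage. In
#' `branch_mode = "any"` form ("blanket" rules) branch lengths are ignored;
#' in `"short"` form the leaf is removed only if its terminal branch is
#' shorter than `multiplier` times the tree's average node-to-tip distance
#' (default multiplier 0.5).
#'
#' @param rule_id Identifier string.
#' @param target Clade prefix whose sequences may be removed.
#' @param forbidden_sisters Character vector of clade prefixes; the rule
#'   fires only when every sister-group taxon matches one of them.
#' @param branch_mode `"any"` or `"short"`.
#' @param multiplier Positive multiplier on the average node-to-tip distance
#'   (used only when `branch_mode = "short"`).
#' @return Object of class `sister_rule`.
#' @export
sister_rule <- function(rule_id, target, forbidden_sisters,
                        branch_mode = c("any", "short"), multiplier = 0.5) {
  branch_mode <- match.arg(branch_mode)
  if (length(forbidden_sisters) == 0L)
    stop("forbidden_sisters must be non-empty", call. = FALSE)
  if (!is.numeric(multiplier) || multiplier <= 0)
    stop("multiplier must be positive", call. = FALSE)
  target <- clade_prefix(target)
  forbidden_sisters <- lapply(forbidden_sisters, clade_prefix)
  structure(list(rule_id = rule_id, target = target,
                 forbidden_sisters = forbidden_sisters,
                 branch_mode = branch_mode, multiplier = multiplier),
            class = "sister_rule")
}

#' Subsister rule constructor
#'
#' A subsister rule removes a pair of co-contaminant sequences that form a
#' cherry together (one leaf matching each pair member) when their joint
#' sister group matches the forbidden specification. Forbidden entries may
#' be plain prefixes (every joint-sister leaf must match one of them) or the
#' complement form `"non-X"` (no joint-sister leaf may match `X`), as in
#' "sister to non-Opisthokonta" = `"non-Op"`.
#'
#' @param rule_id Identifier string.
#' @param pair Character vector of two distinct clade prefixes.
#' @param forbidden_joint_sisters Character vector of prefixes and/or
#'   `"non-X"` complements.
#' @return Object of class `subsister_rule`.
#' @export
subsister_rule <- function(rule_id, pair, forbidden_joint_sisters) {
  if (length(pair) != 2L || pair[1] == pair[2])
    stop("pair must be two distinct clade prefixes", call. = FALSE)
  if (length(forbidden_joint_sisters) == 0L)
    stop("forbidden_joint_sisters must be non-empty", call. = FALSE)
  pair <- lapply(pair, clade_prefix)
  is_compl <- startsWith(forbidden_joint_sisters, "non-")
  positive <- lapply(forbidden_joint_sisters[!is_compl], clade_prefix)
  complement <- lapply(sub("^non-", "", forbidden_joint_sisters[is_compl]), clade_prefix)
  structure(list(rule_id = rule_id, pair = pair,
                 positive = positive, complement = complement),
            class = "subsister_rule")
}

#' Clade-grabbing rule constructor
#'
#' A clade rule retains only target-lineage sequences that fall inside
#' monophyletic clades containing at least `min_target` distinct target
#' taxon codes, tolerating a bounded number (or fraction) of non-target
#' codes. Target sequences outside every qualifying clade are removed unless
#' their taxon matches an exception prefix (orphan lineages that lack close
#' relatives). Non-target sequences are never removed by a clade rule.
#'
#' @param rule_id Identifier string.
#' @param target Clade prefix being grabbed.
#' @param min_target Minimum distinct target taxon codes per qualifying clade.
#' @param nontarget_allowance Count, fraction in (0,1), or `"p%"` string.
#' @param exceptions Character vector of exempt clade prefixes.
#' @return Object of class `clade_rule`.
#' @export
clade_rule <- function(rule_id, target, min_target, nontarget_allowance = 0,
                       exceptions = character()) {
  if (!is.numeric(min_target) || min_target < 1)
    stop("min_target must be a positive count", call. = FALSE)
  structure(list(rule_id = rule_id, target = clade_prefix(target),
                 min_target = as.integer(min_target),
                 nontarget_allowance = nontarget_allowance,
                 exceptions = lapply(exceptions, clade_prefix)),
            class = "clade_rule")
}

#' Read sister/subsister rules from TSV
#'
#' Expected columns: `rule_id`, `mode` (`sister` or `subsister`), `target`
#' (for subsisters the two pair members joined by `;`), `forbidden`
#' (comma-joined prefixes, `non-` complement allowed for subsisters),
#' `branch_mode` (`any`/`short`), `multiplier`. Header row required; lines
#' starting with `#` are ignored.
#'
#' @param path TSV path.
#' @return List of `sister_rule` / `subsister_rule` objects.
#' @export
read_sister_rules <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("rule_id", "mode", "target", "forbidden")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("rules file ", path, " lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    forb <- trimws(strsplit(row$forbidden, ",")[[1]])
    if (identical(row$mode, "sister")) {
      sister_rule(row$rule_id, row$target, forb,
                  branch_mode = if ("branch_mode" %in% names(df) && nzchar(row$branch_mode))
                    row$branch_mode else "any",
                  multiplier = if ("multiplier" %in% names(df) && !is.na(row$multiplier))
                    as.numeric(row$multiplier) else 0.5)
    } else if (identical(row$mode, "subsister")) {
      pair <- trimws(strsplit(row$target, ";")[[1]])
      subsister_rule(row$rule_id, pair, forb)
    } else {
      stop(sprintf("unknown rule mode '%s' in %s", row$mode, path), call. = FALSE)
    }
  })
}

#' Read clade-grabbing rules from TSV
#'
#' Expected columns: `rule_id`, `target`, `min_target`, `allowance` (integer
#' or `"p%"`), and optionally `exceptions_file` (path to a one-prefix-per-line
#' list, resolved relative to the rules file) or `exceptions` (comma-joined
#' prefixes inline).
#'
#' @param path TSV path.
#' @return List of `clade_rule` objects.
#' @export
read_clade_rules <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("rule_id", "target", "min_target")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("clade rules file ", path, " lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    allow <- if ("allowance" %in% names(df) && nzchar(row$allowance)) {
      if (grepl("%$", row$allowance)) row$allowance else as.numeric(row$allowance)
    } else 0
    exc <- character()
    if ("exceptions" %in% names(df) && nzchar(row$exceptions))
      exc <- trimws(strsplit(row$exceptions, ",")[[1]])
    if ("exceptions_file" %in% names(df) && nzchar(row$exceptions_file)) {
      f <- row$exceptions_file
      if (!file.exists(f)) f <- file.path(dirname(path), row$exceptions_file)
      exc <- c(exc, read_id_list(f))
    }
    clade_rule(row$rule_id, row$target, as.numeric(row$min_target), allow, exc)
  })
}
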