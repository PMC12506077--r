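# Independent brute-force oracles. These deliberately avoid the package's
# internal traversal helpers: leaf sets come from ape::extract.clade /
# ape::prop.part, maximality from pairwise subset checks, and the codon
# statistics from direct tabulation with the standard-code family lists
# written out by hand.

oracle_leaves_of_node <- function(t, v) {
  if (v <= ape::Ntip(t)) t$tip.label[v] else ape::extract.clade(t, v)$tip.label
}

oracle_resolve_allowance <- function(allowance, total_codes) {
  if (is.character(allowance))
    return(floor(as.numeric(sub("%$", "", allowance)) / 100 * total_codes + 1e-9))
  if (allowance > 0 && allowance < 1)
    return(floor(allowance * total_codes + 1e-9))
  allowance
}

# every maximal qualifying clade, by exhaustive per-node evaluation
oracle_enumerate_clades <- function(t, target, allowance) {
  nodes <- seq_len(ape::Ntip(t) + t$Nnode)
  qual <- list()
  for (v in nodes) {
    leaves <- oracle_leaves_of_node(t, v)
    codes <- unique(substr(leaves, 1, 10))
    tc <- sum(startsWith(codes, target) &
                (nchar(target) == 10 |
                   substr(codes, nchar(target) + 1, nchar(target) + 1) == "_"))
    ntc <- length(codes) - tc
    if (tc >= 1 && ntc <= oracle_resolve_allowance(allowance, length(codes)))
      qual[[length(qual) + 1L]] <- sort(leaves)
  }
  # maximal = not a proper subset of another qualifying set
  keep <- vapply(seq_along(qual), function(i) {
    !any(vapply(seq_along(qual), function(j)
      i != j && all(qual[[i]] %in% qual[[j]]), logical(1)))
  }, logical(1))
  unique(qual[keep])
}

# exhaustive clade-grab: target leaves outside every qualifying clade
oracle_clade_grab <- function(t, target, min_target, allowance,
                              exceptions = character()) {
  match_pref <- function(codes, p)
    startsWith(codes, p) &
      (nchar(p) == 10 | substr(codes, nchar(p) + 1, nchar(p) + 1) == "_")
  clades <- oracle_enumerate_clades(t, target, allowance)
  qual <- Filter(function(s) {
    codes <- unique(substr(s, 1, 10))
    sum(match_pref(codes, target)) >= min_target
  }, clades)
  protected <- unique(unlist(qual))
  codes <- substr(t$tip.label, 1, 10)
  is_t <- match_pref(codes, target)
  exempt <- Reduce(`|`, lapply(exceptions, function(p) match_pref(codes, p)),
                   rep(FALSE, length(codes)))
  sort(t$tip.label[is_t & !exempt & !(t$tip.label %in% protected)])
}

# rooting-independent monophyly over the split set from ape::prop.part
oracle_is_monophyletic <- function(t, target, k = 0) {
  labs <- t$tip.label
  match_pref <- function(codes)
    startsWith(codes, target) &
      (nchar(target) == 10 |
         substr(codes, nchar(target) + 1, nchar(target) + 1) == "_")
  pp <- ape::prop.part(t)
  sides <- lapply(pp, function(ix) attr(pp, "labels")[ix])
  sides <- c(sides, lapply(sides, function(s) setdiff(labs, s)),
             as.list(labs), lapply(labs, function(x) setdiff(labs, x)),
             list(labs))
  targets <- labs[match_pref(substr(labs, 1, 10))]
  stopifnot(length(targets) > 0)
  for (s in sides) {
    if (!all(targets %in% s)) next
    codes <- unique(substr(s, 1, 10))
    if (sum(!match_pref(codes)) <= k) return(TRUE)
  }
  FALSE
}

# exhaustive (node, sequence) search for the representative ortholog, with
# the package's documented tie-breaks restated from scratch
oracle_select_ortholog <- function(t, taxon, alignment = NULL) {
  codes <- substr(t$tip.label, 1, 10)
  mine <- t$tip.label[codes == taxon]
  if (length(mine) == 0) return(NULL)
  if (length(mine) == 1) return(mine)
  minor <- substr(taxon, 1, 5)
  best <- NULL; key <- NULL
  for (v in seq_len(ape::Ntip(t) + t$Nnode)) {
    leaves <- oracle_leaves_of_node(t, v)
    if (!any(leaves %in% mine)) next
    lc <- unique(substr(leaves, 1, 10))
    dens <- sum(startsWith(lc, minor) &
                  substr(lc, 6, 6) %in% c("_", ""))
    cand_key <- list(dens, length(leaves), min(leaves))
    if (is.null(key) || dens > key[[1]] ||
        (dens == key[[1]] && length(leaves) < key[[2]]) ||
        (dens == key[[1]] && length(leaves) == key[[2]] && min(leaves) < key[[3]])) {
      best <- leaves; key <- cand_key
    }
  }
  cand <- mine[mine %in% best]
  score <- vapply(cand, function(id) {
    len <- regmatches(id, regexpr("(?<=length_)[0-9]+", id, perl = TRUE))
    cov <- regmatches(id, regexpr("(?<=cov_)[0-9.]+", id, perl = TRUE))
    len <- if (length(len)) as.numeric(len) else
      if (!is.null(alignment[[id]])) nchar(gsub("-", "", alignment[[id]])) else 0
    if (length(cov)) len * as.numeric(cov) else len
  }, numeric(1))
  cand[order(-score, cand)][1]
}

# --- codon statistics, standard code, families written out by hand --------

.oracle_fams <- list(
  Phe = c("TTT", "TTC"), Leu = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"),
  Ile = c("ATT", "ATC", "ATA"), Val = c("GTT", "GTC", "GTA", "GTG"),
  Ser = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
  Pro = c("CCT", "CCC", "CCA", "CCG"), Thr = c("ACT", "ACC", "ACA", "ACG"),
  Ala = c("GCT", "GCC", "GCA", "GCG"), Tyr = c("TAT", "TAC"),
  His = c("CAT", "CAC"), Gln = c("CAA", "CAG"), Asn = c("AAT", "AAC"),
  Lys = c("AAA", "AAG"), Asp = c("GAT", "GAC"), Glu = c("GAA", "GAG"),
  Cys = c("TGT", "TGC"), Arg = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"),
  Gly = c("GGT", "GGC", "GGA", "GGG"), Met = "ATG", Trp = "TGG")

oracle_codons <- function(cds) {
  cds <- chartr("U", "T", toupper(cds))
  v <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  v <- v[!grepl("[^ACGT]", v)]
  # trim a terminal stop
  if (length(v) && v[length(v)] %in% c("TAA", "TAG", "TGA")) v <- v[-length(v)]
  v
}

oracle_gc3s <- function(cds) {
  v <- oracle_codons(cds)
  eligible <- unlist(.oracle_fams[vapply(.oracle_fams, length, 1L) > 1])
  v <- v[v %in% eligible]
  if (!length(v)) return(NA_real_)
  mean(substr(v, 3, 3) %in% c("G", "C"))
}

oracle_enc <- function(cds) {
  v <- oracle_codons(cds)
  cnt <- table(factor(v, levels = unlist(.oracle_fams)))
  f_of <- function(codons) {
    n <- sum(cnt[codons])
    if (n < 2) return(NA_real_)
    p <- as.numeric(cnt[codons]) / n
    f <- (n * sum(p^2) - 1) / (n - 1)
    if (f <= 0) NA_real_ else f
  }
  degs <- vapply(.oracle_fams, length, 1L)
  fbar <- sapply(c(2, 3, 4, 6), function(k) {
    fs <- unlist(lapply(.oracle_fams[degs == k], f_of))
    mean(fs[!is.na(fs)])
  })
  names(fbar) <- c("2", "3", "4", "6")
  if (is.nan(fbar[["3"]]) && !is.nan(fbar[["2"]]) && !is.nan(fbar[["4"]]))
    fbar[["3"]] <- (fbar[["2"]] + fbar[["4"]]) / 2
  if (any(is.nan(fbar))) return(NA_real_)
  min(2 + 9 / fbar[["2"]] + 1 / fbar[["3"]] + 5 / fbar[["4"]] + 3 / fbar[["6"]], 61)
}
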