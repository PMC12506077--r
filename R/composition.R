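# Synonymous-family structure of a genetic code: codons grouped by encoded
# amino acid, stops dropped. Degeneracy classes are re-derived from the code
# table, so non-standard codes (ciliate nuclear etc.) are handled uniformly.
codon_families <- function(genetic_code = Biostrings::GENETIC_CODE) {
  aa <- genetic_code[genetic_code != "*"]
  split(names(aa), unname(aa))
}

split_codons <- function(cds) {
  cds <- toupper(gsub("\\s", "", cds))
  cds <- chartr("U", "T", cds)
  if (nchar(cds) %% 3 != 0)
    stop("coding sequence length not divisible by 3", call. = FALSE)
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  # ambiguity codes: skip whole codon
  codons[!grepl("[^ACGT]", codons)]
}

#' Silent-site GC content (GC3S)
#'
#' Fraction of G or C at the third positions of codons belonging to
#' synonymously variable amino-acid families under the given genetic code.
#' Single-codon families (Met and Trp under the standard code) and stop
#' codons are excluded; a terminal stop codon is trimmed; codons containing
#' ambiguity characters are skipped.
#'
#' @param cds Nucleotide coding sequence (string; T or U).
#' @param genetic_code Named character vector codon -> amino acid, as
#'   returned by [Biostrings::getGeneticCode()]; standard code by default.
#' @return Fraction in \[0, 1\], or `NA` when no eligible codon is present.
#' @export
gc3s <- function(cds, genetic_code = Biostrings::GENETIC_CODE) {
  codons <- split_codons(cds)
  if (length(codons) && genetic_code[codons[length(codons)]] == "*")
    codons <- codons[-length(codons)]
  fams <- codon_families(genetic_code)
  variable <- unlist(fams[vapply(fams, length, integer(1)) > 1L], use.names = FALSE)
  codons <- codons[codons %in% variable]
  if (length(codons) == 0L) return(NA_real_)
  third <- substr(codons, 3, 3)
  mean(third %in% c("G", "C"))
}

#' Effective number of codons (Nc)
#'
#' Wright's codon-usage-bias statistic: Nc ranges from the number of amino
#' acids (20, each using a single codon) to the number of sense codons (61
#' under the standard code, uniform usage). Computed as
#' `Nc = N1 + sum_k N_k / Fbar_k`, with `N_k` the number of k-fold
#' degenerate families in the code and `Fbar_k` the average family
#' homozygosity `F = (n * sum(p_i^2) - 1) / (n - 1)` over families observed
#' at least twice. A missing 3-fold class average is substituted by
#' `(Fbar_2 + Fbar_4) / 2`; any other missing class makes Nc undefined.
#' Values above the sense-codon count are capped.
#'
#' @inheritParams gc3s
#' @return Nc, or `NA` when family coverage is insufficient.
#' @export
enc <- function(cds, genetic_code = Biostrings::GENETIC_CODE) {
  codons <- split_codons(cds)
  if (length(codons) && genetic_code[codons[length(codons)]] == "*")
    codons <- codons[-length(codons)]
  fams <- codon_families(genetic_code)
  deg <- vapply(fams, length, integer(1))
  n_sense <- sum(deg)
  counts <- table(codons)
  # per-family homozygosity, for families with >= 2 observations
  f_by_class <- list()
  for (aa in names(fams)) {
    k <- deg[[aa]]
    if (k == 1L) next
    obs <- as.numeric(counts[fams[[aa]]])
    obs[is.na(obs)] <- 0
    n <- sum(obs)
    if (n < 2) next
    p <- obs / n
    f <- (n * sum(p^2) - 1) / (n - 1)
    if (f <= 0) next  # uninformative family at tiny n
    key <- as.character(k)
    f_by_class[[key]] <- c(f_by_class[[key]], f)
  }
  fbar <- vapply(f_by_class, mean, numeric(1))
  nc <- sum(deg == 1L)
  for (k in sort(unique(deg[deg > 1L]))) {
    key <- as.character(k)
    nk <- sum(deg == k)
    fk <- fbar[key]
    if (is.na(fk) || length(fk) == 0L) {
      if (k == 3L && all(c("2", "4") %in% names(fbar))) {
        fk <- (fbar[["2"]] + fbar[["4"]]) / 2
      } else {
        return(NA_real_)
      }
    }
    nc <- nc + nk / fk
  }
  min(nc, n_sense)
}

#' Per-sequence composition report
#'
#' @param cds Named character vector of nucleotide coding sequences
#'   (names = sequence ids).
#' @inheritParams gc3s
#' @return Data.frame `seq_id`, `gc3s`, `enc` (`NA` where undefined).
#' @export
compute_composition <- function(cds, genetic_code = Biostrings::GENETIC_CODE) {
  data.frame(
    seq_id = names(cds),
    gc3s = vapply(cds, function(s) tryCatch(gc3s(s, genetic_code),
                                            error = function(e) NA_real_), numeric(1)),
    enc = vapply(cds, function(s) tryCatch(enc(s, genetic_code),
                                           error = function(e) NA_real_), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Classify sequences by silent-site GC against per-taxon ranges
#'
#' Sequences inside their taxon's GC3S range keep the `OG6` class; those
#' above it are labelled `OGG` (GC-rich) and those below `OGA` (AT-rich).
#' Both range boundaries are closed. The gene-family token in the emitted
#' sequence id is rewritten to carry the class prefix.
#'
#' @param records Data.frame with columns `seq_id` and `gc3s` (e.g. from
#'   [compute_composition()]).
#' @param ranges Data.frame with columns `taxon`, `lower`, `upper`.
#' @param default_range Optional numeric length-2 `c(lower, upper)` used for
#'   taxa absent from `ranges`; an error is raised otherwise.
#' @return `records` with added `gc_class` and `labeled_id` columns.
#' @export
classify_gc <- function(records, ranges, default_range = NULL) {
  stopifnot(all(c("seq_id", "gc3s") %in% names(records)),
            all(c("taxon", "lower", "upper") %in% names(ranges)))
  if (any(ranges$lower > ranges$upper | ranges$lower < 0 | ranges$upper > 1))
    stop("invalid GC range: need 0 <= lower <= upper <= 1", call. = FALSE)
  taxa <- substr(records$seq_id, 1, 10)
  idx <- match(taxa, ranges$taxon)
  lower <- ranges$lower[idx]; upper <- ranges$upper[idx]
  if (anyNA(idx)) {
    if (is.null(default_range))
      stop("no GC range for taxon ", taxa[which(is.na(idx))[1]],
           " and no default supplied", call. = FALSE)
    lower[is.na(idx)] <- default_range[1]
    upper[is.na(idx)] <- default_range[2]
  }
  cls <- ifelse(is.na(records$gc3s), NA_character_,
         ifelse(records$gc3s > upper, "OGG",
         ifelse(records$gc3s < lower, "OGA", "OG6")))
  records$gc_class <- cls
  records$labeled_id <- records$seq_id
  ok <- !is.na(cls)
  records$labeled_id[ok] <- mapply(function(id, cl) {
    sub("OG[6GA]_([0-9]{6})$", paste0(cl, "_\\1"), id)
  }, records$seq_id[ok], cls[ok], USE.NAMES = FALSE)
  records
}

#' Read per-taxon GC ranges from TSV
#' @param path TSV with columns `taxon`, `lower`, `upper`.
#' @return Data.frame.
#' @export
read_gc_ranges <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("taxon", "lower", "upper") %in% names(df)))
  df
}

# identity of two amino-acid sequences under ends-free global alignment:
# matches / aligned length, internal gaps counted in the denominator,
# terminal overhangs excluded.
pairwise_identity <- function(a, b) {
  alpha <- unique(strsplit(paste0(a, b), "")[[1]])
  mat <- matrix(-1, length(alpha), length(alpha), dimnames = list(alpha, alpha))
  diag(mat) <- 1
  aln <- Biostrings::pairwiseAlignment(a, b, type = "overlap",
                                       substitutionMatrix = mat,
                                       gapOpening = 2, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  if (length(pa) == 0L) return(0)
  sum(pa == sb & pa != "-") / length(pa)
}

#' Similarity filter: drop near-duplicate sequences within a taxon
#'
#' Greedy clustering of one taxon's amino-acid sequences within one gene
#' family, in descending length order (ties: lexicographically smallest id
#' first). A sequence is dropped when its pairwise identity to an
#' already-kept sequence reaches the cutoff (99% by default); identity is
#' matches over aligned length, counting internal gaps and excluding
#' terminal overhangs.
#'
#' @param seqs Named character vector of amino-acid sequences (one taxon,
#'   one gene family).
#' @param identity_cutoff Drop threshold in (0, 1]; default 0.99.
#' @return Named character vector of kept sequences.
#' @export
similarity_filter <- function(seqs, identity_cutoff = 0.99) {
  if (length(seqs) <= 1L) return(seqs)
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  kept <- character()
  for (id in names(seqs)) {
    dup <- FALSE
    for (kid in kept) {
      if (pairwise_identity(seqs[[id]], seqs[[kid]]) >= identity_cutoff) {
        dup <- TRUE
        break
      }
    }
    if (!dup) kept <- c(kept, id)
  }
  seqs[kept]
}

#' Relative-length filter against gene-family mean lengths
#'
#' Keeps a sequence iff its length is between one-third and 1.5 times the
#' reference mean length of its gene family (closed bounds). Sequences
#' whose gene family is absent from the reference table are kept with a
#' warning.
#'
#' @param seqs Named character vector of sequences (names = sequence ids,
#'   from which the gene-family token is parsed).
#' @param gf_mean_lengths Named numeric vector (GF token -> mean length) or
#'   data.frame with columns `gf`, `mean_len`.
#' @return Named character vector of kept sequences.
#' @export
relative_length_filter <- function(seqs, gf_mean_lengths) {
  if (is.data.frame(gf_mean_lengths))
    gf_mean_lengths <- stats::setNames(gf_mean_lengths$mean_len, gf_mean_lengths$gf)
  gfs <- vapply(names(seqs), function(id) parse_seq_id(id)$gf, character(1))
  keep <- logical(length(seqs))
  for (i in seq_along(seqs)) {
    m <- gf_mean_lengths[gfs[i]]
    if (is.na(m)) {
      warning("no reference mean length for GF ", gfs[i], "; keeping ", names(seqs)[i],
              call. = FALSE)
      keep[i] <- TRUE
    } else {
      len <- nchar(gsub("-", "", seqs[[i]], fixed = TRUE))
      keep[i] <- len >= m / 3 && len <= 1.5 * m
    }
  }
  seqs[keep]
}
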