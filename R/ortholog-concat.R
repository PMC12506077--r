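#' Score a sequence for ortholog selection
#'
#' Score = residue length times k-mer coverage when coverage is parseable
#' from the contig token (`cov_<float>`, as emitted by transcriptome
#' assemblers), otherwise just length. Length is taken from the contig token
#' (`length_<int>`) when present, else from the ungapped sequence if one is
#' supplied, else 0.
#'
#' @param seq_id Sequence identifier string.
#' @param seq Optional (aligned or unaligned) sequence used as a length
#'   fallback; gaps are not counted.
#' @return A single numeric score.
#' @export
seq_score <- function(seq_id, seq = NULL) {
  sid <- parse_seq_id(seq_id)
  len <- sid$contig_length
  if (is.na(len)) {
    len <- if (!is.null(seq)) nchar(gsub("-", "", seq, fixed = TRUE)) else 0
  }
  if (!is.na(sid$contig_cov)) len * sid$contig_cov else len
}

#' Select the representative ortholog of a taxon in a gene tree
#'
#' When a gene family contains several sequences from one taxon, the
#' representative is chosen from the monophyletic clade that contains the
#' greatest number of distinct taxon codes of the taxon's own clade (its
#' minor clade by default): among all nodes containing at least one of the
#' taxon's sequences, the node maximising that count wins (ties: fewest
#' leaves, then lexicographically smallest contained leaf label), and within
#' the winning clade the taxon's sequence with the highest [seq_score()] is
#' returned (ties: lexicographically smallest id).
#'
#' @param t A rooted gene tree.
#' @param taxon A 10-character taxon code (string or [parse_taxon_code()]).
#' @param alignment Optional named character vector (id -> aligned sequence)
#'   used as a length fallback for scoring.
#' @param clade_level `"minor"` (default) or `"major"`: the granularity at
#'   which relative density is counted.
#' @return The selected sequence id, or `NULL` if the taxon is absent.
#' @export
select_ortholog <- function(t, taxon, alignment = NULL,
                            clade_level = c("minor", "major")) {
  clade_level <- match.arg(clade_level)
  code <- taxon_of(taxon)
  tips <- t$tip.label
  codes <- substr(tips, 1, 10)
  mine <- tips[codes == code]
  if (length(mine) == 0L) return(NULL)
  if (length(mine) == 1L) return(mine)
  group_prefix <- if (clade_level == "minor") substr(code, 1, 5) else substr(code, 1, 2)
  sets <- clade_leafsets(t)
  best <- NULL; best_density <- -1L; best_size <- Inf; best_min <- ""
  for (v in seq_along(sets)) {
    leaves <- sets[[v]]
    if (is.null(leaves) || !any(leaves %in% mine)) next
    dens <- length(unique(substr(leaves, 1, 10)[
      matches_prefix(substr(leaves, 1, 10), group_prefix)]))
    size <- length(leaves)
    mn <- min(leaves)
    better <- dens > best_density ||
      (dens == best_density && size < best_size) ||
      (dens == best_density && size == best_size && mn < best_min)
    if (better) {
      best <- leaves; best_density <- dens; best_size <- size; best_min <- mn
    }
  }
  cand <- mine[mine %in% best]
  scores <- vapply(cand, function(id) seq_score(id, alignment[[id]]), numeric(1))
  cand <- cand[order(-scores, cand)]
  cand[1]
}

#' Build a gap-filled supermatrix from per-gene-family alignments
#'
#' Concatenates one selected sequence per taxon per gene family, in the
#' given partition order. Taxa absent from a gene family are filled with
#' `-` gaps across that partition. Column indices in the partition map are
#' 0-based, half-open.
#'
#' @param alignments Named list (by GF token) of named character vectors
#'   (sequence id -> aligned sequence); each alignment must be equal-width.
#' @param taxa Character vector of taxon codes (row order of the matrix).
#' @param selected Data.frame with columns `gf`, `taxon`, `seq_id` mapping
#'   each (gene family, taxon) to its representative, e.g. from
#'   [select_orthologs()].
#' @return Object of class `supermatrix`: list with `taxa`, `rows` (named
#'   character vector of concatenated residue strings), and `partitions`
#'   (data.frame `gf`, `start`, `end`).
#' @export
build_supermatrix <- function(alignments, taxa, selected) {
  if (length(alignments) == 0L) stop("no alignments supplied", call. = FALSE)
  stopifnot(all(c("gf", "taxon", "seq_id") %in% names(selected)))
  widths <- integer(length(alignments))
  for (k in seq_along(alignments)) {
    w <- unique(nchar(alignments[[k]]))
    if (length(w) != 1L)
      stop("alignment for GF ", names(alignments)[k], " has unequal row widths",
           call. = FALSE)
    widths[k] <- w
  }
  gfs <- names(alignments)
  starts <- cumsum(c(0L, widths[-length(widths)]))
  rows <- stats::setNames(rep("", length(taxa)), taxa)
  for (k in seq_along(gfs)) {
    gf <- gfs[k]
    aln <- alignments[[k]]
    gap_row <- strrep("-", widths[k])
    sel <- selected[selected$gf == gf, , drop = FALSE]
    for (tax in taxa) {
      id <- sel$seq_id[sel$taxon == tax]
      if (length(id) == 1L && !is.na(id)) {
        if (!id %in% names(aln))
          stop(sprintf("selected id '%s' missing from GF %s alignment", id, gf),
               call. = FALSE)
        rows[[tax]] <- paste0(rows[[tax]], aln[[id]])
      } else {
        rows[[tax]] <- paste0(rows[[tax]], gap_row)
      }
    }
  }
  structure(list(
    taxa = taxa, rows = rows,
    partitions = data.frame(gf = gfs, start = starts, end = starts + widths)
  ), class = "supermatrix")
}

#' Select representatives for every (gene family, taxon) pair
#'
#' Convenience wrapper running [select_ortholog()] across a set of gene
#' trees.
#'
#' @param trees Named list (by GF token) of rooted gene trees.
#' @param taxa Character vector of taxon codes.
#' @param alignments Optional named list of alignments (length fallback).
#' @param clade_level Passed to [select_ortholog()].
#' @return Data.frame `gf`, `taxon`, `seq_id` (NA when the taxon is absent).
#' @export
select_orthologs <- function(trees, taxa, alignments = NULL,
                             clade_level = "minor") {
  out <- expand.grid(gf = names(trees), taxon = taxa,
                     stringsAsFactors = FALSE)
  out$seq_id <- NA_character_
  for (i in seq_len(nrow(out))) {
    sel <- select_ortholog(trees[[out$gf[i]]], out$taxon[i],
                           alignments[[out$gf[i]]], clade_level)
    if (!is.null(sel)) out$seq_id[i] <- sel
  }
  out
}

#' Mask high-gap alignment columns
#'
#' Removes every column whose gap fraction is at or above the threshold
#' ("at least 95% gaps" removed at `max_gap_fraction = 0.95`); retained
#' columns have gap fraction strictly below it. Works on a plain named
#' character vector of equal-width rows or on a [build_supermatrix()]
#' result, whose partition map is re-indexed.
#'
#' @param aln Named character vector of aligned rows, or a `supermatrix`.
#' @param max_gap_fraction Threshold in (0, 1].
#' @return Object of the same shape with offending columns removed.
#' @export
mask_gap_columns <- function(aln, max_gap_fraction = 0.95) {
  if (!is.numeric(max_gap_fraction) || max_gap_fraction <= 0 || max_gap_fraction > 1)
    stop("max_gap_fraction must be in (0, 1]", call. = FALSE)
  sm <- inherits(aln, "supermatrix")
  rows <- if (sm) aln$rows else aln
  if (length(rows) == 0L) stop("empty alignment", call. = FALSE)
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("alignment rows have unequal widths", call. = FALSE)
  if (w == 0L) stop("empty alignment", call. = FALSE)
  mat <- do.call(rbind, strsplit(rows, ""))
  gap_frac <- colMeans(mat == "-")
  keep <- gap_frac < max_gap_fraction
  new_rows <- apply(mat[, keep, drop = FALSE], 1, paste, collapse = "")
  new_rows <- stats::setNames(new_rows, names(rows))
  if (!sm) return(new_rows)
  # re-index partitions: count surviving columns per original partition
  parts <- aln$partitions
  new_w <- vapply(seq_len(nrow(parts)), function(i) {
    sum(keep[(parts$start[i] + 1L):parts$end[i]])
  }, integer(1))
  starts <- cumsum(c(0L, new_w[-length(new_w)]))
  structure(list(taxa = aln$taxa, rows = new_rows,
                 partitions = data.frame(gf = parts$gf, start = starts,
                                         end = starts + new_w)),
            class = "supermatrix")
}

#' Write a supermatrix and its partition map
#'
#' Emits the concatenated alignment as FASTA (rows named by taxon code), a
#' TSV partition map (`gf`, `start`, `end`; 0-based half-open), and a
#' RAxML-style partition file (`PROT, gf = start-end` with 1-based closed
#' ranges).
#'
#' @param sm A `supermatrix`.
#' @param fasta,partitions_tsv,partitions_raxml Output paths (NULL to skip).
#' @export
write_supermatrix <- function(sm, fasta = NULL, partitions_tsv = NULL,
                              partitions_raxml = NULL) {
  stopifnot(inherits(sm, "supermatrix"))
  if (!is.null(fasta)) write_fasta(sm$rows, fasta)
  if (!is.null(partitions_tsv))
    utils::write.table(sm$partitions, partitions_tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(partitions_raxml)) {
    lines <- sprintf("PROT, %s = %d-%d", sm$partitions$gf,
                     sm$partitions$start + 1L, sm$partitions$end)
    writeLines(lines, partitions_raxml)
  }
  invisible(sm)
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d taxa x %d columns, %d partitions\n",
              length(x$taxa), if (length(x$rows)) nchar(x$rows[[1]]) else 0L,
              nrow(x$partitions)))
  invisible(x)
}
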