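# The eight recognised major-clade tokens: Bacteria, Archaea, Opisthokonta,
# Amoebozoa, excavate lineages, SAR, Archaeplastida, orphan lineages.
MAJOR_CLADES <- c("Ba", "Za", "Op", "Am", "Ex", "Sr", "Pl", "EE")

GF_REGEX <- "OG[6GA]_[0-9]{6}"

#' Parse a 10-character taxon code
#'
#' Taxon codes have the fixed layout `MM_mm_Ssss`: a two-letter major-clade
#' token (one of `Ba`, `Za`, `Op`, `Am`, `Ex`, `Sr`, `Pl`, `EE`), a two-letter
#' minor-clade token, and a four-character species/sample token, separated by
#' underscores. Humans, for example, are `Op_me_Hsap` (Opisthokonta, metazoa,
#' Homo sapiens). Each distinct 10-character code is treated as the counting
#' unit throughout the package; conspecific samples (`Am_tu_Hp01`,
#' `Am_tu_Hp02`) count separately.
#'
#' @param s A character string of length 10.
#' @return An object of class `taxon_code`: a list with fields `major`,
#'   `minor`, `species` and `full` (the input, preserved verbatim).
#' @examples
#' parse_taxon_code("Op_me_Hsap")
#' parse_taxon_code("Pl_gr_Atha")$major
#' @export
parse_taxon_code <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(s))
    stop("taxon code must be a single non-empty string", call. = FALSE)
  if (nchar(s) != 10L)
    stop(sprintf("malformed taxon code '%s': expected 10 characters, got %d",
                 s, nchar(s)), call. = FALSE)
  if (substr(s, 3L, 3L) != "_" || substr(s, 6L, 6L) != "_")
    stop(sprintf("malformed taxon code '%s': underscores must sit at positions 3 and 6", s),
         call. = FALSE)
  major <- substr(s, 1L, 2L)
  minor <- substr(s, 4L, 5L)
  species <- substr(s, 7L, 10L)
  if (!major %in% MAJOR_CLADES)
    stop(sprintf("unknown major clade '%s' in taxon code '%s' (expected one of %s)",
                 major, s, paste(MAJOR_CLADES, collapse = ", ")), call. = FALSE)
  if (grepl("_", minor, fixed = TRUE) || grepl("_", species, fixed = TRUE))
    stop(sprintf("malformed taxon code '%s': stray underscore inside a token", s),
         call. = FALSE)
  structure(list(major = major, minor = minor, species = species, full = s),
            class = "taxon_code")
}

#' @export
format.taxon_code <- function(x, ...) x$full

#' @export
print.taxon_code <- function(x, ...) {
  cat(sprintf("<taxon_code> %s  (major=%s minor=%s species=%s)\n",
              x$full, x$major, x$minor, x$species))
  invisible(x)
}

#' Test whether a string is a valid taxon code
#' @param s Character vector.
#' @return Logical vector.
#' @export
is_valid_taxon_code <- function(s) {
  vapply(s, function(x) {
    !inherits(try(parse_taxon_code(x), silent = TRUE), "try-error")
  }, logical(1), USE.NAMES = FALSE)
}

#' Parse a full sequence identifier
#'
#' Sequence identifiers begin with the 10-character taxon code, continue with
#' a free-form contig/CDS token (which for transcriptome assemblies embeds
#' `length_<int>` and `cov_<float>` fields), and end with a gene-family token
#' `OG6_` + six digits (`OGG`/`OGA` variants mark GC-rich / AT-rich
#' composition classes). Parsing is greedy: the taxon is always the first 10
#' characters, the GF token is always the final `OG[6GA]_\\d{6}` match, and
#' the contig is everything in between.
#'
#' @param s A sequence identifier string.
#' @return An object of class `seq_id`: list with `taxon` (a [parse_taxon_code()]
#'   result), `contig`, `gf`, `full`, and parsed `contig_length` / `contig_cov`
#'   (NA when the contig token does not carry them).
#' @examples
#' sid <- parse_seq_id("Am_tu_Hp01_NODE_7_length_900_cov_12.5_OG6_000123")
#' sid$gf
#' sid$contig_cov
#' @export
parse_seq_id <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(s))
    stop("sequence id must be a single non-empty string", call. = FALSE)
  if (nchar(s) < 10L)
    stop(sprintf("sequence id '%s' is shorter than a taxon code", s), call. = FALSE)
  taxon <- parse_taxon_code(substr(s, 1L, 10L))
  m <- regexpr(paste0(GF_REGEX, "$"), s)
  if (m < 0L)
    stop(sprintf("sequence id '%s' lacks a terminal gene-family token (OG6_/OGG_/OGA_ + 6 digits)", s),
         call. = FALSE)
  gf <- substr(s, m, nchar(s))
  contig <- substr(s, 11L, m - 1L)
  contig <- sub("^_", "", sub("_$", "", contig))
  if (!nzchar(contig))
    stop(sprintf("sequence id '%s' has no contig token between taxon code and gene-family token", s),
         call. = FALSE)
  len <- regmatches(contig, regexpr("(?<=length_)[0-9]+", contig, perl = TRUE))
  cov <- regmatches(contig, regexpr("(?<=cov_)[0-9]+\\.?[0-9]*", contig, perl = TRUE))
  structure(list(
    taxon = taxon, contig = contig, gf = gf, full = s,
    contig_length = if (length(len)) as.numeric(len) else NA_real_,
    contig_cov = if (length(cov)) as.numeric(cov) else NA_real_
  ), class = "seq_id")
}

#' @export
format.seq_id <- function(x, ...) x$full

#' @export
print.seq_id <- function(x, ...) {
  cat(sprintf("<seq_id> %s\n  taxon=%s contig=%s gf=%s\n",
              x$full, x$taxon$full, x$contig, x$gf))
  invisible(x)
}

#' Construct / validate a clade prefix
#'
#' Curation rules address taxa at three levels: major clade (`"Op"`), minor
#' clade (`"Op_me"`), or a full taxon code (`"Op_me_Hsap"`). The level is
#' derived from the string length.
#'
#' @param text Prefix string at one of the three levels.
#' @return Object of class `clade_prefix` with fields `text` and `level`
#'   (one of `"major"`, `"minor"`, `"taxon"`).
#' @examples
#' clade_prefix("Sr_ci")$level
#' @export
clade_prefix <- function(text) {
  if (inherits(text, "clade_prefix")) return(text)
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("clade prefix must be a single string", call. = FALSE)
  level <- switch(as.character(nchar(text)),
                  "2" = "major", "5" = "minor", "10" = "taxon", NA_character_)
  if (is.na(level))
    stop(sprintf("clade prefix '%s' must be 2 (major), 5 (minor) or 10 (full code) characters", text),
         call. = FALSE)
  # validate by extending to a syntactically complete code
  probe <- switch(level,
                  major = paste0(text, "_xx_Xxxx"),
                  minor = paste0(text, "_Xxxx"),
                  taxon = text)
  parse_taxon_code(probe)
  structure(list(text = text, level = level), class = "clade_prefix")
}

taxon_of <- function(id) {
  if (inherits(id, "seq_id")) return(id$taxon$full)
  if (inherits(id, "taxon_code")) return(id$full)
  if (is.character(id)) return(substr(id, 1L, 10L))
  stop("cannot extract a taxon code from object of class ", class(id)[1])
}

#' Prefix match at a token boundary
#'
#' Tests whether a taxon code (or the taxon part of a sequence id) begins
#' with a clade prefix at a token boundary, so `"Op_me"` matches
#' `Op_me_Hsap` but not a hypothetical `Op_mel...`. Matching is reflexive on
#' full codes and monotone in prefix length.
#'
#' @param id A `seq_id`, `taxon_code`, or character string (a sequence id or
#'   taxon code); character vectors are vectorised.
#' @param p A `clade_prefix` or a prefix string.
#' @return Logical.
#' @examples
#' matches_prefix("Op_me_Hsap_c1_OG6_000001", "Op_me")
#' @export
matches_prefix <- function(id, p) {
  p <- clade_prefix(p)
  codes <- if (is.character(id)) substr(id, 1L, 10L) else taxon_of(id)
  n <- nchar(p$text)
  ok <- substr(codes, 1L, n) == p$text
  # token boundary: prefix ends at an underscore or the end of the code
  boundary <- n == 10L | substr(codes, n + 1L, n + 1L) == "_"
  ok & boundary
}

# vectorised: does each code match ANY of the prefixes?
matches_any_prefix <- function(codes, prefixes) {
  if (length(prefixes) == 0L) return(rep(FALSE, length(codes)))
  hit <- rep(FALSE, length(codes))
  for (p in prefixes) hit <- hit | matches_prefix(codes, p)
  hit
}

#' Read a one-identifier-per-line list
#'
#' @param path Path to a plain-text file, one sequence id or taxon code per
#'   line; blank lines and `#` comments are ignored.
#' @param validate Validate each entry with [parse_seq_id()] (`"seq"`),
#'   [parse_taxon_code()] (`"taxon"`), or not at all (`"none"`).
#' @return Character vector of identifiers.
#' @export
read_id_list <- function(path, validate = c("none", "seq", "taxon")) {
  validate <- match.arg(validate)
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (validate == "seq") invisible(lapply(x, parse_seq_id))
  if (validate == "taxon") invisible(lapply(x, parse_taxon_code))
  x
}
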