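#' Read a FASTA file into a named character vector
#'
#' Thin wrapper over Biostrings that returns plain named character vectors,
#' the representation the curation functions work on. Headers are truncated
#' at the first whitespace.
#'
#' @param path FASTA path.
#' @return Named character vector (header -> sequence).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  seqs <- as.character(x)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write a named character vector as FASTA
#'
#' @param seqs Named character vector (header -> sequence).
#' @param path Output path.
#' @param width Line width for wrapping (default 80).
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
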