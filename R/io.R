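# File input/output: FASTA corpora via Biostrings, tab-separated tables.
# All tables are written as TSV (header row, '.' decimal, UTF-8) with
# floating point at 6 significant digits.

#' Read a coding-sequence FASTA file
#'
#' Description lines are truncated at the first whitespace token, which
#' becomes the sequence identifier.
#'
#' @param path Path to a (multi-)FASTA file.
#' @return Named character vector of uppercase nucleotide sequences.
#' @export
read_cds_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a data.frame as a TSV file
#'
#' Numeric columns are rounded to 6 significant digits.
#'
#' @param df A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 6)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
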