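# FASTA I/O. Biostrings does the parsing/writing; we layer IUPAC validation
# with record/position error reporting on top, and keep sequences as plain
# character columns so results pipe through dplyr verbs.

#' Read a FASTA file into a tibble
#'
#' @param path Path to a FASTA file (may be multi-record; wrapped lines and
#'   blank lines are tolerated).
#' @return A tibble with columns `id` (header token up to the first
#'   whitespace), `seq` (uppercase IUPAC DNA) and `length` (bp). Empty input
#'   yields a zero-row tibble. A non-IUPAC character (including U) is an
#'   error naming the record and position.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  seqs <- unname(validate_dna(seqs, ids))
  tibble::tibble(id = ids, seq = seqs, length = nchar(seqs))
}

#' Write sequences to a FASTA file
#'
#' @param seqs A tibble with columns `id` and `seq` (as from [read_fasta()]).
#' @param path Output path. Sequences are wrapped at 60 columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  set <- Biostrings::BStringSet(setNames(toupper(seqs$seq), seqs$id))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}
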