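# IUPAC nucleotide algebra. Each of the 15 DNA ambiguity codes is stored as a
# 4-bit mask over {A=1, C=2, G=4, T=8}; set operations on expansions then
# reduce to bitwAnd. U is deliberately absent: this assay is DNA-only.

.BASE_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L)

.IUPAC_MASK <- vapply(
  Biostrings::IUPAC_CODE_MAP,
  function(x) sum(.BASE_BITS[strsplit(x, "")[[1]]]),
  integer(1)
)

.IUPAC_LETTERS <- names(.IUPAC_MASK)

.IUPAC_EXPANSION <- lapply(Biostrings::IUPAC_CODE_MAP,
                           function(x) strsplit(x, "")[[1]])

#' Expand an IUPAC code to the concrete bases it denotes
#'
#' @param code Character vector of single IUPAC letters (case-insensitive).
#' @return A list of character vectors, one per input letter; e.g. `"R"`
#'   expands to `c("A", "G")` and `"N"` to all four bases.
#' @examples
#' iupac_expand(c("N", "Y", "a"))
#' @export
iupac_expand <- function(code) {
  code <- toupper(code)
  bad <- !code %in% .IUPAC_LETTERS
  if (any(bad)) {
    abort(sprintf("invalid IUPAC code(s): %s",
                  paste(unique(code[bad]), collapse = ", ")))
  }
  .IUPAC_EXPANSION[code]
}

#' Test whether a subject base satisfies an IUPAC pattern position
#'
#' A concrete subject base matches when it belongs to the pattern code's
#' expansion. When the subject itself is ambiguous the `policy` decides:
#' `"intersect"` (default) accepts any overlap of the two expansions, which is
#' the permissive reading needed for reference sequences containing N runs;
#' `"subset"` requires the subject's expansion to lie entirely inside the
#' pattern's.
#'
#' @param pattern,subject Character vectors of single IUPAC letters; recycled
#'   to common length.
#' @param policy `"intersect"` or `"subset"`.
#' @return Logical vector.
#' @examples
#' iupac_match("R", c("A", "G", "C"))
#' iupac_match("R", "N", policy = "subset")
#' @export
iupac_match <- function(pattern, subject, policy = c("intersect", "subset")) {
  policy <- match.arg(policy)
  p <- .IUPAC_MASK[toupper(pattern)]
  s <- .IUPAC_MASK[toupper(subject)]
  if (anyNA(p) || anyNA(s)) {
    abort("invalid IUPAC code in pattern or subject")
  }
  if (policy == "intersect") {
    unname(bitwAnd(p, s) > 0L)
  } else {
    unname(bitwAnd(p, s) == s)
  }
}

# Encode a sequence string as a vector of bit masks; NA marks invalid letters.
.encode_iupac <- function(bases) {
  chars <- strsplit(toupper(bases), "")[[1]]
  unname(.IUPAC_MASK[chars])
}

#' Validate DNA strings against the IUPAC alphabet
#'
#' @param seq Character vector of sequences.
#' @param id Optional identifiers used in error messages.
#' @return `seq`, uppercased, invisibly usable downstream. Errors name the
#'   offending record and 1-based position; `U` is rejected (DNA only).
#' @export
validate_dna <- function(seq, id = NULL) {
  seq <- toupper(seq)
  if (is.null(id)) id <- as.character(seq_along(seq))
  for (i in seq_along(seq)) {
    codes <- .IUPAC_MASK[strsplit(seq[[i]], "")[[1]]]
    if (anyNA(codes)) {
      pos <- which(is.na(codes))[1]
      abort(sprintf(
        "invalid character '%s' in record '%s' at position %d (IUPAC DNA only; U is rejected)",
        substr(seq[[i]], pos, pos), id[[i]], pos
      ))
    }
  }
  seq
}

#' Reverse-complement DNA sequences, honouring ambiguity codes
#'
#' Applying the function twice returns the input; the complement map is the
#' usual involution on the 15 IUPAC codes (R<->Y, S<->S, ...).
#'
#' @param seq Character vector of IUPAC DNA strings.
#' @return Character vector of reverse complements, uppercase.
#' @examples
#' reverse_complement(c("AAR", "GGCC"))
#' @export
reverse_complement <- function(seq) {
  seq <- validate_dna(seq)
  out <- character(length(seq))
  nz <- nzchar(seq)
  if (any(nz)) {
    out[nz] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seq[nz])
    ))
  }
  out
}
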