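# In-silico PCR with degenerate primers. The scan is a positional IUPAC
# bitmask comparison (one vectorised pass per pattern position), so a 26-mer
# against a genome costs 26 vector operations. Coordinates are 0-based
# half-open internally and 1-based inclusive in every returned tibble.

.H60F_PATTERN <- "GGNGAYGGNACNACNACNGCNACNGT"
.H60R_PATTERN <- "TCNCCRAANCCNGGNGCYTTNACNGC"
# pattern bit codes, precomputed once: the scanners sit in tight loops
.H60F_CODES <- local(.encode_iupac(.H60F_PATTERN))
.H60R_RC_CODES <- local(.encode_iupac("GCNGTNAARGCNCCNGGNTTYGGNGA"))

#' The universal hsp60 primer pair
#'
#' H60F/H60R amplify ~590 bp of the bifidobacterial hsp60 (groEL) gene; the
#' oligos were designed on the conserved chaperonin peptide motifs GDGTTATV
#' and AVKAPGFGD and are written here in IUPAC one-letter form.
#'
#' @return A tibble with columns `name`, `pattern` (IUPAC) and `orientation`
#'   (`"forward"`/`"reverse"`).
#' @examples
#' hsp60_primers()
#' @export
hsp60_primers <- function() {
  tibble::tibble(
    name = c("H60F", "H60R"),
    pattern = c(.H60F_PATTERN, .H60R_PATTERN),
    orientation = c("forward", "reverse")
  )
}

# Core scanner: start positions (1-based) where `pattern` matches `subject`
# with at most `max_mismatches` failed positions. `mismatch_at = "concrete"`
# only charges mismatches at non-degenerate pattern positions.
.scan_sites <- function(subject_codes, pattern_codes, max_mismatches = 0L,
                        policy = c("intersect", "subset"),
                        mismatch_at = c("any", "concrete")) {
  policy <- match.arg(policy)
  mismatch_at <- match.arg(mismatch_at)
  n <- length(subject_codes)
  m <- length(pattern_codes)
  if (m == 0L || m > n) {
    return(tibble::tibble(start = integer(), mismatches = integer()))
  }
  counted <- if (mismatch_at == "concrete") {
    pattern_codes %in% .BASE_BITS
  } else {
    rep(TRUE, m)
  }
  mism <- integer(n - m + 1L)
  for (j in seq_len(m)) {
    s <- subject_codes[j:(n - m + j)]
    ok <- if (policy == "intersect") {
      bitwAnd(pattern_codes[[j]], s) > 0L
    } else {
      bitwAnd(pattern_codes[[j]], s) == s
    }
    if (counted[[j]]) mism <- mism + !ok
  }
  hit <- which(mism <= max_mismatches)
  tibble::tibble(start = hit, mismatches = mism[hit])
}

.as_primer_row <- function(primer) {
  if (is.character(primer) && length(primer) == 1L) {
    p <- hsp60_primers()
    p <- p[p$name == primer, ]
    if (nrow(p) == 0L) abort(sprintf("unknown primer '%s'", primer))
    return(p)
  }
  stopifnot(all(c("name", "pattern", "orientation") %in% names(primer)),
            nrow(primer) == 1L)
  primer
}

#' Locate degenerate-primer binding sites
#'
#' Forward primers are scanned as written on the forward strand; reverse
#' primers are scanned as their reverse complement on the forward strand (the
#' site where the amplicon's right end falls).
#'
#' @param seqs Tibble with columns `id`, `seq` (as from [read_fasta()]).
#' @param primer A primer name (`"H60F"`, `"H60R"`) or a one-row tibble with
#'   `name`, `pattern`, `orientation`.
#' @param max_mismatches Maximum number of pattern positions allowed to fail
#'   the IUPAC match (default 0: the primers are already highly degenerate).
#' @param policy Ambiguity policy for subject bases, see [iupac_match()].
#' @param mismatch_at `"any"` counts every failed position; `"concrete"`
#'   charges mismatches only at non-degenerate pattern positions.
#' @return Tibble `id`, `primer`, `start`, `end` (1-based inclusive),
#'   `strand`, `mismatches`, sorted by `id` then `start`. A primer longer
#'   than its subject simply yields no rows.
#' @export
find_primer_sites <- function(seqs, primer, max_mismatches = 0L,
                              policy = c("intersect", "subset"),
                              mismatch_at = c("any", "concrete")) {
  policy <- match.arg(policy)
  mismatch_at <- match.arg(mismatch_at)
  p <- .as_primer_row(primer)
  pattern <- if (p$orientation == "forward") p$pattern else reverse_complement(p$pattern)
  strand <- if (p$orientation == "forward") "+" else "-"
  pat_codes <- .encode_iupac(pattern)
  purrr::map_dfr(seq_len(nrow(seqs)), function(i) {
    hits <- .scan_sites(.encode_iupac(validate_dna(seqs$seq[[i]], seqs$id[[i]])),
                        pat_codes, max_mismatches, policy, mismatch_at)
    tibble::tibble(
      id = seqs$id[[i]], primer = p$name,
      start = hits$start, end = hits$start + length(pat_codes) - 1L,
      strand = strand, mismatches = hits$mismatches
    )
  }) |>
    dplyr::arrange(.data$id, .data$start)
}

# Forward/reverse pairing on one strand of one sequence (codes pre-encoded).
.pair_amplicons <- function(codes, fwd_codes, rev_rc_codes, max_mismatches,
                            policy, mismatch_at, min_len, max_len) {
  f <- .scan_sites(codes, fwd_codes, max_mismatches, policy, mismatch_at)$start
  r <- .scan_sites(codes, rev_rc_codes, max_mismatches, policy, mismatch_at)$start
  if (length(f) == 0L || length(r) == 0L) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  grid <- tidyr::expand_grid(f = f, r = r)
  grid$end <- grid$r + length(rev_rc_codes) - 1L
  grid$len <- grid$end - grid$f + 1L
  grid <- grid[grid$f < grid$r & grid$len >= min_len & grid$len <= max_len, ]
  tibble::tibble(start = grid$f, end = grid$end)
}

#' Extract amplicons bounded by a degenerate primer pair
#'
#' Every forward-site/reverse-site pairing whose primer-inclusive span falls
#' inside the length window is reported; both strands of the input are
#' searched and all coordinates refer to the forward strand of the input.
#' Zero amplicons is a valid result.
#'
#' @inheritParams find_primer_sites
#' @param fwd,rev Primer specifications (default the hsp60 pair H60F/H60R).
#' @param min_len,max_len Plausibility window for the product length in bp
#'   (default 400-900 around the ~590 bp assay product).
#' @return Tibble `id`, `start`, `end` (1-based inclusive, forward strand),
#'   `strand`, `length`, `seq` (the product as amplified, i.e.
#'   reverse-complemented for minus-strand products), sorted by `id`, `start`,
#'   `length`.
#' @export
extract_amplicons <- function(seqs, fwd = "H60F", rev = "H60R",
                              min_len = 400L, max_len = 900L,
                              max_mismatches = 0L,
                              policy = c("intersect", "subset"),
                              mismatch_at = c("any", "concrete")) {
  policy <- match.arg(policy)
  mismatch_at <- match.arg(mismatch_at)
  stopifnot(min_len <= max_len)
  fp <- .as_primer_row(fwd)
  rp <- .as_primer_row(rev)
  fwd_codes <- .encode_iupac(fp$pattern)
  rev_rc_codes <- .encode_iupac(reverse_complement(rp$pattern))
  purrr::map_dfr(seq_len(nrow(seqs)), function(i) {
    s <- validate_dna(seqs$seq[[i]], seqs$id[[i]])
    L <- nchar(s)
    codes <- .encode_iupac(s)
    plus <- .pair_amplicons(codes, fwd_codes, rev_rc_codes, max_mismatches,
                            policy, mismatch_at, min_len, max_len)
    minus <- .pair_amplicons(rev(.complement_code(codes)),
                             fwd_codes, rev_rc_codes, max_mismatches,
                             policy, mismatch_at, min_len, max_len)
    out <- dplyr::bind_rows(
      tibble::tibble(id = seqs$id[[i]], start = plus$start, end = plus$end,
                     strand = "+"),
      tibble::tibble(id = seqs$id[[i]], start = L - minus$end + 1L,
                     end = L - minus$start + 1L, strand = "-")
    )
    out$length <- out$end - out$start + 1L
    out$seq <- substr(rep(s, nrow(out)), out$start, out$end)
    flip <- out$strand == "-"
    if (any(flip)) out$seq[flip] <- reverse_complement(out$seq[flip])
    out
  }) |>
    dplyr::arrange(.data$id, .data$start, .data$length)
}

# Complement of a single bit code: reverse the 4-bit mask (A<->T, C<->G).
.complement_code <- function(code) {
  bitwOr(
    bitwOr(ifelse(bitwAnd(code, 1L) > 0L, 8L, 0L),
           ifelse(bitwAnd(code, 2L) > 0L, 4L, 0L)),
    bitwOr(ifelse(bitwAnd(code, 4L) > 0L, 2L, 0L),
           ifelse(bitwAnd(code, 8L) > 0L, 1L, 0L))
  )
}
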