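# Synthetic fixtures: amplicons with HaeIII sites planted at known offsets,
# optionally embedded in primer-free genomic flanks, so every pipeline stage
# can be tested against an analytically known answer without downloads.
# Everything is driven by an explicit seed and the caller's RNG state is
# left untouched.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.random_bases <- function(n, gc = 0.5) {
  if (n == 0L) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# One concrete realisation of an IUPAC pattern (uniform over expansions).
.concretize <- function(pattern) {
  paste(vapply(.IUPAC_EXPANSION[strsplit(toupper(pattern), "")[[1]]],
               function(x) x[[sample.int(length(x), 1L)]], character(1)),
        collapse = "")
}

# All primer binding sites of the hsp60 pair on both strands of `s`:
# starts of H60F-pattern matches and of reverse-complemented H60R matches,
# on the sequence and its reverse complement. Works on raw bit codes to stay
# cheap inside rejection loops.
.primer_hits <- function(s) {
  codes <- .encode_iupac(s)
  rc_codes <- rev(.complement_code(codes))
  list(
    fwd = .scan_sites(codes, .H60F_CODES)$start,
    rev = .scan_sites(codes, .H60R_RC_CODES)$start,
    fwd_rc = .scan_sites(rc_codes, .H60F_CODES)$start,
    rev_rc = .scan_sites(rc_codes, .H60R_RC_CODES)$start
  )
}

#' Generate a synthetic hsp60-style amplicon with known HaeIII cuts
#'
#' The sequence starts with a concrete realisation of H60F, ends with the
#' reverse complement of a realisation of H60R, and contains `GGCC` exactly
#' at the planted cut positions: position `p` means the enzyme cuts after the
#' p-th base, i.e. the site occupies bases `p-1..p+2`. The background is
#' rejection-sampled until no unplanned HaeIII site and no unplanned primer
#' match remains, so the fragment profile is known by construction:
#' `diff(c(0, cut_positions, length))`.
#'
#' @param seed Integer seed; the same seed always yields the same sequence.
#' @param amplicon_length Amplicon length in bp (default 590, the assay product).
#' @param cut_positions Strictly increasing integer positions (bp), each at
#'   least 4 from its neighbours and clear of the two 26 bp primer tracts.
#' @param gc GC fraction of the background (default 0.5).
#' @param max_tries Rejection-sampling budget before giving up (default 200).
#' @return A list with `seq` (a one-row tibble `id`, `seq`, `length`) and
#'   `expected_fragments` (integer vector).
#' @examples
#' synthetic_amplicon(1, cut_positions = c(196, 392))$expected_fragments
#' @export
synthetic_amplicon <- function(seed, amplicon_length = 590L,
                               cut_positions = integer(),
                               gc = 0.5, max_tries = 200L) {
  amplicon_length <- as.integer(amplicon_length)
  cut_positions <- as.integer(cut_positions)
  plen <- 26L
  if (amplicon_length < 2L * plen + 4L) abort("amplicon too short to hold both primers")
  if (is.unsorted(cut_positions, strictly = TRUE)) {
    abort("cut positions must be strictly increasing")
  }
  if (length(cut_positions) > 0L) {
    if (any(diff(cut_positions) < 4L)) {
      abort("cut positions closer than 4 bp cannot host disjoint GGCC sites")
    }
    if (any(cut_positions - 2L < plen) || any(cut_positions + 2L > amplicon_length - plen)) {
      abort("cut positions must be clear of the primer tracts and sequence ends")
    }
  }
  hae <- bifido_enzymes("HaeIII")
  .with_seed(seed, {
    primers <- hsp60_primers()
    for (try in seq_len(max_tries)) {
      # resample the primer concretizations each try: some realisations of
      # the degenerate patterns themselves contain a GGCC site
      fwd <- .concretize(primers$pattern[primers$orientation == "forward"])
      # concretizing the reverse-complemented pattern directly draws from the
      # same distribution as reverse-complementing a concretized H60R
      rev_rc <- .concretize("GCNGTNAARGCNCCNGGNTTYGGNGA")
      interior <- strsplit(.random_bases(amplicon_length - 2L * plen, gc), "")[[1]]
      seq_chars <- c(strsplit(fwd, "")[[1]], interior,
                     strsplit(rev_rc, "")[[1]])
      for (p in cut_positions) {
        seq_chars[(p - 1L):(p + 2L)] <- c("G", "G", "C", "C")
      }
      # break every unplanned GGCC by mutating one of its interior bases to A
      # (two GGCC occurrences can never overlap, so planted sites are safe);
      # occurrences entirely inside a primer tract are handled by resampling
      s <- paste(seq_chars, collapse = "")
      occ <- gregexpr("(?=GGCC)", s, perl = TRUE)[[1]]
      occ <- occ[occ > 0L]
      unplanned <- setdiff(occ, cut_positions - 1L)
      all_broken <- TRUE
      for (o in unplanned) {
        span <- o:(o + 3L)
        span <- span[span > plen & span <= amplicon_length - plen]
        if (length(span) == 0L) {  # inside a primer tract: resample
          all_broken <- FALSE
          break
        }
        seq_chars[span[[1]]] <- "A"
      }
      if (!all_broken) next
      s <- paste(seq_chars, collapse = "")
      tbl <- tibble::tibble(id = sprintf("synthetic_seed%d", seed), seq = s,
                            length = amplicon_length)
      cuts <- .cut_positions(s, hae)
      if (!identical(as.integer(cuts), cut_positions)) next
      hits <- .primer_hits(s)
      if (!identical(hits$fwd, 1L) ||
          !identical(hits$rev, amplicon_length - 25L) ||
          length(hits$fwd_rc) != 0L || length(hits$rev_rc) != 0L) next
      return(list(seq = tbl,
                  expected_fragments = diff(c(0L, cut_positions, amplicon_length))))
    }
    abort(sprintf("could not realise the requested site layout in %d tries",
                  max_tries))
  })
}

#' Embed synthetic amplicons in primer-free genomic flanks
#'
#' Builds a longer sequence containing `n_amplicons` copies of a planted
#' amplicon separated/surrounded by random background, rejection-sampled so
#' the background contains no primer match; [extract_amplicons()] must
#' therefore recover exactly the planted products at the planted coordinates.
#'
#' @inheritParams synthetic_amplicon
#' @param flank_lengths Two-element integer vector: bp of background before
#'   the first and after the last amplicon (also used between copies).
#' @param n_amplicons Number of embedded copies (default 1).
#' @return A list with `seq` (one-row tibble), `amplicon_starts` (1-based),
#'   `amplicon_length` and `expected_fragments`.
#' @export
synthetic_genome_context <- function(seed, amplicon_length = 590L,
                                     cut_positions = integer(),
                                     flank_lengths = c(150L, 150L),
                                     n_amplicons = 1L, gc = 0.5,
                                     max_tries = 200L) {
  stopifnot(length(flank_lengths) == 2L, all(flank_lengths >= 0L),
            n_amplicons >= 1L)
  amp <- synthetic_amplicon(seed, amplicon_length, cut_positions, gc, max_tries)
  aseq <- amp$seq$seq
  .with_seed(seed + 1L, {
    for (try in seq_len(max_tries)) {
      pieces <- character(2L * n_amplicons + 1L)
      pieces[[1]] <- .random_bases(flank_lengths[[1]], gc)
      for (k in seq_len(n_amplicons)) {
        pieces[[2L * k]] <- aseq
        pieces[[2L * k + 1L]] <- .random_bases(
          if (k == n_amplicons) flank_lengths[[2]] else flank_lengths[[1]], gc)
      }
      s <- paste(pieces, collapse = "")
      tbl <- tibble::tibble(id = sprintf("context_seed%d", seed), seq = s,
                            length = nchar(s))
      starts <- cumsum(c(1L, utils::head(nchar(pieces), -1L)))[2L * seq_len(n_amplicons)]
      sites <- .primer_hits(s)
      planted_ok <- identical(sites$fwd, as.integer(starts)) &&
        identical(sites$rev, as.integer(starts + amplicon_length - 26L)) &&
        length(sites$fwd_rc) == 0L && length(sites$rev_rc) == 0L
      if (!planted_ok) next
      hits <- extract_amplicons(tbl, min_len = amplicon_length,
                                max_len = amplicon_length)
      if (nrow(hits) == n_amplicons && all(hits$strand == "+") &&
          identical(sort(hits$start), as.integer(sort(starts))) &&
          all(hits$seq == aseq)) {
        return(list(seq = tbl, amplicon_starts = as.integer(sort(starts)),
                    amplicon_length = amplicon_length,
                    expected_fragments = amp$expected_fragments))
      }
    }
    abort(sprintf("could not build a primer-free context in %d tries",
                  max_tries))
  })
}
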