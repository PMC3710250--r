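# Restriction enzyme catalog and complete linear digestion.
#
# Sites are written in caret notation ("GG^CC": cut between the two pairs).
# Digestion is complete: every recognised site is cut exactly once, fragment
# lengths are the successive differences of the cut positions, and their sum
# always equals the sequence length.

#' Parse an enzyme catalog in caret notation
#'
#' @param path Path to a text file with lines `NAME<TAB>SITE`, the site an
#'   IUPAC string containing exactly one caret at the cut position. `#`
#'   comment lines and blank lines are skipped.
#' @return Tibble `enzyme`, `site` (caret removed), `cut_offset` (0-based
#'   offset of the cut within the site), `overhang` (`"blunt"`/`"sticky"`,
#'   derived: blunt iff the cut bisects the site). Duplicate names, zero or
#'   multiple carets, and non-IUPAC site letters are errors naming the line.
#' @export
read_enzyme_catalog <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) {
    return(tibble::tibble(enzyme = character(), site = character(),
                          cut_offset = integer(), overhang = character()))
  }
  recs <- purrr::map_dfr(keep, function(ln) {
    parts <- strsplit(lines[[ln]], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      abort(sprintf("line %d: expected NAME<TAB>SITE", ln))
    }
    raw <- parts[[2]]
    n_caret <- lengths(regmatches(raw, gregexpr("^", raw, fixed = TRUE)))
    if (n_caret == 0L) abort(sprintf("line %d: no cut position ('^') in site '%s'", ln, raw))
    if (n_caret > 1L) abort(sprintf("line %d: more than one cut position in site '%s'", ln, raw))
    site <- sub("^", "", raw, fixed = TRUE)
    if (nchar(site) < 2L) abort(sprintf("line %d: site '%s' shorter than 2 bp", ln, raw))
    ok <- tryCatch({validate_dna(site, parts[[1]]); TRUE},
                   error = function(e) FALSE)
    if (!ok) abort(sprintf("line %d: invalid IUPAC in site '%s'", ln, raw))
    cut <- regexpr("^", raw, fixed = TRUE)[[1]] - 1L
    tibble::tibble(enzyme = parts[[1]], site = toupper(site),
                   cut_offset = cut)
  })
  if (anyDuplicated(recs$enzyme)) {
    abort(sprintf("duplicate enzyme name(s): %s",
                  paste(unique(recs$enzyme[duplicated(recs$enzyme)]),
                        collapse = ", ")))
  }
  recs$overhang <- ifelse(nchar(recs$site) %% 2L == 0L &
                            recs$cut_offset == nchar(recs$site) / 2L,
                          "blunt", "sticky")
  recs
}

#' Built-in enzyme catalog
#'
#' The enzymes screened for the hsp60 assay: blunt-end frequent cutters
#' (HaeIII, RsaI, AluI, AccII) and the sticky-end enzymes Sau3AI, AatII and
#' PvuI.
#'
#' @param enzyme Optional name; if given, the single matching row is returned.
#' @return Tibble as from [read_enzyme_catalog()].
#' @examples
#' bifido_enzymes("HaeIII")
#' @export
bifido_enzymes <- function(enzyme = NULL) {
  cat <- .pkg_cache$catalog
  if (is.null(cat)) {
    cat <- read_enzyme_catalog(
      system.file("extdata", "enzymes.tsv", package = "bifidotyper",
                  mustWork = TRUE)
    )
    .pkg_cache$catalog <- cat
  }
  if (is.null(enzyme)) return(cat)
  row <- cat[cat$enzyme == enzyme, ]
  if (nrow(row) == 0L) abort(sprintf("enzyme '%s' not in the built-in catalog", enzyme))
  row
}

.as_enzyme_row <- function(enzyme) {
  if (is.character(enzyme) && length(enzyme) == 1L) return(bifido_enzymes(enzyme))
  stopifnot(all(c("enzyme", "site", "cut_offset") %in% names(enzyme)),
            nrow(enzyme) == 1L)
  enzyme
}

.is_palindromic_site <- function(site) {
  identical(reverse_complement(site), toupper(site))
}

# Cut positions (0-based, between-base) on one concrete/ambiguous sequence.
# Both strand nicks of every double-strand break are recorded: a forward
# occurrence cuts at start + offset, the bottom-strand recognition (the
# reverse-complemented site, which for palindromes coincides with the
# forward occurrence) at start + len - offset. For blunt cutters the two
# collapse; for staggered cuts both appear, which keeps digestion strictly
# strand-symmetric - the price is that a sticky site contributes its
# (sub-visible) overhang as a short fragment.
.cut_positions <- function(seq, enz, policy = "intersect") {
  codes <- .encode_iupac(seq)
  site_codes <- .encode_iupac(enz$site)
  m <- length(site_codes)
  L <- length(codes)
  starts <- .scan_sites(codes, site_codes, 0L, policy)$start
  cuts <- (starts - 1L) + enz$cut_offset
  rc_site <- reverse_complement(enz$site)
  rc_starts <- if (identical(rc_site, toupper(enz$site))) starts else {
    .scan_sites(codes, .encode_iupac(rc_site), 0L, policy)$start
  }
  cuts <- c(cuts, (rc_starts - 1L) + (m - enz$cut_offset))
  cuts <- sort(unique(cuts))
  cuts[cuts > 0L & cuts < L]
}

#' Find restriction cut sites
#'
#' Every IUPAC-matched occurrence of the recognition site contributes the
#' nick positions of its double-strand break: `site_start + cut_offset` on
#' the forward strand and the mirrored bottom-strand position (identical for
#' blunt cutters), with reverse-strand occurrences of non-palindromic sites
#' mapped back to forward coordinates. This keeps digestion strand-symmetric:
#' a sequence and its reverse complement always give the same fragment
#' multiset. Overlapping occurrences all cut. A site spanning an ambiguous
#' subject base (e.g. an N run) counts as a cut under the default
#' intersection policy and raises a warning.
#'
#' @param seqs Tibble with columns `id`, `seq`.
#' @param enzyme An enzyme name from the built-in catalog or a one-row tibble
#'   with `enzyme`, `site`, `cut_offset`.
#' @param policy Ambiguity policy for subject bases, see [iupac_match()].
#' @return Tibble `id`, `enzyme`, `cut` where `cut` is the 1-based position
#'   of the last base before the cut (i.e. the length of the prefix fragment).
#' @export
find_cut_sites <- function(seqs, enzyme, policy = c("intersect", "subset")) {
  policy <- match.arg(policy)
  enz <- .as_enzyme_row(enzyme)
  purrr::map_dfr(seq_len(nrow(seqs)), function(i) {
    s <- validate_dna(seqs$seq[[i]], seqs$id[[i]])
    if (policy == "intersect" && grepl("[^ACGT]", s)) {
      strict <- .cut_positions(s, enz, "subset")
      loose <- .cut_positions(s, enz, "intersect")
      if (length(loose) > length(strict)) {
        warn(sprintf(
          "record '%s': %d potential %s site(s) span ambiguous bases and are counted as cuts",
          seqs$id[[i]], length(loose) - length(strict), enz$enzyme
        ))
      }
      cuts <- loose
    } else {
      cuts <- .cut_positions(s, enz, policy)
    }
    tibble::tibble(id = seqs$id[[i]], enzyme = enz$enzyme, cut = cuts)
  })
}

#' Digest linear sequences to completion
#'
#' @inheritParams find_cut_sites
#' @return A long tibble `id`, `enzyme`, `fragment` (bp), one row per
#'   fragment in positional order along the molecule. Duplicated lengths are
#'   preserved (a multiset); per record the fragments sum to the sequence
#'   length and number one more than the cuts. A zero-length sequence yields
#'   no rows.
#' @examples
#' digest_linear(tibble::tibble(id = "x", seq = "GGCCGGCC"), "HaeIII")
#' @export
digest_linear <- function(seqs, enzyme, policy = c("intersect", "subset")) {
  policy <- match.arg(policy)
  enz <- .as_enzyme_row(enzyme)
  purrr::map_dfr(seq_len(nrow(seqs)), function(i) {
    L <- nchar(seqs$seq[[i]])
    if (L == 0L) {
      return(tibble::tibble(id = character(), enzyme = character(),
                            fragment = integer()))
    }
    cc <- find_cut_sites(seqs[i, , drop = FALSE], enz, policy)$cut
    tibble::tibble(id = seqs$id[[i]], enzyme = enz$enzyme,
                   fragment = diff(c(0L, cc, L)))
  })
}
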