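# Independent oracles and small generators used across the suite. These
# deliberately avoid the package's bitmask scanner: matching goes through
# character-set expansion or regular expressions instead.

iupac_sets <- lapply(Biostrings::IUPAC_CODE_MAP, function(x) strsplit(x, "")[[1]])

# Position-by-position scan using explicit expansion sets.
naive_match_starts <- function(seq, pattern, policy = "intersect") {
  sc <- strsplit(toupper(seq), "")[[1]]
  pc <- strsplit(toupper(pattern), "")[[1]]
  n <- length(sc); m <- length(pc)
  if (m > n) return(integer())
  hits <- integer()
  for (i in seq_len(n - m + 1L)) {
    ok <- TRUE
    for (j in seq_len(m)) {
      p <- iupac_sets[[pc[[j]]]]
      s <- iupac_sets[[sc[[i + j - 1L]]]]
      match_j <- if (policy == "intersect") length(intersect(p, s)) > 0 else all(s %in% p)
      if (!match_j) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

# IUPAC site -> regex character classes; overlapping matches via lookahead.
# Valid for concrete (ACGT-only) subjects.
iupac_regex <- function(site) {
  paste(vapply(strsplit(toupper(site), "")[[1]], function(ch) {
    set <- iupac_sets[[ch]]
    if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1)), collapse = "")
}

# Both nicks of each double-strand break: top-strand cut at start + offset,
# bottom-strand cut at start + len - offset (scanning the reverse-complement
# site for the bottom strand).
regex_cut_oracle <- function(seq, site, cut_offset) {
  stopifnot(!grepl("[^ACGT]", seq))
  find <- function(pat) {
    starts <- gregexpr(paste0("(?=", iupac_regex(pat), ")"), seq, perl = TRUE)[[1]]
    starts[starts > 0L]
  }
  rc_site <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(site))
  rc_site <- paste(rev(strsplit(rc_site, "")[[1]]), collapse = "")
  cuts <- c(find(site) - 1L + cut_offset,
            find(rc_site) - 1L + (nchar(site) - cut_offset))
  sort(unique(cuts[cuts > 0L & cuts < nchar(seq)]))
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Concrete realisations of the two primers used in hand-built fixtures
# (verified against the degenerate patterns in the primer tests).
H60F_CONCRETE <- "GGAGACGGTACCACGACTGCAACCGT"
H60R_RC_CONCRETE <- "GCAGTAAAAGCACCAGGATTCGGAGA"

# A concrete amplicon with GGCC planted at the given cut positions over an
# AC-repeat background (which can host no recognition site of the built-in
# catalog: it contains neither G, T outside the planted motifs).
planted_acgg_amplicon <- function(id, cuts, len = 590L) {
  ch <- strsplit(substr(strrep("AC", ceiling(len / 2)), 1L, len), "")[[1]]
  for (p in cuts) ch[(p - 1L):(p + 2L)] <- c("G", "G", "C", "C")
  tibble::tibble(id = id, seq = paste(ch, collapse = ""))
}
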