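# Full assay in one call: amplify -> digest -> gel profile -> identify.
# Defaults reproduce the published protocol: H60F/H60R, HaeIII, 25-360 bp
# visibility window, max(2 bp, 3%) co-migration tolerance.

#' Run the complete hsp60 PCR-RFLP identification workflow
#'
#' Each input record is amplified in silico with the H60F/H60R pair, the
#' product digested, the fragments reduced to gel bands and the band set
#' identified against the reference key. Typing assumes one gel lane per
#' record: zero amplicons gives status `"no_amplicon"`, more than one gives
#' `"ambiguous_amplification"` (with a warning); both leave the
#' identification columns `NA`.
#'
#' @param fasta Path to a FASTA file, or a tibble with columns `id`, `seq`.
#' @param enzyme Enzyme name or catalog row (default `"HaeIII"`).
#' @param gel A [gel_model()].
#' @param db Reference database (default the packaged one).
#' @param key Optional prebuilt [build_key()] key (built once otherwise).
#' @param min_len,max_len,max_mismatches Amplification settings, see
#'   [extract_amplicons()].
#' @param threshold Identification confirmation threshold, see
#'   [identify_bands()].
#' @return A tibble with one row per input record: `id`, `status`
#'   (`"identified"`, `"no_match"`, `"no_amplicon"`,
#'   `"ambiguous_amplification"`), amplicon coordinates (1-based) and length,
#'   `fragments` and `bands` list-columns, `taxon` (best taxa, collapsed with
#'   " / "), `id_status`, `distance` and `decision_path` (compact
#'   "size+/size-" trace of the key walk).
#' @export
run_pipeline <- function(fasta, enzyme = "HaeIII", gel = gel_model(),
                         db = load_reference_db(), key = NULL,
                         min_len = 400L, max_len = 900L, max_mismatches = 0L,
                         threshold = 0.25) {
  seqs <- if (is.character(fasta)) read_fasta(fasta) else fasta
  if (is.null(key)) key <- build_key(db, gel)
  empty_row <- function(id, status) {
    tibble::tibble(
      id = id, status = status, amplicon_start = NA_integer_,
      amplicon_end = NA_integer_, strand = NA_character_,
      amplicon_length = NA_integer_, fragments = list(integer()),
      bands = list(numeric()), taxon = NA_character_,
      id_status = NA_character_, distance = NA_real_,
      decision_path = NA_character_
    )
  }
  purrr::map_dfr(seq_len(nrow(seqs)), function(i) {
    rec <- seqs[i, , drop = FALSE]
    amps <- extract_amplicons(rec, min_len = min_len, max_len = max_len,
                              max_mismatches = max_mismatches)
    if (nrow(amps) == 0L) return(empty_row(rec$id, "no_amplicon"))
    if (nrow(amps) > 1L) {
      warn(sprintf("record '%s': %d amplicons found; one gel lane holds one product",
                   rec$id, nrow(amps)))
      return(empty_row(rec$id, "ambiguous_amplification"))
    }
    frag <- digest_linear(tibble::tibble(id = rec$id, seq = amps$seq), enzyme)
    bands <- .band_vector(frag$fragment, gel)
    ident <- identify_bands(bands, key = key, db = db, gel = gel,
                            threshold = threshold)
    path <- paste0(ident$decision_path$band,
                   ifelse(ident$decision_path$present, "+", "-"),
                   collapse = " ")
    tibble::tibble(
      id = rec$id,
      status = if (ident$status == "no_match") "no_match" else "identified",
      amplicon_start = amps$start, amplicon_end = amps$end,
      strand = amps$strand, amplicon_length = amps$length,
      fragments = list(frag$fragment), bands = list(bands),
      taxon = paste(ident$best_taxa, collapse = " / "),
      id_status = ident$status, distance = ident$distance,
      decision_path = path
    )
  })
}

#' Re-run the validation panel against the reference key
#'
#' Each of the 39 validation strains is assigned the gel band set its RFLP
#' profile was observed to equal - its deposited taxon's reference profile,
#' except for the two documented reassignments (B1955 produced the
#' *B. adolescentis* profile, Su864 the *B. breve* profile) - and identified
#' with the key. A strain is concordant when its deposited taxon is among the
#' identified taxa (subspecies sharing a profile group count as concordant,
#' as the assay cannot separate them).
#'
#' @inheritParams run_pipeline
#' @param panel Validation panel from [load_validation_set()].
#' @return A tibble, one row per strain: `strain`, `claimed_taxon`,
#'   `profile_taxon` (whose profile the strain showed), `identified`,
#'   `id_status`, `concordant`; the concordance percentage is
#'   `100 * mean(concordant)`.
#' @export
run_validation_panel <- function(db = load_reference_db(),
                                 panel = load_validation_set(),
                                 gel = gel_model(), key = NULL) {
  if (is.null(key)) key <- build_key(db, gel)
  purrr::map_dfr(seq_len(nrow(panel)), function(i) {
    claimed <- panel$claimed_taxon[[i]]
    shown <- dplyr::coalesce(panel$reassigned_taxon[[i]], claimed)
    ref <- db[db$taxon == shown & !db$no_insilico_data, ]
    if (nrow(ref) != 1L) {
      abort(sprintf("strain %s: no reference profile for taxon '%s'",
                    panel$strain[[i]], shown))
    }
    r <- identify_bands(.band_vector(ref$fragments[[1]], gel),
                        key = key, db = db, gel = gel)
    tibble::tibble(
      strain = panel$strain[[i]], claimed_taxon = claimed,
      profile_taxon = shown,
      identified = paste(r$best_taxa, collapse = " / "),
      id_status = r$status,
      concordant = claimed %in% r$best_taxa
    )
  })
}

#' Check a user-supplied hsp60 sequence against a reference profile
#'
#' End-to-end verification helper: amplifies the supplied sequence (e.g. the
#' GenBank entry AY004272 for *B. catenulatum*, downloaded by the user),
#' digests the product and compares the visible band set with the packaged
#' profile of the stated taxon.
#'
#' @param fasta Path to a FASTA file or a tibble with `id`, `seq`
#'   (one record).
#' @param taxon Reference taxon to compare against.
#' @inheritParams run_pipeline
#' @return A list: `amplicon_length`, `fragments`, `bands`,
#'   `expected_bands`, `largest_fragment`, `matches` (logical).
#' @export
check_reference_sequence <- function(fasta, taxon, enzyme = "HaeIII",
                                     gel = gel_model(),
                                     db = load_reference_db()) {
  seqs <- if (is.character(fasta)) read_fasta(fasta) else fasta
  stopifnot(nrow(seqs) == 1L)
  ref <- db[db$taxon == taxon & !db$no_insilico_data, ]
  if (nrow(ref) != 1L) abort(sprintf("no reference profile for taxon '%s'", taxon))
  amps <- extract_amplicons(seqs)
  if (nrow(amps) != 1L) {
    abort(sprintf("expected exactly one amplicon, found %d", nrow(amps)))
  }
  frag <- digest_linear(tibble::tibble(id = seqs$id, seq = amps$seq), enzyme)
  bands <- .band_vector(frag$fragment, gel)
  expected <- .band_vector(ref$fragments[[1]], gel)
  list(
    amplicon_length = amps$length,
    fragments = sort(frag$fragment),
    bands = bands,
    expected_bands = expected,
    largest_fragment = max(frag$fragment),
    matches = !band_sets_distinguishable(bands, expected, gel)
  )
}
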