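# Packaged reference database: the predicted HaeIII fragment profiles of the
# 30 most widely distributed Bifidobacterium type strains, transcribed
# digit-for-digit from the published in-silico digestion table, plus the
# 39-strain validation panel. The TSV ships with a recorded checksum so a
# corrupted or edited copy refuses to load.

.REFERENCE_MD5 <- "405375a3d7240136b77ef52f95f64550"

.ref_path <- function() {
  system.file("extdata", "hsp60_haeIII_profiles.tsv",
              package = "bifidotyper", mustWork = TRUE)
}

#' Load the packaged hsp60/HaeIII reference database
#'
#' 30 type-strain records spanning 25 species. 29 records carry a predicted
#' fragment profile; *B. subtile* has none. The three *B. longum* subspecies
#' share one `profile_group` ("longum") and the two *B. thermacidophilum*
#' subspecies another ("thermacidophilum"): their predicted profiles are
#' identical and the assay cannot separate them. Known anomalies of the
#' source table (a collection number printed for two species, accessions
#' shared between rows) are preserved verbatim and flagged in `note`.
#'
#' @return Tibble `taxon` (species + subspecies label), `species`,
#'   `subspecies`, `collection_id`, `genbank_entry`, `fragments`
#'   (list-column of integer fragment sizes, bp), `profile_group`,
#'   `no_insilico_data`, `note`.
#' @examples
#' load_reference_db()
#' @export
load_reference_db <- function() {
  path <- .ref_path()
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, .REFERENCE_MD5)) {
    abort("reference database checksum mismatch; refusing to load a modified copy")
  }
  raw <- utils::read.delim(path, colClasses = "character")
  db <- tibble::as_tibble(raw) |>
    dplyr::mutate(
      taxon = ifelse(nzchar(.data$subspecies),
                     paste0(.data$species, " subsp. ", .data$subspecies),
                     .data$species),
      subspecies = dplyr::na_if(.data$subspecies, ""),
      genbank_entry = dplyr::na_if(.data$genbank_entry, ""),
      profile_group = dplyr::na_if(.data$profile_group, ""),
      note = dplyr::na_if(.data$note, ""),
      no_insilico_data = .data$no_insilico_data == "TRUE",
      fragments = purrr::map(.data$fragments, function(f) {
        if (!nzchar(f)) return(integer())
        as.integer(strsplit(f, "-", fixed = TRUE)[[1]])
      })
    ) |>
    dplyr::select("taxon", "species", "subspecies", "collection_id",
                  "genbank_entry", "fragments", "profile_group",
                  "no_insilico_data", "note")
  # shape invariants: fail closed rather than serve a malformed database
  sums <- vapply(db$fragments, sum, numeric(1))
  ok <- nrow(db) == 30L &&
    dplyr::n_distinct(db$species) == 25L &&
    sum(db$no_insilico_data) == 1L &&
    db$species[db$no_insilico_data] == "B. subtile" &&
    all(lengths(db$fragments[!db$no_insilico_data]) > 0L) &&
    all(sums[!db$no_insilico_data] >= 584 & sums[!db$no_insilico_data] <= 598) &&
    identical(sum(db$profile_group == "longum", na.rm = TRUE), 3L) &&
    identical(sum(db$profile_group == "thermacidophilum", na.rm = TRUE), 2L)
  if (!ok) abort("reference database failed shape validation; refusing to load")
  db
}

#' Load the validation strain panel
#'
#' 39 field isolates spanning 12 species/subspecies labels, used to confirm
#' that RFLP profiles are conserved within taxa. Two strains carry documented
#' reassignments: B1955 (deposited as *B. catenulatum*) produced the
#' *B. adolescentis* profile, and Su864 (deposited as *B. longum* subsp.
#' *suis*) the *B. breve* profile.
#'
#' @return Tibble `strain`, `claimed_taxon`, `species`, `subspecies`,
#'   `source`, `reassigned_taxon` (NA when the original call stood).
#' @export
load_validation_set <- function() {
  path <- system.file("extdata", "validation_strains.tsv",
                      package = "bifidotyper", mustWork = TRUE)
  raw <- tibble::as_tibble(utils::read.delim(path, colClasses = "character"))
  vs <- raw |>
    dplyr::mutate(
      claimed_taxon = ifelse(nzchar(.data$subspecies),
                             paste0(.data$species, " subsp. ", .data$subspecies),
                             .data$species),
      reassigned_taxon = dplyr::na_if(
        ifelse(nzchar(.data$reassigned_subspecies),
               paste0(.data$reassigned_species, " subsp. ",
                      .data$reassigned_subspecies),
               .data$reassigned_species), ""),
      subspecies = dplyr::na_if(.data$subspecies, ""),
      source = dplyr::na_if(.data$source, "")
    ) |>
    dplyr::select("strain", "claimed_taxon", "species", "subspecies",
                  "source", "reassigned_taxon")
  if (nrow(vs) != 39L || dplyr::n_distinct(vs$claimed_taxon) != 12L ||
      sum(!is.na(vs$reassigned_taxon)) != 2L) {
    abort("validation panel failed shape validation; refusing to load")
  }
  vs
}

#' Reference profiles as a long fragment table
#'
#' @param db A reference database from [load_reference_db()].
#' @return Tibble `id` (taxon label), `fragment`, ready for the gel verbs;
#'   the profile-less *B. subtile* record is dropped.
#' @export
reference_fragments <- function(db = load_reference_db()) {
  db |>
    dplyr::filter(!.data$no_insilico_data) |>
    dplyr::select(id = "taxon", "fragments") |>
    tidyr::unnest_longer("fragments", values_to = "fragment") |>
    dplyr::mutate(fragment = as.numeric(.data$fragment))
}

# Named list of band-size vectors for the profiled reference taxa.
.reference_band_sets <- function(db, gel) {
  frs <- db$fragments[!db$no_insilico_data]
  setNames(lapply(frs, .band_vector, gel = gel),
           db$taxon[!db$no_insilico_data])
}

#' Integrity report for a reference database
#'
#' @param db A reference database from [load_reference_db()].
#' @return A list with `per_taxon` (tibble: taxon, n_fragments, fragment_sum,
#'   min/max fragment), `global_min`/`global_max` fragment size over all
#'   profiles, and `duplicate_accessions` (tibble of GenBank entries shared
#'   by more than one record, e.g. AY004282). Emits a warning per duplicated
#'   accession.
#' @export
db_integrity_report <- function(db = load_reference_db()) {
  profiled <- db[!db$no_insilico_data, ]
  per_taxon <- tibble::tibble(
    taxon = profiled$taxon,
    n_fragments = lengths(profiled$fragments),
    fragment_sum = vapply(profiled$fragments, sum, numeric(1)),
    min_fragment = vapply(profiled$fragments, min, numeric(1)),
    max_fragment = vapply(profiled$fragments, max, numeric(1))
  )
  acc <- profiled$genbank_entry[!is.na(profiled$genbank_entry)]
  dup <- sort(unique(acc[duplicated(acc)]))
  dups <- dplyr::filter(profiled, .data$genbank_entry %in% dup) |>
    dplyr::select("genbank_entry", "taxon") |>
    dplyr::arrange(.data$genbank_entry, .data$taxon)
  for (a in dup) {
    warn(sprintf("accession %s appears in %d records (as printed in the source table)",
                 a, sum(acc == a)))
  }
  list(
    per_taxon = per_taxon,
    global_min = min(per_taxon$min_fragment),
    global_max = max(per_taxon$max_fragment),
    duplicate_accessions = dups
  )
}
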