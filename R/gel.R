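# Gel model: what an agarose gel actually shows of a fragment multiset.
#
# Two effects matter for reading RFLP profiles off a 3% gel: fragments below
# ~25 bp run with the primer front and fragments above ~360 bp may reflect
# incomplete digestion, so both are dropped; and fragments of near-identical
# size co-migrate into a single band, modelled as single-linkage merging
# under a max(2 bp, 3%) tolerance.

#' Gel interpretation parameters
#'
#' @param min_visible Smallest fragment scored (bp; default 25 - shorter
#'   fragments co-migrate with primers and carry no discriminatory signal).
#' @param max_reliable Largest fragment scored (bp; default 360 - longer
#'   fragments risk reflecting incomplete digestion).
#' @param comigration_rel Relative co-migration tolerance (default 0.03,
#'   i.e. 3% of the smaller of two sizes).
#' @param comigration_abs Absolute co-migration tolerance (bp; default 2).
#'   Two sizes co-migrate when they differ by at most
#'   `max(comigration_abs, comigration_rel * smaller)`.
#' @return An object of class `gel_model`.
#' @examples
#' gel_model()
#' @export
gel_model <- function(min_visible = 25, max_reliable = 360,
                      comigration_rel = 0.03, comigration_abs = 2) {
  stopifnot(min_visible < max_reliable, comigration_rel >= 0,
            comigration_abs >= 0)
  structure(
    list(min_visible = min_visible, max_reliable = max_reliable,
         comigration_rel = comigration_rel, comigration_abs = comigration_abs),
    class = "gel_model"
  )
}

#' @export
print.gel_model <- function(x, ...) {
  cat(sprintf(
    "<gel_model> visible window [%g, %g] bp; co-migration max(%g bp, %g%%)\n",
    x$min_visible, x$max_reliable, x$comigration_abs, 100 * x$comigration_rel
  ))
  invisible(x)
}

# Pairwise co-migration tolerance for sizes a and b.
.gel_tol <- function(g, a, b = a) {
  pmax(g$comigration_abs, g$comigration_rel * pmin(a, b))
}

#' Keep only gel-visible fragments
#'
#' @param fragments A long tibble with a `fragment` column (bp), e.g. from
#'   [digest_linear()], or a bare numeric vector.
#' @param gel A [gel_model()].
#' @return Same shape as the input, restricted to
#'   `min_visible <= fragment <= max_reliable`; order and multiplicity
#'   preserved. Idempotent. Set `max_reliable = Inf` in the gel model to keep
#'   large fragments.
#' @export
apply_visibility_filter <- function(fragments, gel = gel_model()) {
  if (is.numeric(fragments)) {
    return(fragments[fragments >= gel$min_visible & fragments <= gel$max_reliable])
  }
  dplyr::filter(fragments, .data$fragment >= gel$min_visible,
                .data$fragment <= gel$max_reliable)
}

# Single-linkage clustering of sorted sizes under the co-migration rule;
# returns an integer cluster index per (sorted) element.
.comigration_clusters <- function(sorted_sizes, gel) {
  if (length(sorted_sizes) == 0L) return(integer())
  gaps <- diff(sorted_sizes)
  tol <- .gel_tol(gel, head(sorted_sizes, -1L), tail(sorted_sizes, -1L))
  cumsum(c(1L, as.integer(gaps > tol)))
}

#' Merge co-migrating fragments into bands
#'
#' Adjacent sizes differing by at most the co-migration tolerance collapse
#' (single linkage) into one band whose representative size is the rounded
#' mean of the merged fragments; bands that swallowed two or more fragments
#' are flagged (a doubled fragment shows as a single, brighter band on a
#' gel - e.g. the doubled 139 bp fragment of *B. breve*).
#'
#' @param fragments A visibility-filtered long tibble with columns `id` and
#'   `fragment`, or a bare numeric vector for a single lane.
#' @param gel A [gel_model()].
#' @return Tibble `id`, `band` (bp), `n_fragments`, `comigrating` (logical),
#'   sorted by size within `id`. For vector input the `id` column is `"lane"`.
#' @export
merge_comigrating <- function(fragments, gel = gel_model()) {
  if (is.numeric(fragments)) {
    fragments <- tibble::tibble(id = "lane", fragment = fragments)
  }
  fragments |>
    dplyr::group_by(.data$id) |>
    dplyr::arrange(.data$fragment, .by_group = TRUE) |>
    dplyr::mutate(.cluster = .comigration_clusters(.data$fragment, gel)) |>
    dplyr::group_by(.data$id, .data$.cluster) |>
    dplyr::summarise(band = round(mean(.data$fragment)),
                     n_fragments = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(comigrating = .data$n_fragments >= 2L) |>
    dplyr::select(!".cluster") |>
    dplyr::arrange(.data$id, .data$band)
}

# Fragment lengths -> band-size vector for one lane.
.band_vector <- function(lengths, gel) {
  merge_comigrating(apply_visibility_filter(as.numeric(lengths), gel), gel)$band
}

# Greedy order-preserving matching of two sorted band vectors; returns the
# number of matched pairs. Two bands pair when they differ by at most the
# co-migration tolerance; on failure the smaller value is skipped.
.match_bands <- function(a, b, gel) {
  a <- sort(a); b <- sort(b)
  i <- 1L; j <- 1L; matched <- 0L
  while (i <= length(a) && j <= length(b)) {
    if (abs(a[[i]] - b[[j]]) <= .gel_tol(gel, a[[i]], b[[j]])) {
      matched <- matched + 1L; i <- i + 1L; j <- j + 1L
    } else if (a[[i]] < b[[j]]) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  matched
}

#' Can a gel tell two band sets apart?
#'
#' Two lanes are indistinguishable when greedy order-preserving matching
#' pairs every band of one with a band of the other within the co-migration
#' tolerance, and vice versa. Bands are compared as sets of representative
#' sizes (multiplicity flags ignored) by default, matching how a gel is read;
#' `strict_multiplicity = TRUE` additionally requires matched bands to agree
#' on the co-migration flag.
#'
#' @param a,b Numeric vectors of band sizes, or tibbles from
#'   [merge_comigrating()] (single lane).
#' @param gel A [gel_model()].
#' @param strict_multiplicity Compare multiplicity flags too (default FALSE).
#' @return TRUE iff the band sets are distinguishable. Symmetric; any set is
#'   indistinguishable from itself.
#' @export
band_sets_distinguishable <- function(a, b, gel = gel_model(),
                                      strict_multiplicity = FALSE) {
  av <- .as_band_tbl(a); bv <- .as_band_tbl(b)
  if (nrow(av) != nrow(bv)) return(TRUE)
  if (.match_bands(av$band, bv$band, gel) != nrow(av)) return(TRUE)
  if (strict_multiplicity &&
      !identical(av$comigrating[order(av$band)], bv$comigrating[order(bv$band)])) {
    return(TRUE)
  }
  FALSE
}

.as_band_tbl <- function(x) {
  if (is.numeric(x)) {
    return(tibble::tibble(band = sort(unique(as.numeric(x))),
                          comigrating = FALSE))
  }
  stopifnot("band" %in% names(x))
  if (!"comigrating" %in% names(x)) x$comigrating <- FALSE
  x[order(x$band), c("band", "comigrating")]
}

#' Fraction of unmatched bands between two lanes
#'
#' `1 - matched / max(|a|, |b|)` under the greedy tolerance matching of
#' [band_sets_distinguishable()]: 0 iff indistinguishable, 1 for disjoint
#' sets, symmetric. Two empty sets have distance 0.
#'
#' @inheritParams band_sets_distinguishable
#' @return A fraction in \[0, 1\].
#' @export
profile_distance <- function(a, b, gel = gel_model()) {
  av <- .as_band_tbl(a)$band
  bv <- .as_band_tbl(b)$band
  if (length(av) == 0L && length(bv) == 0L) return(0)
  1 - .match_bands(av, bv, gel) / max(length(av), length(bv))
}

#' Draw lanes of a virtual gel
#'
#' @param bands Tibble with columns `id` and `band` (bp), e.g. from
#'   [merge_comigrating()].
#' @param gel A [gel_model()] (drawn as dashed visibility limits).
#' @return A ggplot: one lane per `id`, migration distance increasing as
#'   size decreases (log scale, as on a real gel).
#' @export
plot_gel <- function(bands, gel = gel_model()) {
  stopifnot(all(c("id", "band") %in% names(bands)))
  if (!"comigrating" %in% names(bands)) bands$comigrating <- FALSE
  ggplot2::ggplot(bands, ggplot2::aes(x = .data$id, y = .data$band)) +
    ggplot2::geom_hline(yintercept = c(gel$min_visible, gel$max_reliable),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$id,
                   y = .data$band * 0.985, yend = .data$band * 1.015,
                   linewidth = .data$comigrating)
    ) +
    ggplot2::scale_linewidth_manual(values = c(`FALSE` = 4, `TRUE` = 6),
                                    guide = "none") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "size (bp)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
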