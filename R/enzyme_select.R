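# Discriminating-enzyme screening: score a candidate digestion by the
# fraction of taxon pairs whose gel band sets it can tell apart. This is the
# screen that singles out HaeIII for the hsp60 assay: under the default gel
# model it resolves every pair except the B. longum subspecies trio and the
# B. thermacidophilum subspecies pair, whose predicted profiles are identical.

#' Score how well one digestion discriminates a taxon set
#'
#' All unordered taxon pairs are compared with
#' [band_sets_distinguishable()]; the score is the resolved fraction.
#' Taxa involved in at least one unresolved pair are grouped by transitive
#' closure of indistinguishability.
#'
#' @param profiles A long tibble with columns `id` (taxon) and `fragment`
#'   (bp), e.g. [reference_fragments()] or [digest_linear()] output (its
#'   `enzyme` column, if present, names the result).
#' @param gel A [gel_model()].
#' @param enzyme Optional label for the scored enzyme; defaults to the
#'   `enzyme` column of `profiles` when present.
#' @return An object of class `enzyme_discrimination`: list with `enzyme`,
#'   `score`, `resolvable_pairs`, `total_pairs`, `unresolved_groups` (list of
#'   character vectors partitioning the taxa of unresolved pairs) and
#'   `band_sets`. Fewer than two taxa is an error.
#' @examples
#' score_enzyme(reference_fragments(), enzyme = "HaeIII")
#' @export
score_enzyme <- function(profiles, gel = gel_model(), enzyme = NULL) {
  if (is.null(enzyme)) {
    enzyme <- if ("enzyme" %in% names(profiles)) profiles$enzyme[[1]] else "profile"
  }
  ids <- unique(profiles$id)
  if (length(ids) < 2L) abort("need at least two taxa to score discrimination")
  bands <- lapply(ids, function(i) {
    .band_vector(profiles$fragment[profiles$id == i], gel)
  })
  names(bands) <- ids
  n <- length(ids)
  pairs <- utils::combn(n, 2L)
  resolved <- vapply(seq_len(ncol(pairs)), function(k) {
    band_sets_distinguishable(bands[[pairs[1L, k]]], bands[[pairs[2L, k]]], gel)
  }, logical(1))
  unresolved <- pairs[, !resolved, drop = FALSE]
  groups <- list()
  if (ncol(unresolved) > 0L) {
    gr <- igraph::graph_from_edgelist(
      cbind(ids[unresolved[1L, ]], ids[unresolved[2L, ]]), directed = FALSE
    )
    comp <- igraph::components(gr)
    groups <- unname(lapply(
      seq_len(comp$no),
      function(k) sort(names(comp$membership)[comp$membership == k])
    ))
    groups <- groups[order(vapply(groups, `[[`, character(1), 1L))]
  }
  structure(
    list(enzyme = enzyme, score = sum(resolved) / ncol(pairs),
         resolvable_pairs = sum(resolved), total_pairs = ncol(pairs),
         unresolved_groups = groups, band_sets = bands, gel = gel),
    class = "enzyme_discrimination"
  )
}

#' @export
print.enzyme_discrimination <- function(x, ...) {
  cat(sprintf("<enzyme_discrimination> %s: %d/%d pairs resolved (score %.3f)\n",
              x$enzyme, x$resolvable_pairs, x$total_pairs, x$score))
  if (length(x$unresolved_groups) > 0L) {
    cat("unresolved groups:\n")
    for (g in x$unresolved_groups) cat("  - ", paste(g, collapse = " / "), "\n", sep = "")
  }
  invisible(x)
}

#' @rdname score_enzyme
#' @param x An `enzyme_discrimination` object.
#' @param ... Unused.
#' @export
tidy.enzyme_discrimination <- function(x, ...) {
  tibble::tibble(
    taxon = names(x$band_sets),
    n_bands = lengths(x$band_sets),
    group = vapply(names(x$band_sets), function(t) {
      hit <- which(vapply(x$unresolved_groups, function(g) t %in% g, logical(1)))
      if (length(hit) == 0L) NA_character_ else paste(x$unresolved_groups[[hit]], collapse = " / ")
    }, character(1))
  )
}

#' @rdname score_enzyme
#' @export
glance.enzyme_discrimination <- function(x, ...) {
  tibble::tibble(
    enzyme = x$enzyme, score = x$score,
    resolvable_pairs = x$resolvable_pairs, total_pairs = x$total_pairs,
    n_unresolved_groups = length(x$unresolved_groups)
  )
}

#' Rank catalog enzymes by discriminatory power on a set of amplicons
#'
#' Each amplicon is digested in silico with each enzyme and the resulting
#' profiles scored with [score_enzyme()]. Results are sorted by score
#' (descending), then by the variance of visible band counts across taxa
#' (ascending: flatter profiles are easier to read), then by enzyme name, so
#' the ranking is deterministic.
#'
#' @param amplicons Tibble with columns `id` (taxon) and `seq` (amplicon
#'   DNA), at least two rows.
#' @param catalog An enzyme catalog tibble (default [bifido_enzymes()]).
#' @param gel A [gel_model()].
#' @return Tibble `enzyme`, `score`, `resolvable_pairs`, `total_pairs`,
#'   `n_unresolved_groups`, `band_count_var`, with `unresolved_groups` as a
#'   list-column.
#' @export
rank_enzymes <- function(amplicons, catalog = bifido_enzymes(),
                         gel = gel_model()) {
  stopifnot(nrow(catalog) >= 1L)
  res <- purrr::map_dfr(seq_len(nrow(catalog)), function(k) {
    enz <- catalog[k, ]
    frag <- digest_linear(amplicons, enz)
    sc <- score_enzyme(dplyr::rename(frag, fragment = "fragment"), gel,
                       enzyme = enz$enzyme)
    tibble::tibble(
      enzyme = enz$enzyme, score = sc$score,
      resolvable_pairs = sc$resolvable_pairs, total_pairs = sc$total_pairs,
      n_unresolved_groups = length(sc$unresolved_groups),
      band_count_var = ifelse(length(sc$band_sets) > 1,
                              var(lengths(sc$band_sets)), 0),
      unresolved_groups = list(sc$unresolved_groups)
    )
  })
  dplyr::arrange(res, dplyr::desc(.data$score), .data$band_count_var,
                 .data$enzyme)
}

#' @export
autoplot.enzyme_discrimination <- function(object, ...) {
  bands <- purrr::imap_dfr(object$band_sets, function(b, id) {
    tibble::tibble(id = id, band = b)
  })
  plot_gel(bands, object$gel) +
    ggplot2::ggtitle(sprintf("%s: %d/%d pairs resolved", object$enzyme,
                             object$resolvable_pairs, object$total_pairs))
}
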