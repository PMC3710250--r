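# Dichotomous key: a binary decision tree over band-presence questions
# ("is there a band at ~X bp?") whose leaves are taxa or identical-profile
# groups. The published key is a figure; here the tree is reconstructed
# algorithmically with the contract that its leaf partition reproduces the
# assay's discriminations, not the figure's exact branch order.

# Presence of a band near size `c` in a band-size vector, under the gel's
# co-migration tolerance.
.has_band <- function(bands, c, gel) {
  any(abs(bands - c) <= .gel_tol(gel, bands, c))
}

# Signed margin of the presence call: positive distance to the decision
# boundary in bp. Calls with margin < 1 bp can flip under +/-1 bp gel noise.
.presence_margin <- function(bands, c, gel) {
  d <- abs(bands - c)
  tol <- .gel_tol(gel, bands, c)
  min(abs(d - tol))
}

.all_indistinguishable <- function(bands, gel) {
  n <- length(bands)
  if (n <= 1L) return(TRUE)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (band_sets_distinguishable(bands[[i]], bands[[j]], gel)) return(FALSE)
    }
  }
  TRUE
}

# Candidate test sizes for a node: co-migration cluster representatives of
# the pooled band sizes, plus the exact sizes themselves (fallback when a
# cluster mean matches both sides of a tight pair).
.candidate_sizes <- function(bands, gel) {
  all_sizes <- sort(unique(unlist(bands)))
  cl <- .comigration_clusters(all_sizes, gel)
  reps <- vapply(split(all_sizes, cl), function(x) round(mean(x)), numeric(1))
  sort(unique(c(unname(reps), all_sizes)))
}

.build_node <- function(taxa, bands, gel) {
  if (length(taxa) == 1L || .all_indistinguishable(bands[taxa], gel)) {
    return(list(type = "leaf", taxa = sort(taxa)))
  }
  cands <- .candidate_sizes(bands[taxa], gel)
  best <- NULL
  for (c in cands) {
    has <- vapply(taxa, function(t) .has_band(bands[[t]], c, gel), logical(1))
    n_yes <- sum(has)
    if (n_yes == 0L || n_yes == length(taxa)) next
    margin <- min(vapply(taxa, function(t) .presence_margin(bands[[t]], c, gel),
                         numeric(1)))
    cand <- list(size = c, has = has, balance = abs(2L * n_yes - length(taxa)),
                 robust = margin >= 1)
    better <- is.null(best) ||
      (cand$robust && !best$robust) ||
      (cand$robust == best$robust &&
         (cand$balance < best$balance ||
            (cand$balance == best$balance && cand$size > best$size)))
    if (better) best <- cand
  }
  if (is.null(best)) {
    # no presence test separates the remaining taxa; identification falls
    # back to distance confirmation at the leaf
    return(list(type = "leaf", taxa = sort(taxa)))
  }
  list(
    type = "test", band = best$size,
    yes = .build_node(taxa[best$has], bands, gel),
    no = .build_node(taxa[!best$has], bands, gel)
  )
}

#' Build a dichotomous identification key from the reference database
#'
#' Greedy recursive construction: at each node the candidate band size whose
#' presence/absence question splits the remaining taxa most evenly is chosen
#' (ties toward the larger size), preferring questions every taxon answers
#' with at least 1 bp of margin against the co-migration tolerance so that
#' small gel-reading errors cannot flip a branch. Recursion stops when the
#' remaining taxa are mutually indistinguishable (identical-profile groups
#' stay together in one leaf). The construction is deterministic: the same
#' database and gel model always yield the same tree.
#'
#' @param db A reference database from [load_reference_db()] (taxa without a
#'   profile are excluded from the key).
#' @param gel A [gel_model()].
#' @return An object of class `dichotomous_key`.
#' @export
build_key <- function(db = load_reference_db(), gel = gel_model()) {
  bands <- .reference_band_sets(db, gel)
  if (length(bands) < 1L) abort("no profiled taxa to key")
  tree <- .build_node(sort(names(bands)), bands, gel)
  structure(
    list(tree = tree, gel = gel, band_sets = bands,
         db_md5 = unname(tools::md5sum(.ref_path())),
         version = as.character(utils::packageVersion("bifidotyper"))),
    class = "dichotomous_key"
  )
}

.key_leaves <- function(node) {
  if (node$type == "leaf") return(list(node$taxa))
  c(.key_leaves(node$yes), .key_leaves(node$no))
}

.key_depth <- function(node) {
  if (node$type == "leaf") return(0L)
  1L + max(.key_depth(node$yes), .key_depth(node$no))
}

#' @export
print.dichotomous_key <- function(x, ...) {
  leaves <- .key_leaves(x$tree)
  cat(sprintf("<dichotomous_key> %d taxa in %d leaves, depth %d\n",
              length(unlist(leaves)), length(leaves), .key_depth(x$tree)))
  invisible(x)
}

#' @rdname build_key
#' @param x A `dichotomous_key`.
#' @param ... Unused.
#' @export
tidy.dichotomous_key <- function(x, ...) {
  walk <- function(node, depth, path) {
    if (node$type == "leaf") {
      return(tibble::tibble(depth = depth, path = path, band = NA_real_,
                            leaf = paste(node$taxa, collapse = " / ")))
    }
    dplyr::bind_rows(
      tibble::tibble(depth = depth, path = path, band = node$band,
                     leaf = NA_character_),
      walk(node$yes, depth + 1L, paste0(path, "Y")),
      walk(node$no, depth + 1L, paste0(path, "N"))
    )
  }
  walk(x$tree, 0L, "")
}

#' @rdname build_key
#' @export
glance.dichotomous_key <- function(x, ...) {
  leaves <- .key_leaves(x$tree)
  tibble::tibble(
    n_taxa = length(unlist(leaves)), n_leaves = length(leaves),
    n_group_leaves = sum(lengths(leaves) > 1L), depth = .key_depth(x$tree)
  )
}

#' @export
autoplot.dichotomous_key <- function(object, ...) {
  nodes <- tidy(object)
  nodes$label <- ifelse(is.na(nodes$band), nodes$leaf,
                        sprintf("%g bp?", nodes$band))
  nodes$x <- vapply(nodes$path, function(p) {
    if (!nzchar(p)) return(0.5)
    bits <- strsplit(p, "")[[1]] == "Y"
    sum(ifelse(bits, 1, 0) * 0.5^seq_along(bits)) + 0.5^(length(bits) + 1)
  }, numeric(1))
  ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = -.data$depth)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 2.5) +
    ggplot2::theme_void()
}

#' Serialize / restore a dichotomous key (JSON)
#'
#' The JSON carries the tree, the gel-model parameters, the package version
#' and the reference-database checksum; serialization is byte-stable so keys
#' can be diffed and version-controlled.
#'
#' @param key A `dichotomous_key`.
#' @param path Output (input) file path.
#' @return `write_key()` returns `path` invisibly; `read_key()` a
#'   `dichotomous_key`.
#' @export
write_key <- function(key, path) {
  payload <- list(
    version = key$version, db_md5 = key$db_md5,
    gel = unclass(key$gel), band_sets = key$band_sets, tree = key$tree
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_key
#' @export
read_key <- function(path) {
  p <- jsonlite::fromJSON(readLines(path), simplifyVector = TRUE,
                          simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  fix <- function(node) {
    if (identical(node$type, "leaf")) {
      return(list(type = "leaf", taxa = unlist(node$taxa)))
    }
    list(type = "test", band = node$band, yes = fix(node$yes), no = fix(node$no))
  }
  structure(
    list(tree = fix(p$tree),
         gel = do.call(gel_model, p$gel),
         band_sets = lapply(p$band_sets, unlist),
         db_md5 = p$db_md5, version = p$version),
    class = "dichotomous_key"
  )
}

#' Identify an isolate from its observed gel bands
#'
#' Walks the key answering each band-presence question from the observed
#' band sizes, then confirms the leaf by [profile_distance()] against every
#' leaf member; the nearest-neighbour match over the whole database is
#' reported alongside as a safeguard against unknown species funnelling into
#' a wrong leaf (a key alone cannot reject).
#'
#' @param observed Numeric vector of observed band sizes (bp), non-empty.
#' @param key A `dichotomous_key` from [build_key()]; built on the fly from
#'   `db` and `gel` when `NULL`.
#' @param db The reference database the key was built from.
#' @param gel A [gel_model()].
#' @param threshold Maximum confirmation distance (default 0.25); above it
#'   the status is `"no_match"`.
#' @return An object of class `rflp_identification`: `best_taxa` (character),
#'   `status` (`"unambiguous"`, `"group"` or `"no_match"`), `distance`,
#'   `decision_path` (tibble `band`, `present`), `candidates` (per leaf
#'   member), `nearest` (full-database nearest neighbours). `tidy()` returns
#'   the full-database distance table.
#' @examples
#' identify_bands(c(53, 198, 338))
#' @export
identify_bands <- function(observed, key = NULL, db = load_reference_db(),
                           gel = gel_model(), threshold = 0.25) {
  observed <- sort(unique(as.numeric(observed)))
  if (length(observed) == 0L) abort("observed band set is empty")
  # sizes closer than the gel can resolve are one band, whatever the input says
  observed <- merge_comigrating(observed, gel)$band
  if (is.null(key)) key <- build_key(db, gel)
  node <- key$tree
  path <- list()
  while (node$type == "test") {
    present <- .has_band(observed, node$band, gel)
    path[[length(path) + 1L]] <- tibble::tibble(band = node$band,
                                                present = present)
    node <- if (present) node$yes else node$no
  }
  leaf <- node$taxa
  all_dist <- tibble::tibble(
    taxon = names(key$band_sets),
    distance = vapply(key$band_sets, profile_distance, numeric(1),
                      b = observed, gel = gel)
  ) |> dplyr::arrange(.data$distance, .data$taxon)
  candidates <- dplyr::filter(all_dist, .data$taxon %in% leaf)
  best_d <- min(candidates$distance)
  best <- sort(candidates$taxon[candidates$distance == best_d])
  status <- if (best_d > threshold) "no_match"
            else if (length(best) == 1L) "unambiguous"
            else "group"
  structure(
    list(
      best_taxa = best, status = status, distance = best_d,
      decision_path = if (length(path)) dplyr::bind_rows(path)
                      else tibble::tibble(band = numeric(), present = logical()),
      leaf_taxa = leaf, candidates = candidates,
      nearest = utils::head(all_dist, 5L), observed = observed,
      threshold = threshold, all_distances = all_dist
    ),
    class = "rflp_identification"
  )
}

#' @export
print.rflp_identification <- function(x, ...) {
  cat(sprintf("<rflp_identification> bands: %s\n",
              paste(x$observed, collapse = ", ")))
  cat(sprintf("  %s: %s (distance %.3f)\n", x$status,
              paste(x$best_taxa, collapse = " / "), x$distance))
  if (x$status == "no_match") {
    cat(sprintf("  nearest reference: %s (distance %.3f)\n",
                x$nearest$taxon[[1]], x$nearest$distance[[1]]))
  }
  invisible(x)
}

#' @rdname identify_bands
#' @param x An `rflp_identification`.
#' @param ... Unused.
#' @export
tidy.rflp_identification <- function(x, ...) {
  x$all_distances
}

#' @rdname identify_bands
#' @export
glance.rflp_identification <- function(x, ...) {
  tibble::tibble(
    status = x$status, best = paste(x$best_taxa, collapse = " / "),
    distance = x$distance, n_bands = length(x$observed),
    n_tests = nrow(x$decision_path)
  )
}

#' Read observed gel bands from a text file
#'
#' Accepts either one integer band size per line (a single unnamed lane) or
#' TSV lines `lane_id<TAB>size,size,...`.
#'
#' @param path Input file.
#' @return Tibble `id`, `band`.
#' @export
read_bands <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), value = TRUE, invert = TRUE)
  if (length(lines) == 0L) return(tibble::tibble(id = character(), band = numeric()))
  if (any(grepl("\t", lines, fixed = TRUE))) {
    purrr::map_dfr(lines, function(l) {
      parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
      if (length(parts) != 2L) abort(sprintf("malformed band line: '%s'", l))
      tibble::tibble(id = parts[[1]],
                     band = as.numeric(strsplit(parts[[2]], ",")[[1]]))
    })
  } else {
    tibble::tibble(id = "lane", band = as.numeric(lines))
  }
}
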