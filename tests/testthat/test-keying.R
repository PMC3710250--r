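# Dichotomous key construction and band-based identification.

ref_key <- build_key()
ref_db <- load_reference_db()
ref_gel <- gel_model()
ref_bands <- bifidotyper:::.reference_band_sets(ref_db, ref_gel)

test_that("the key partitions the 29 profiled taxa into 26 leaves", {
  gl <- glance(ref_key)
  expect_equal(gl$n_taxa, 29L)
  expect_equal(gl$n_leaves, 26L)
  expect_equal(gl$n_group_leaves, 2L)
  leaves <- bifidotyper:::.key_leaves(ref_key$tree)
  sizes <- sort(lengths(leaves))
  expect_equal(sizes, c(rep(1L, 24L), 2L, 3L))
  # each profiled taxon sits in exactly one leaf; profile groups share theirs
  expect_setequal(unlist(leaves), names(ref_bands))
  grouped <- leaves[lengths(leaves) > 1L]
  expect_setequal(
    vapply(grouped, paste, character(1), collapse = "|"),
    c(paste(sort(ref_db$taxon[which(ref_db$profile_group == "longum")]), collapse = "|"),
      paste(sort(ref_db$taxon[which(ref_db$profile_group == "thermacidophilum")]), collapse = "|"))
  )
})

test_that("toy databases build the obvious keys", {
  toy <- tibble::tibble(
    taxon = c("a", "b"), species = c("a", "b"), subspecies = NA_character_,
    collection_id = "", genbank_entry = NA_character_,
    fragments = list(100L, 200L), profile_group = NA_character_,
    no_insilico_data = FALSE, note = NA_character_
  )
  k <- build_key(toy, ref_gel)
  expect_equal(k$tree$type, "test")
  expect_equal(k$tree$yes$type, "leaf")
  expect_equal(k$tree$no$type, "leaf")
  expect_equal(glance(k)$n_leaves, 2L)

  one <- build_key(toy[1, ], ref_gel)
  expect_equal(one$tree$type, "leaf")

  # all-indistinguishable taxa give a single-leaf key
  twin <- toy
  twin$fragments <- list(100L, 101L)
  expect_equal(glance(build_key(twin, ref_gel))$n_leaves, 1L)
})

test_that("every reference profile routes back to itself at distance zero", {
  for (t in names(ref_bands)) {
    r <- identify_bands(ref_bands[[t]], key = ref_key, db = ref_db, gel = ref_gel)
    expect_true(t %in% r$best_taxa, info = t)
    expect_equal(r$distance, 0, info = t)
    grp <- ref_db$profile_group[ref_db$taxon == t]
    if (!is.na(grp)) {
      expect_equal(r$status, "group", info = t)
      expect_setequal(r$best_taxa,
                      ref_db$taxon[which(ref_db$profile_group == grp)])
    } else {
      expect_equal(r$status, "unambiguous", info = t)
    }
    # key walk and flat nearest-neighbour search agree
    expect_equal(min(r$all_distances$distance), 0, info = t)
    nn_best <- r$all_distances$taxon[r$all_distances$distance == 0]
    expect_setequal(r$best_taxa, nn_best)
  }
})

test_that("identification survives 1 bp of gel-reading noise on every band", {
  for (d in c(-1, 1)) {
    for (t in names(ref_bands)) {
      r <- identify_bands(ref_bands[[t]] + d, key = ref_key, db = ref_db,
                          gel = ref_gel)
      expect_true(t %in% r$best_taxa, info = sprintf("%s (%+d bp)", t, d))
      expect_true(r$status != "no_match", info = sprintf("%s (%+d bp)", t, d))
    }
  }
})

test_that("published example band sets identify as published", {
  cat_id <- identify_bands(c(53, 198, 338), key = ref_key)
  expect_equal(cat_id$status, "unambiguous")
  expect_equal(cat_id$best_taxa, "B. catenulatum")

  longum <- identify_bands(c(42, 113, 138, 139, 158), key = ref_key)
  expect_equal(longum$status, "group")
  expect_setequal(longum$best_taxa,
                  c("B. longum subsp. longum", "B. longum subsp. infantis",
                    "B. longum subsp. suis"))

  # strain B1955's bands equal the B. adolescentis profile
  b1955 <- identify_bands(c(31, 36, 81, 103, 339), key = ref_key)
  expect_equal(b1955$status, "unambiguous")
  expect_equal(b1955$best_taxa, "B. adolescentis")
})

test_that("band sets far from every reference are rejected", {
  r <- identify_bands(c(26, 350), key = ref_key)
  expect_equal(r$status, "no_match")
  expect_gt(r$distance, 0.25)
  expect_error(identify_bands(numeric(), key = ref_key), "empty")
})

test_that("key serialization is byte-stable and survives a round-trip", {
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_key(ref_key, f1)
  write_key(build_key(ref_db, ref_gel), f2)
  expect_identical(readLines(f1), readLines(f2))

  back <- read_key(f1)
  expect_equal(glance(back), glance(ref_key))
  for (t in c("B. catenulatum", "B. breve", "B. dentium")) {
    a <- identify_bands(ref_bands[[t]], key = back)
    expect_true(t %in% a$best_taxa)
  }
})

test_that("tidy, glance and plots expose the tree structure", {
  td <- tidy(ref_key)
  expect_equal(sum(!is.na(td$leaf)), 26L)
  expect_equal(sum(!is.na(td$band)), 25L)  # binary tree: leaves - 1 tests
  expect_s3_class(autoplot(ref_key), "ggplot")
  gl <- glance(identify_bands(c(53, 198, 338), key = ref_key))
  expect_equal(gl$status, "unambiguous")
})

test_that("observed band files parse in both accepted layouts", {
  f <- withr::local_tempfile()
  writeLines(c("53", "198", "338"), f)
  b <- read_bands(f)
  expect_equal(b$band, c(53, 198, 338))
  f2 <- withr::local_tempfile()
  writeLines(c("lane1\t53,198,338", "lane2\t42,113,138,158"), f2)
  b2 <- read_bands(f2)
  expect_equal(dplyr::n_distinct(b2$id), 2L)
  expect_equal(b2$band[b2$id == "lane2"], c(42, 113, 138, 158))
})
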