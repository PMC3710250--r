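# Discriminating-enzyme scoring and ranking.

test_that("HaeIII on the reference profiles leaves exactly two merged groups", {
  sc <- score_enzyme(reference_fragments(), enzyme = "HaeIII")
  expect_equal(sc$total_pairs, choose(29, 2))
  expect_equal(length(sc$unresolved_groups), 2L)
  expect_equal(
    sc$unresolved_groups[[1]],
    c("B. longum subsp. infantis", "B. longum subsp. longum",
      "B. longum subsp. suis")
  )
  expect_equal(
    sc$unresolved_groups[[2]],
    c("B. thermacidophilum subsp. porcinum",
      "B. thermacidophilum subsp. thermacidophilum")
  )
  # 3 longum pairs + 1 thermacidophilum pair unresolved
  expect_equal(sc$resolvable_pairs, choose(29, 2) - 4L)
  # oracle: exhaustive pairwise comparison of the packaged band sets
  g <- gel_model()
  bands <- lapply(split(reference_fragments()$fragment, reference_fragments()$id),
                  function(f) merge_comigrating(apply_visibility_filter(f, g), g)$band)
  unresolved <- 0L
  for (i in seq_along(bands)) for (j in seq_len(i - 1L)) {
    if (!band_sets_distinguishable(bands[[i]], bands[[j]], g)) unresolved <- unresolved + 1L
  }
  expect_equal(sc$total_pairs - sc$resolvable_pairs, unresolved)
})

test_that("degenerate discrimination cases score 0 and 1", {
  g <- gel_model()
  same <- tibble::tibble(id = c("a", "a", "b", "b"), fragment = c(100, 200, 100, 200))
  sc0 <- score_enzyme(same, g)
  expect_equal(sc0$score, 0)
  expect_equal(sc0$unresolved_groups, list(c("a", "b")))
  two <- tibble::tibble(id = c("a", "b"), fragment = c(100, 200))
  expect_equal(score_enzyme(two, g)$score, 1)
  expect_error(score_enzyme(tibble::tibble(id = "a", fragment = 100), g),
               "at least two")
})

test_that("the score ignores taxon labels and input order", {
  g <- gel_model()
  p <- tibble::tibble(id = rep(c("x", "y", "z"), each = 2),
                      fragment = c(50, 100, 50, 200, 100, 300))
  a <- score_enzyme(p, g)
  shuffled <- p[sample(nrow(p)), ]
  shuffled$id <- chartr("xyz", "qrs", shuffled$id)
  b <- score_enzyme(shuffled, g)
  expect_equal(a$score, b$score)
  expect_equal(a$resolvable_pairs, b$resolvable_pairs)
})

test_that("an indistinguishable newcomer can only lower the score", {
  g <- gel_model()
  base <- score_enzyme(tibble::tibble(id = c("a", "b"), fragment = c(100, 200)), g)
  extended <- score_enzyme(
    tibble::tibble(id = c("a", "b", "c"), fragment = c(100, 200, 201)), g
  )
  expect_lt(extended$score, base$score)
  expect_equal(extended$unresolved_groups, list(c("b", "c")))
})

test_that("enzyme ranking is deterministic and puts the resolving enzyme first", {
  amps <- dplyr::bind_rows(
    planted_acgg_amplicon("A", c(150L, 350L)),
    planted_acgg_amplicon("B", c(100L, 300L)),
    planted_acgg_amplicon("C", 250L)
  )
  rk <- rank_enzymes(amps)
  expect_equal(nrow(rk), 7L)
  expect_equal(rk$enzyme[[1]], "HaeIII")
  expect_equal(rk$score[[1]], 1)
  # no other catalog enzyme can cut an AC-repeat background: all profiles
  # collapse to one >360 bp fragment, filtered invisible, hence score 0
  expect_true(all(rk$score[-1] == 0))
  expect_equal(rk$enzyme[-1], sort(rk$enzyme[-1]))
  rk2 <- rank_enzymes(amps)
  expect_identical(rk, rk2)

  single <- rank_enzymes(amps, bifido_enzymes("HaeIII"))
  expect_equal(nrow(single), 1L)

  # duplicate-site enzymes under different names score identically
  dup <- dplyr::bind_rows(
    bifido_enzymes("HaeIII"),
    tibble::tibble(enzyme = "HaeIIIbis", site = "GGCC", cut_offset = 2L,
                   overhang = "blunt")
  )
  rkd <- rank_enzymes(amps, dup)
  expect_equal(rkd$score[[1]], rkd$score[[2]])
})

test_that("tidy and glance summarise a discrimination result", {
  sc <- score_enzyme(reference_fragments(), enzyme = "HaeIII")
  td <- tidy(sc)
  expect_equal(nrow(td), 29L)
  expect_equal(sum(!is.na(td$group)), 5L)
  gl <- glance(sc)
  expect_equal(gl$n_unresolved_groups, 2L)
  expect_equal(gl$score, sc$score)
  expect_s3_class(autoplot(sc), "ggplot")
})
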