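# Enzyme catalog parsing and complete linear digestion.

test_that("caret-notation catalog lines parse to sites and offsets", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "HaeIII\tGG^CC", "", "Sau3AI\t^GATC"), f)
  cat <- read_enzyme_catalog(f)
  expect_equal(cat$enzyme, c("HaeIII", "Sau3AI"))
  expect_equal(cat$site, c("GGCC", "GATC"))
  expect_equal(cat$cut_offset, c(2L, 0L))
  expect_equal(cat$overhang, c("blunt", "sticky"))
})

test_that("malformed catalog lines are rejected with line numbers", {
  bad1 <- withr::local_tempfile(); writeLines("Bad\tGGCC", bad1)
  expect_error(read_enzyme_catalog(bad1), "no cut position")
  bad2 <- withr::local_tempfile(); writeLines("Bad\tG^G^CC", bad2)
  expect_error(read_enzyme_catalog(bad2), "more than one cut")
  bad3 <- withr::local_tempfile(); writeLines("Bad\tGG^CU", bad3)
  expect_error(read_enzyme_catalog(bad3), "invalid IUPAC")
  bad4 <- withr::local_tempfile()
  writeLines(c("A\tGG^CC", "A\tGT^AC"), bad4)
  expect_error(read_enzyme_catalog(bad4), "duplicate")
})

test_that("the built-in catalog carries the screened enzymes", {
  cat <- bifido_enzymes()
  expect_setequal(cat$enzyme,
                  c("HaeIII", "RsaI", "AluI", "AccII", "Sau3AI", "AatII", "PvuI"))
  hae <- bifido_enzymes("HaeIII")
  expect_equal(hae$site, "GGCC")
  expect_equal(hae$cut_offset, 2L)
  expect_equal(hae$overhang, "blunt")
})

test_that("cut sites and fragments match hand-worked examples", {
  expect_equal(find_cut_sites(tibble::tibble(id = "x", seq = "AAGGCCTT"), "HaeIII")$cut, 4L)
  expect_equal(find_cut_sites(tibble::tibble(id = "x", seq = "GGCCGGCC"), "HaeIII")$cut, c(2L, 6L))
  expect_equal(nrow(find_cut_sites(tibble::tibble(id = "x", seq = "ACGTACGT"), "HaeIII")), 0L)

  expect_equal(digest_linear(tibble::tibble(id = "x", seq = "AAGGCCTT"), "HaeIII")$fragment, c(4L, 4L))
  expect_equal(digest_linear(tibble::tibble(id = "x", seq = "GGCCGGCC"), "HaeIII")$fragment, c(2L, 4L, 2L))
  no_site <- digest_linear(tibble::tibble(id = "x", seq = random_dna(590, c("A", "T"))), "HaeIII")
  expect_equal(no_site$fragment, 590L)
  empty <- digest_linear(tibble::tibble(id = "x", seq = ""), "HaeIII")
  expect_equal(nrow(empty), 0L)
})

test_that("overlapping site occurrences all cut", {
  # AluI AG^CT on AGCTAGCT... and a self-overlapping CGCG run for AccII
  expect_equal(find_cut_sites(tibble::tibble(id = "x", seq = "CGCGCG"), "AccII")$cut,
               c(2L, 4L))
})

test_that("non-palindromic sites cut on both strands", {
  enz <- tibble::tibble(enzyme = "Toy", site = "GGTCTC", cut_offset = 1L)
  # forward occurrence (0-based start 2): cut at 2 + 1 = 3; the
  # reverse-strand occurrence reads GAGACC (0-based start 10) and its cut
  # maps to 10 + (6 - 1) = 15
  s <- tibble::tibble(id = "x", seq = "AAGGTCTCAAGAGACCAA")
  cuts <- find_cut_sites(s, enz)$cut
  expect_equal(cuts, c(3L, 15L))
  expect_equal(cuts, regex_cut_oracle(s$seq, "GGTCTC", 1L))
})

test_that("staggered palindromic cuts report both strand nicks", {
  # Sau3AI ^GATC: top-strand nick before the site, bottom-strand nick after
  # it; the 4 bp in between is the single-stranded overhang
  cuts <- find_cut_sites(tibble::tibble(id = "x", seq = "AAAGATCAAA"), "Sau3AI")$cut
  expect_equal(cuts, c(3L, 7L))
  # blunt symmetric cutters still nick once per site
  expect_equal(find_cut_sites(tibble::tibble(id = "x", seq = "AAGGCCTT"), "HaeIII")$cut, 4L)
})

test_that("sites spanning ambiguous bases cut with a warning by default", {
  s <- tibble::tibble(id = "amb", seq = "AAAGGNCAAA")
  expect_warning(cuts <- find_cut_sites(s, "HaeIII"), "ambiguous")
  expect_equal(cuts$cut, 5L)
  strict <- find_cut_sites(s, "HaeIII", policy = "subset")
  expect_equal(nrow(strict), 0L)
})

test_that("digestion conserves length and fragment counts on random inputs", {
  set.seed(31)
  catalog <- bifido_enzymes()
  for (i in 1:40) {
    s <- random_dna(sample(50:800, 1))
    tbl <- tibble::tibble(id = "r", seq = s)
    enz <- catalog[sample(nrow(catalog), 1), ]
    cuts <- find_cut_sites(tbl, enz)
    frag <- digest_linear(tbl, enz)
    expect_equal(sum(frag$fragment), nchar(s))
    expect_equal(nrow(frag), nrow(cuts) + 1L)
    # palindromic recognition: same fragment multiset on the other strand
    rc <- tibble::tibble(id = "r", seq = reverse_complement(s))
    expect_equal(sort(digest_linear(rc, enz)$fragment), sort(frag$fragment))
  }
})

test_that("cut finding agrees with an independent regex oracle", {
  set.seed(41)
  catalog <- bifido_enzymes()
  for (i in 1:25) {
    s <- random_dna(sample(100:1000, 1))
    for (k in seq_len(nrow(catalog))) {
      enz <- catalog[k, ]
      expect_equal(
        find_cut_sites(tibble::tibble(id = "r", seq = s), enz)$cut,
        regex_cut_oracle(s, enz$site, enz$cut_offset),
        info = enz$enzyme
      )
    }
  }
})
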