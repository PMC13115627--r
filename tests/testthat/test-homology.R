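test_that("flank extraction slices the expected circular windows", {
  ref <- toy_reference(L = 100L, seed = 13L)
  chars <- strsplit(ref$sequence, "")[[1L]]

  fl <- extract_flanks(ref, b5 = 50, b3 = 80, w = 20)
  expect_equal(fl$flank5, paste(chars[30:69], collapse = ""))
  expect_equal(fl$flank3, paste(chars[60:99], collapse = ""))

  wrap <- extract_flanks(ref, b5 = 5, b3 = 98, w = 20)
  expect_equal(nchar(wrap$flank5), 40L)
  expect_equal(wrap$flank5, paste(chars[c(85:100, 1:24)], collapse = ""))
  expect_equal(wrap$flank3, paste(chars[c(78:100, 1:17)], collapse = ""))

  tiny <- extract_flanks(ref, b5 = 50, b3 = 80, w = 1)
  expect_equal(nchar(tiny$flank5), 2L)
  expect_equal(tiny$flank5, paste(chars[49:50], collapse = ""))
})

test_that("junction-anchored microhomology: caps, zeros, planted repeats", {
  w <- 20L
  f <- strrep("ACGT", 10)
  expect_equal(microhomology_length(f, f, w), 2L * w)

  a <- paste0(strrep("A", 20), strrep("C", 20))
  b <- paste0(strrep("G", 20), strrep("T", 20))
  expect_equal(microhomology_length(a, b, w), 0L)

  # plant a 5-base run straddling nothing else: equal bases only at 21..25
  base5 <- paste0(strrep("A", 20), "GGGGG", strrep("A", 15))
  base3 <- paste0(strrep("C", 20), "GGGGG", strrep("C", 15))
  expect_equal(microhomology_length(base5, base3, w), 5L)

  # backward + forward runs add up across the junction
  bk5 <- paste0(strrep("A", 17), "TTT", "GG", strrep("A", 18))
  bk3 <- paste0(strrep("C", 17), "TTT", "GG", strrep("C", 18))
  expect_equal(microhomology_length(bk5, bk3, w), 5L)

  expect_error(microhomology_length("ACGT", "AC", 2), "lengths differ")
  expect_error(microhomology_length("ACGT", "ACGT", 20), "2w bases")
})

test_that("anchored rule agrees with the brute-force run oracle", {
  set.seed(410)
  for (i in 1:300) {
    fl <- random_flanks(w = 20L)
    expect_equal(
      microhomology_length(fl$f5, fl$f3, 20L),
      oracle_mh(fl$f5, fl$f3, 20L)
    )
  }
  # symmetry under exchanging the flanks
  for (i in 1:50) {
    fl <- random_flanks(w = 20L)
    expect_equal(microhomology_length(fl$f5, fl$f3, 20L),
                 microhomology_length(fl$f3, fl$f5, 20L))
  }
})

test_that("substring method finds unanchored matches and bounds anchored", {
  # an 8-mer shared away from the junction
  f5 <- paste0("AAAAACGTACGTA", strrep("T", 27))
  f3 <- paste0(strrep("G", 27), "ACGTACGTA", "GGGG")
  expect_gte(microhomology_length(f5, f3, 20, method = "substring"), 8L)
  set.seed(411)
  for (i in 1:50) {
    fl <- random_flanks(w = 20L)
    expect_gte(microhomology_length(fl$f5, fl$f3, 20, method = "substring"),
               microhomology_length(fl$f5, fl$f3, 20))
  }
})

test_that("microhomology is invariant under genome rotation", {
  ref <- toy_reference(L = 200L, seed = 14L)
  b5 <- 60L
  b3 <- 140L
  mh <- function(r, x5, x3) {
    fl <- extract_flanks(r, x5, x3, w = 10)
    microhomology_length(fl$flank5, fl$flank3, w = 10)
  }
  baseline <- mh(ref, b5, b3)
  for (shift in c(37L, 111L, 180L)) {
    rotated <- mito_reference(
      paste0(substr(ref$sequence, shift + 1, 200), substr(ref$sequence, 1, shift)),
      regions = ref$regions
    )
    wrap1 <- function(p) ((p - shift - 1L) %% 200L) + 1L
    expect_equal(mh(rotated, wrap1(b5), wrap1(b3)), baseline)
  }
})

test_that("D-loop exclusion and scoring integrate over a deletion set", {
  ref <- simulate_reference(16569, seed = 15)
  dels <- tibble::tibble(
    b5 = c(8470L, 16100L, 6000L),
    b3 = c(13447L, 300L, 9000L)
  )
  scored <- score_microhomology(ref, dels)
  expect_equal(nrow(scored), 2L)   # the D-loop junction is dropped
  expect_true(all(scored$mh_len >= 0 & scored$mh_len <= 40))
  kept_all <- score_microhomology(ref, dels, exclude_dloop = FALSE)
  expect_equal(nrow(kept_all), 3L)
})

test_that("homology summaries count fractions and histograms", {
  scored <- tibble::tibble(
    b5 = 1:4, b3 = 11:14,
    mh_len = c(0L, 0L, 2L, 3L)
  )
  s <- homology_summary(scored)
  expect_equal(s$fraction$pct_mh, 50)
  expect_equal(s$fraction$n, 4L)
  hist <- tibble::deframe(dplyr::select(s$histogram, mh_len, n))
  expect_equal(hist[["0"]], 2L)
  expect_equal(hist[["2"]], 1L)
  expect_equal(hist[["3"]], 1L)

  all_mh <- homology_summary(dplyr::mutate(scored, mh_len = c(1L, 2L, 2L, 9L)))
  expect_equal(all_mh$fraction$pct_mh, 100)

  # the same deletions through a "catalogue" source give identical histograms
  both <- dplyr::bind_rows(
    dplyr::mutate(scored, source = "sample"),
    dplyr::mutate(scored, source = "MITOMAP")
  )
  s2 <- homology_summary(both)
  by_src <- split(s2$histogram$n, s2$histogram$source)
  expect_equal(by_src$sample, by_src$MITOMAP)

  empty <- homology_summary(scored[0, ])
  expect_equal(nrow(empty$fraction), 0L)
})

test_that("catalogue loading validates coordinates", {
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(b5 = c(8470, 6000, 20000, NA),
                                  b3 = c(13447, 9000, 100, 500)), path)
  expect_warning(cat1 <- load_catalogue(path, source = "MITOMAP"), "rejected")
  expect_equal(nrow(cat1), 2L)
  expect_equal(cat1$source, rep("MITOMAP", 2))

  shifted <- load_catalogue(path, source = "custom", shift = 1L) |>
    suppressWarnings()
  expect_equal(shifted$b5[1], 8471L)

  bad <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(b5 = 99999, b3 = 88888), bad)
  expect_error(suppressWarnings(load_catalogue(bad)), "no usable rows")

  wrongcols <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(x = 1, y = 2), wrongcols)
  expect_error(load_catalogue(wrongcols), "lacks columns")
})
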