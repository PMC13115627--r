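test_that("simulated references are deterministic, scaled and balanced", {
  a <- simulate_reference(16569, seed = 7)
  b <- simulate_reference(16569, seed = 7)
  expect_identical(a$sequence, b$sequence)
  expect_false(identical(a$sequence, simulate_reference(16569, seed = 8)$sequence))

  small <- simulate_reference(2000, seed = 1)
  expect_equal(small$length, 2000L)
  expect_true(all(small$regions$end <= 2000L))

  gc <- sum(strsplit(a$sequence, "")[[1L]] %in% c("G", "C")) / 16569
  expect_gt(gc, 0.4)
  expect_lt(gc, 0.6)
  expect_error(simulate_reference(100), "at least 200")
})

test_that("planted microhomology measures exactly k at the junction", {
  for (k in c(1L, 3L, 5L, 12L)) {
    ref <- plant_microhomology(simulate_reference(4000, seed = 20 + k),
                               b5 = 1500L, b3 = 2600L, k = k)
    fl <- extract_flanks(ref, 1500L, 2600L, w = 20)
    expect_equal(microhomology_length(fl$flank5, fl$flank3, 20L), k)
    expect_equal(oracle_mh(fl$flank5, fl$flank3, 20L), k)
  }
  ref <- simulate_reference(4000, seed = 33)
  expect_identical(plant_microhomology(ref, 1500L, 2600L, 0L)$sequence,
                   ref$sequence)
  expect_error(plant_microhomology(ref, 1500L, 2600L, 21L), "at most")

  # two junctions each measure their own k
  ref2 <- simulate_reference(8000, seed = 34) |>
    plant_microhomology(1000L, 2500L, 4L) |>
    plant_microhomology(4000L, 6500L, 9L)
  f1 <- extract_flanks(ref2, 1000L, 2500L, 20)
  f2 <- extract_flanks(ref2, 4000L, 6500L, 20)
  expect_equal(microhomology_length(f1$flank5, f1$flank3, 20L), 4L)
  expect_equal(microhomology_length(f2$flank5, f2$flank3, 20L), 9L)
})

test_that("simulated samples are deterministic and SAM-consistent", {
  ref <- simulate_reference(16569, seed = 7)
  cfg <- sim_config(
    deletions = tibble::tibble(b5 = 8470L, b3 = 13447L, fraction = 0.3),
    mean_coverage = 60, seed = 99
  )
  sim <- simulate_sample(ref, cfg)
  sim2 <- simulate_sample(ref, cfg)
  expect_identical(sim$reads, sim2$reads)

  s1 <- tempfile(fileext = ".sam")
  s2 <- tempfile(fileext = ".sam")
  write_sam(sim$reads, ref, s1)
  write_sam(sim2$reads, ref, s2)
  expect_identical(readLines(s1), readLines(s2))

  # CIGAR query widths match emitted sequences, records stay on the circle
  qw <- GenomicAlignments::cigarWidthAlongQuerySpace(sim$reads$cigar,
                                                     after.soft.clipping = TRUE)
  expect_equal(qw, nchar(sim$reads$seq))
  ends <- sim$reads$ref_start +
    GenomicAlignments::cigarWidthAlongReferenceSpace(sim$reads$cigar) - 1L
  expect_true(all(sim$reads$ref_start >= 1L & ends <= 16569L))

  # round trip through an on-disk SAM preserves the alignments
  back <- read_mito_alignments(s1, contig = "chrM")
  expect_equal(nrow(back), nrow(sim$reads))
  expect_setequal(back$read_id, sim$reads$read_id)
})

test_that("deletion-negative configurations emit no qualifying deletions", {
  ref <- simulate_reference(16569, seed = 7)
  sim <- simulate_sample(ref, sim_config(mean_coverage = 40, seed = 12))
  ev <- collect_sample_deletions(sim$reads)
  expect_equal(nrow(ev), 0L)
  expect_true(all(sim$truth$molecule == "intact"))
  expect_false(any(sim$truth$spans_junction))
})

test_that("planted breakpoints are recovered exactly from error-free reads", {
  ref <- simulate_reference(16569, seed = 7)
  dels <- tibble::tibble(b5 = c(6456L, 10000L), b3 = c(11399L, 15200L),
                         fraction = c(0.2, 0.15))
  sim <- simulate_sample(ref, sim_config(deletions = dels, mean_coverage = 120,
                                         seed = 3))
  ev <- collect_sample_deletions(sim$reads)
  expect_setequal(unique(ev$b5), dels$b5)
  expect_setequal(unique(ev$b3), dels$b3)
  # every deletion read in the events table truly spans a junction
  truth <- sim$truth[match(unique(ev$read_id), sim$truth$read_id), ]
  expect_true(all(truth$spans_junction))
  # and every junction-spanning read is recovered
  expect_equal(sort(unique(ev$read_id)),
               sort(sim$truth$read_id[sim$truth$spans_junction]))
})

test_that("substitutions perturb sequences but never alignments", {
  ref <- simulate_reference(16569, seed = 7)
  base <- sim_config(deletions = tibble::tibble(b5 = 8470L, b3 = 13447L,
                                                fraction = 0.3),
                     mean_coverage = 30, seed = 5)
  noisy <- base
  noisy$substitution_rate <- 0.02
  s0 <- simulate_sample(ref, base)
  s1 <- simulate_sample(ref, noisy)
  expect_identical(s0$reads$cigar, s1$reads$cigar)
  expect_identical(s0$reads$ref_start, s1$reads$ref_start)
  expect_false(identical(s0$reads$seq, s1$reads$seq))
  expect_equal(nchar(s0$reads$seq), nchar(s1$reads$seq))
})

test_that("molecule-level truth matches configured heteroplasmy", {
  ref <- simulate_reference(16569, seed = 7)
  cfg <- sim_config(deletions = tibble::tibble(b5 = 8470L, b3 = 13447L,
                                               fraction = 0.4),
                    mean_coverage = 250, seed = 8)
  sim <- simulate_sample(ref, cfg)
  expect_equal(sim$truth_summary$expected_heteroplasmy_pct, 40)
  # read-level molecule mix: fragment sampling is length-weighted, so the
  # deletion-read share sits near f*Md / (f*Md + (1-f)*L)
  md <- 16569 - 4977
  expected_share <- 0.4 * md / (0.4 * md + 0.6 * 16569)
  got <- mean(sim$truth$molecule != "intact")
  n <- nrow(sim$truth)
  expect_lt(abs(got - expected_share),
            3 * sqrt(expected_share * (1 - expected_share) / n))
})

test_that("linear-only placement emits single-record reads", {
  ref <- simulate_reference(16569, seed = 7)
  cfg <- sim_config(deletions = tibble::tibble(b5 = 8470L, b3 = 13447L,
                                               fraction = 0.3),
                    mean_coverage = 30, seed = 6, linear_only = TRUE)
  sim <- simulate_sample(ref, cfg)
  expect_true(all(sim$truth$n_records == 1L))
  expect_false(any(sim$reads$is_supplementary))
})
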