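round2 <- function(x) round(x + 1e-9, 2)

#' Long-read deletion heteroplasmy
#'
#' Heteroplasmy is the percentage of sequenced mtDNA molecules that carry a
#' large-scale deletion: the number of deletion-bearing reads divided by the
#' mean coverage of the MT-RNR2 gene, which stands in for the total number
#' of molecules sequenced (mirroring the ddPCR reference probe in that
#' gene), times 100.
#'
#' @param n_del Count of deletion-bearing reads (vectorised).
#' @param rnr2_cov Mean MT-RNR2 coverage; must be positive.
#' @param digits Decimal places for the reported value (default 2; use
#'   `NULL` for full precision).
#' @return Heteroplasmy percentage(s).
#' @examples
#' lrs_heteroplasmy(372, 582.03) # 63.91
#' @export
lrs_heteroplasmy <- function(n_del, rnr2_cov, digits = 2) {
  if (any(rnr2_cov <= 0)) {
    stop("MT-RNR2 coverage must be positive")
  }
  if (any(n_del < 0)) {
    stop("deletion-read count cannot be negative")
  }
  pct <- 100 * n_del / rnr2_cov
  if (any(pct > 100)) {
    warning("heteroplasmy above 100%: more deletion reads than MT-RNR2 depth")
  }
  if (is.null(digits)) pct else round(pct + 1e-9, digits)
}

#' ddPCR deletion heteroplasmy
#'
#' Two-probe droplet digital PCR estimate: `[1 - ND4/RNR2] x 100%`, where
#' the MT-ND4 probe counts non-deleted molecules (the gene sits inside the
#' commonly deleted arc) and MT-RNR2 counts all molecules.
#'
#' @param nd4_count,rnr2_count Droplet-derived molecule counts.
#' @return Percentage; small negative values (probe noise) are clamped to 0
#'   with a warning.
#' @export
ddpcr_heteroplasmy <- function(nd4_count, rnr2_count) {
  if (any(rnr2_count <= 0)) {
    stop("RNR2 count must be positive")
  }
  if (any(nd4_count < 0)) {
    stop("ND4 count cannot be negative")
  }
  pct <- (1 - nd4_count / rnr2_count) * 100
  if (any(pct < 0)) {
    warning("negative ddPCR heteroplasmy clamped to 0")
    pct <- pmax(pct, 0)
  }
  pct
}

#' Coverage-downsampling precision experiment
#'
#' Randomly subsamples reads without replacement at each fraction, reruns
#' deletion calling and heteroplasmy quantification, and records the mean
#' genome coverage and estimate per replicate. The default grid is 5% to
#' 100% of total coverage in 5% increments with 5 sub-replicates, the design
#' used to ask how much depth heteroplasmy quantification needs.
#'
#' Subsampling operates on read ids, so split alignments of one molecule are
#' kept or dropped together.
#'
#' @param reads Alignment tibble for one sample.
#' @param ref [mito_reference()] (supplies length and MT-RNR2).
#' @param fractions Numeric vector in (0, 1].
#' @param n_reps Replicates per fraction.
#' @param seed Integer seed; the full table is reproducible given it.
#' @param ... Passed to [collect_sample_deletions()].
#' @return Tibble `fraction`, `rep`, `n_reads`, `mean_cov`, `heteroplasmy`
#'   (NA when a draw holds no reads).
#' @export
downsample_series <- function(reads, ref, fractions = seq(0.05, 1, by = 0.05),
                              n_reps = 5L, seed = 1L, ...) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  ids <- unique(reads$read_id)
  grid <- tidyr::expand_grid(fraction = fractions, rep = seq_len(n_reps))
  withr::with_seed(seed, {
    purrr::pmap(grid, function(fraction, rep) {
      take <- sample(ids, size = round(fraction * length(ids)))
      sub <- dplyr::filter(reads, .data$read_id %in% take)
      if (nrow(sub) == 0L) {
        return(tibble::tibble(fraction = fraction, rep = rep, n_reads = 0L,
                              mean_cov = 0, heteroplasmy = NA_real_))
      }
      prof <- depth_profile(sub, ref$length)
      ev <- collect_sample_deletions(sub, L = ref$length, ...)
      rnr2 <- mean_region_coverage(prof, "MT-RNR2", ref)
      h <- if (rnr2 > 0) {
        lrs_heteroplasmy(n_deletion_reads(ev), rnr2, digits = NULL)
      } else {
        NA_real_
      }
      tibble::tibble(fraction = fraction, rep = rep,
                     n_reads = length(take),
                     mean_cov = mean(prof$depth), heteroplasmy = h)
    }) |> dplyr::bind_rows()
  })
}

#' Per-fraction spread of downsampled heteroplasmy
#'
#' @param series Output of [downsample_series()].
#' @return Tibble `fraction`, `mean_cov`, `mean_h`, `sd_h` (sample SD over
#'   replicates).
#' @export
downsample_summary <- function(series) {
  series |>
    dplyr::group_by(.data$fraction) |>
    dplyr::summarise(
      mean_cov = mean(.data$mean_cov),
      mean_h = mean(.data$heteroplasmy, na.rm = TRUE),
      sd_h = stats::sd(.data$heteroplasmy, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Pearson correlation between LRS and ddPCR heteroplasmy
#'
#' @param pairs Tibble with columns `lrs_pct` and `ddpcr_pct`.
#' @return Product-moment correlation coefficient.
#' @export
pearson_r <- function(pairs) {
  stopifnot(nrow(pairs) >= 2L)
  if (stats::sd(pairs$lrs_pct) == 0 || stats::sd(pairs$ddpcr_pct) == 0) {
    stop("correlation undefined: zero variance in one method")
  }
  stats::cor(pairs$lrs_pct, pairs$ddpcr_pct, method = "pearson")
}

#' Bland-Altman agreement between LRS and ddPCR
#'
#' Differences are `lrs - ddpcr`; the bias is their mean and the limits of
#' agreement are bias +/- 1.96 times the sample standard deviation (n-1
#' divisor) of the differences.
#'
#' @param pairs Tibble with columns `lrs_pct`, `ddpcr_pct` and optionally
#'   `sample_id`.
#' @return Object of class `bland_altman` with elements `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n` and the per-sample `data`.
#' @examples
#' pairs <- tibble::tibble(lrs_pct = c(63.91, 33.43, 25.25, 31.03),
#'                         ddpcr_pct = c(73, 45, 40, 34))
#' bland_altman(pairs)
#' @export
bland_altman <- function(pairs) {
  if (nrow(pairs) < 2L) {
    stop("Bland-Altman needs at least two pairs")
  }
  d <- pairs$lrs_pct - pairs$ddpcr_pct
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  structure(
    list(
      bias = bias, sd_diff = sd_diff,
      loa_low = bias - 1.96 * sd_diff, loa_high = bias + 1.96 * sd_diff,
      n = nrow(pairs),
      data = dplyr::mutate(
        tibble::as_tibble(pairs),
        mean_pct = (lrs_pct + ddpcr_pct) / 2, diff_pct = d
      )
    ),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman agreement (n = %d)\n  bias %.2f%%  SD of differences %.2f\n  limits of agreement [%.2f%%, %.2f%%]\n",
    x$n, x$bias, x$sd_diff, x$loa_low, x$loa_high
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-sample Bland-Altman differences
#'
#' @param x A [bland_altman()] object.
#' @param ... Unused.
#' @return Tibble of pairs with `mean_pct` and `diff_pct` columns.
#' @exportS3Method generics::tidy
tidy.bland_altman <- function(x, ...) {
  x$data
}

#' One-row Bland-Altman summary
#'
#' @param x A [bland_altman()] object.
#' @param ... Unused.
#' @return Tibble with `bias`, `sd_diff`, `loa_low`, `loa_high`, `n`.
#' @exportS3Method generics::glance
glance.bland_altman <- function(x, ...) {
  tibble::tibble(bias = x$bias, sd_diff = x$sd_diff,
                 loa_low = x$loa_low, loa_high = x$loa_high, n = x$n)
}

#' True-negative count under the fixed-denominator convention
#'
#' Benchmarks against a truth call set treat every untouched reference
#' position as a negative: `tn = L - total_called`, with `total_called` the
#' size of the truth (short-read) call set.
#'
#' @param tp,fp,fn Non-negative counts.
#' @param total_called Truth-set call count.
#' @param L Reference length (default 16,569).
#' @return Tibble with columns `tp`, `fp`, `fn`, `tn`, `total_called`.
#' @export
benchmark_counts <- function(tp, fp, fn, total_called, L = 16569L) {
  counts <- tibble::tibble(tp = tp, fp = fp, fn = fn,
                           total_called = total_called)
  if (any(unlist(counts) < 0)) {
    stop("counts must be non-negative")
  }
  dplyr::mutate(counts, tn = L - .data$total_called,
                .before = "total_called")
}

#' Sensitivity, specificity, precision and recall from benchmark counts
#'
#' Percentages at two decimals; any 0/0 ratio is reported as 0.00 (the
#' convention used when a class has no true or called events at all).
#'
#' @param counts Tibble with columns `tp`, `fp`, `fn`, `tn` (see
#'   [benchmark_counts()]); extra columns are carried through.
#' @return Input with `sensitivity`, `specificity`, `precision`, `recall`
#'   columns appended.
#' @export
benchmark_metrics <- function(counts) {
  if (any(unlist(counts[c("tp", "fp", "fn", "tn")]) < 0)) {
    stop("counts must be non-negative")
  }
  ratio <- function(num, den) ifelse(den == 0, 0, 100 * num / den)
  dplyr::mutate(
    tibble::as_tibble(counts),
    sensitivity = round2(ratio(tp, tp + fn)),
    specificity = round2(ratio(tn, tn + fp)),
    precision = round2(ratio(tp, tp + fp)),
    recall = .data$sensitivity
  )
}
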