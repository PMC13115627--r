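#' End-to-end deletion detection for one sample
#'
#' Runs the full workflow on a set of mitochondrial alignments: per-base
#' depth, CIGAR and split-read deletion extraction within the size window,
#' wrap-aware DBSCAN clustering of breakpoints, sample classification, and
#' heteroplasmy quantification against mean MT-RNR2 coverage.
#'
#' @param reads Alignment tibble from [read_mito_alignments()] (or a path to
#'   a SAM/BAM file, read with defaults).
#' @param ref A [mito_reference()].
#' @param sample_id Sample label.
#' @param min_len,max_len Deletion size window (default 500-15,000 bp).
#' @param eps,min_pts DBSCAN parameters (default 50 bp, 2 reads).
#' @param min_support Support needed to trust a lone cluster.
#' @param ... Further arguments to [collect_sample_deletions()].
#' @return Object of class `mito_call`: list with `sample_id`,
#'   `classification`, `heteroplasmy_pct`, `n_deletion_reads`, `rnr2_cov`,
#'   `mean_cov`, `events`, `clusters`, `profile`.
#' @export
mito_detect <- function(reads, ref, sample_id = "sample",
                        min_len = 500L, max_len = 15000L,
                        eps = 50, min_pts = 2L, min_support = 2L, ...) {
  if (is.character(reads)) {
    reads <- read_mito_alignments(reads, contig = ref$name)
  }
  profile <- depth_profile(reads, ref$length)
  events <- collect_sample_deletions(reads, sample_id = sample_id,
                                     min_len = min_len, max_len = max_len,
                                     L = ref$length, ...)
  clusters <- cluster_deletions(events, eps = eps, min_pts = min_pts,
                                L = ref$length)
  classification <- classify_sample(clusters, min_support = min_support)
  rnr2 <- mean_region_coverage(profile, "MT-RNR2", ref)
  n_del <- n_deletion_reads(events)
  h <- if (rnr2 > 0) lrs_heteroplasmy(n_del, rnr2) else NA_real_
  if (nrow(reads) == 0L) {
    warning("no mitochondrial alignments for ", sample_id,
            "; reporting Negative")
  }
  structure(
    list(
      sample_id = sample_id, classification = classification,
      heteroplasmy_pct = h, n_deletion_reads = n_del,
      rnr2_cov = rnr2, mean_cov = mean(profile$depth),
      events = events, clusters = clusters, profile = profile,
      params = list(min_len = min_len, max_len = max_len, eps = eps,
                    min_pts = min_pts, min_support = min_support)
    ),
    class = "mito_call"
  )
}

#' @export
print.mito_call <- function(x, ...) {
  cat(sprintf(
    "<mito_call> %s: %s\n  mean coverage %.1fx | MT-RNR2 coverage %.2fx\n  %d deletion read(s) in %d cluster(s) | heteroplasmy %.2f%%\n",
    x$sample_id, x$classification, x$mean_cov, x$rnr2_cov,
    x$n_deletion_reads, nrow(x$clusters), x$heteroplasmy_pct
  ))
  invisible(x)
}

#' Cluster-level detail of a detection result
#'
#' @param x A `mito_call` from [mito_detect()].
#' @param ... Unused.
#' @return Cluster tibble with deletion names and per-cluster heteroplasmy
#'   (cluster support over MT-RNR2 coverage).
#' @exportS3Method generics::tidy
tidy.mito_call <- function(x, ...) {
  if (nrow(x$clusters) == 0L) {
    return(dplyr::select(x$clusters, -"members"))
  }
  L <- nrow(x$profile)
  x$clusters |>
    dplyr::select(-"members") |>
    dplyr::mutate(
      name = format_deletion_name(.data$rep_b5, .data$rep_b3, L),
      heteroplasmy_pct = lrs_heteroplasmy(.data$support, x$rnr2_cov)
    )
}

#' One-row summary of a detection result
#'
#' Mirrors the per-sample reporting columns: mean coverage, deletion read
#' count, MT-RNR2 coverage, heteroplasmy and classification.
#'
#' @param x A `mito_call`.
#' @param ... Unused.
#' @return One-row tibble.
#' @exportS3Method generics::glance
glance.mito_call <- function(x, ...) {
  tibble::tibble(
    sample_id = x$sample_id,
    mean_cov = x$mean_cov,
    n_deletion_reads = x$n_deletion_reads,
    rnr2_cov = x$rnr2_cov,
    heteroplasmy_pct = x$heteroplasmy_pct,
    n_clusters = nrow(x$clusters),
    classification = x$classification
  )
}
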