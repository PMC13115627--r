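circ_axis_dist <- function(a, b, L) {
  d <- abs(a - b)
  pmin(d, L - d)
}

#' DBSCAN over breakpoint pairs on the torus
#'
#' Classic DBSCAN (core points have at least `min_pts` neighbours within
#' `eps`, counting themselves; clusters are maximal density-connected sets;
#' the rest is noise) with Euclidean distance in the `(b5, b3)` plane where
#' each axis wraps at the genome length, so junctions straddling the origin
#' co-cluster with their neighbours.
#'
#' @param points Tibble or data frame with columns `b5`, `b3`.
#' @param eps Neighbourhood radius in bp (default 50, generous against HiFi
#'   breakpoint jitter).
#' @param min_pts Minimum neighbourhood size for a core point (default 2, so
#'   any two co-located deletion reads form a cluster).
#' @param L Genome length for the circular metric.
#' @return Integer label per point; 0 marks noise.
#' @export
dbscan_2d <- function(points, eps = 50, min_pts = 2L, L = 16569L) {
  stopifnot(eps > 0, min_pts >= 1L)
  n <- nrow(points)
  if (n == 0L) {
    return(integer())
  }
  dx <- outer(points$b5, points$b5, circ_axis_dist, L = L)
  dy <- outer(points$b3, points$b3, circ_axis_dist, L = L)
  adj <- dx * dx + dy * dy <= eps * eps
  core <- rowSums(adj) >= min_pts
  labels <- integer(n)
  cluster_id <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cluster_id <- cluster_id + 1L
    queue <- i
    labels[i] <- cluster_id
    while (length(queue) > 0L) {
      p <- queue[[1L]]
      queue <- queue[-1L]
      if (!core[p]) next
      nb <- which(adj[p, ] & labels == 0L)
      labels[nb] <- cluster_id
      queue <- c(queue, nb[core[nb]])
    }
  }
  labels
}

#' Cluster deletion events into recurrent junctions
#'
#' Runs [dbscan_2d()] on the event breakpoints; noise points are kept as
#' singleton clusters because single-molecule deletions still count towards
#' a multiple-deletion call. Representative breakpoints are per-coordinate
#' medians of the members.
#'
#' @param events Event tibble from [collect_sample_deletions()].
#' @param eps,min_pts,L See [dbscan_2d()].
#' @return Tibble `cluster_id`, `rep_b5`, `rep_b3`, `del_len`, `support`,
#'   `recurrent`, plus list-column `members` of member row indices into
#'   `events`.
#' @export
cluster_deletions <- function(events, eps = 50, min_pts = 2L, L = 16569L) {
  if (nrow(events) == 0L) {
    return(tibble::tibble(
      cluster_id = integer(), rep_b5 = integer(), rep_b3 = integer(),
      del_len = integer(), support = integer(), recurrent = logical(),
      members = list()
    ))
  }
  labels <- dbscan_2d(events, eps = eps, min_pts = min_pts, L = L)
  noise <- labels == 0L
  labels[noise] <- max(labels) + seq_len(sum(noise))
  circ_median <- function(x) {
    # members lie within eps of each other; unwrap around the first value
    ref <- x[[1L]]
    shifted <- ((x - ref + L / 2) %% L) - L / 2
    as.integer(round(ref + stats::median(shifted))) %% L
  }
  tibble::tibble(idx = seq_len(nrow(events)), label = labels,
                 b5 = events$b5, b3 = events$b3) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      rep_b5 = (circ_median(.data$b5) - 1L) %% L + 1L,
      rep_b3 = (circ_median(.data$b3) - 1L) %% L + 1L,
      support = dplyr::n(),
      members = list(.data$idx),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$support), .data$rep_b5) |>
    dplyr::mutate(
      cluster_id = dplyr::row_number(),
      del_len = circular_gap(.data$rep_b5, .data$rep_b3, L),
      recurrent = .data$support > 1L
    ) |>
    dplyr::select("cluster_id", "rep_b5", "rep_b3", "del_len",
                  "support", "recurrent", "members")
}

#' Classify a sample as SLSMD, MMD, Negative or LowEvidence
#'
#' A sample with no qualifying deletion events is `Negative`. If all events
#' fall in a single recurrent cluster the sample carries a single
#' large-scale deletion (`SLSMD`); two or more clusters — recurrent or not —
#' mean multiple deletions (`MMD`), since even single-molecule junctions
#' count as distinct deletion species. A lone singleton cluster is
#' `LowEvidence` when `min_support > 1`.
#'
#' @param clusters Cluster tibble from [cluster_deletions()].
#' @param min_support Reads required to trust a lone cluster (default 2).
#' @return One of `"SLSMD"`, `"MMD"`, `"Negative"`, `"LowEvidence"`.
#' @export
classify_sample <- function(clusters, min_support = 2L) {
  if (nrow(clusters) == 0L) {
    return("Negative")
  }
  if (nrow(clusters) >= 2L) {
    return("MMD")
  }
  if (clusters$recurrent[[1L]] || min_support <= 1L) "SLSMD" else "LowEvidence"
}

#' Write the cluster table and a circos-arc export
#'
#' @param clusters Cluster tibble.
#' @param path Output TSV; an `.arcs.tsv` sibling with `start`, `end`,
#'   `weight` columns (junction arcs weighted by read support) is written
#'   alongside.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  readr::write_tsv(
    dplyr::select(clusters, -"members"), path
  )
  arcs <- tibble::tibble(
    start = clusters$rep_b5, end = clusters$rep_b3, weight = clusters$support
  )
  readr::write_tsv(arcs, sub("\\.tsv$", ".arcs.tsv", path))
  invisible(path)
}
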