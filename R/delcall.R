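#' Deletion events from CIGAR deletion operations
#'
#' Scans each alignment record for `D` operations whose length falls inside
#' the size window (inclusive at both bounds) and emits one event per
#' qualifying gap: `b5` is the reference position of the first deleted base,
#' `b3 = b5 + length` the first retained base after the gap.
#'
#' @param reads Alignment tibble (see [read_mito_alignments()]).
#' @param min_len,max_len Inclusive deletion size window in bp; defaults
#'   500 and 15,000, the large-scale deletion range.
#' @param merge_gap Merge consecutive `D` operations separated by at most
#'   this many aligned bases before size-filtering (alignment wobble around a
#'   junction). Default 0 (no merging); the merged deleted length includes
#'   the short retained spacer.
#' @return Event tibble: `read_id`, `b5`, `b3`, `del_len`, `evidence`.
#' @export
deletions_from_cigar <- function(reads, min_len = 500L, max_len = 15000L,
                                 merge_gap = 0L) {
  if (nrow(reads) == 0L) {
    return(empty_events())
  }
  rg <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    reads$cigar, pos = reads$ref_start, ops = "D"
  )
  if (merge_gap > 0L) {
    rg <- IRanges::reduce(rg, min.gapwidth = merge_gap + 1L)
  }
  n <- S4Vectors::elementNROWS(rg)
  flat <- unlist(rg)
  ev <- tibble::tibble(
    read_id = rep(reads$read_id, n),
    b5 = IRanges::start(flat),
    b3 = IRanges::start(flat) + IRanges::width(flat),
    del_len = IRanges::width(flat),
    evidence = "cigar"
  )
  dplyr::filter(ev, .data$del_len >= min_len, .data$del_len <= max_len)
}

empty_events <- function() {
  tibble::tibble(
    read_id = character(), b5 = integer(), b3 = integer(),
    del_len = integer(), evidence = character()
  )
}

segment_query_bounds <- function(segments) {
  cig <- segments$cigar
  lead <- vapply(cig, function(x) {
    m <- regmatches(x, regexec("^(\\d+)[SH]", x))[[1L]]
    if (length(m)) as.integer(m[[2L]]) else 0L
  }, integer(1), USE.NAMES = FALSE)
  trail <- vapply(cig, function(x) {
    m <- regmatches(x, regexec("(\\d+)[SH]$", x))[[1L]]
    if (length(m)) as.integer(m[[2L]]) else 0L
  }, integer(1), USE.NAMES = FALSE)
  qw <- GenomicAlignments::cigarWidthAlongQuerySpace(
    cig, after.soft.clipping = TRUE
  )
  minus <- segments$strand == "-"
  qstart <- ifelse(minus, trail, lead) + 1L
  tibble::tibble(
    qstart = as.integer(qstart),
    qend = as.integer(qstart + qw - 1L),
    ref_start = segments$ref_start,
    ref_end = segments$ref_start + ref_consumed(cig) - 1L,
    strand = segments$strand
  )
}

#' Deletion events from split (supplementary) alignments
#'
#' Pairs alignment segments of one read that are adjacent in read
#' coordinates and separated on the reference by a gap inside the size
#' window. The gap is measured on the circle, so junctions of
#' origin-spanning deletions are recovered; contiguous origin-split segments
#' (gap 0) produce no event.
#'
#' @param segments Alignment tibble holding all records of a single read
#'   (primary + supplementary) on the mito contig.
#' @param min_len,max_len Inclusive size window in bp.
#' @param max_read_gap Maximum unaligned read bases tolerated between paired
#'   segments (default 50).
#' @param L Reference length.
#' @return Event tibble (`evidence == "split"`); empty for single segments
#'   or mixed-strand reads (skipped with a warning).
#' @export
deletions_from_split <- function(segments, min_len = 500L, max_len = 15000L,
                                 max_read_gap = 50L, L = 16569L) {
  if (nrow(segments) < 2L) {
    return(empty_events())
  }
  if (dplyr::n_distinct(segments$strand) > 1L) {
    warning("read ", segments$read_id[[1L]],
            ": segments on both strands; skipped")
    return(empty_events())
  }
  qb <- segment_query_bounds(segments)
  ord <- order(qb$qstart)
  qb <- qb[ord, ]
  out <- vector("list", nrow(qb) - 1L)
  for (i in seq_len(nrow(qb) - 1L)) {
    gap_q <- qb$qstart[i + 1L] - qb$qend[i] - 1L
    if (abs(gap_q) > max_read_gap) next
    if (qb$strand[[1L]] == "+") {
      b5 <- (qb$ref_end[i] %% L) + 1L
      b3 <- qb$ref_start[i + 1L]
    } else {
      b5 <- (qb$ref_end[i + 1L] %% L) + 1L
      b3 <- qb$ref_start[i]
    }
    if (b5 == b3) next # contiguous across the origin, no deleted bases
    g <- circular_gap(b5, b3, L)
    if (g >= min_len && g <= max_len) {
      out[[i]] <- tibble::tibble(
        read_id = segments$read_id[[1L]], b5 = b5, b3 = as.integer(b3),
        del_len = g, evidence = "split"
      )
    }
  }
  out <- purrr::compact(out)
  if (length(out) == 0L) empty_events() else dplyr::bind_rows(out)
}

#' Collect all qualifying deletion events for one sample
#'
#' Union of CIGAR and split-read events over all reads, deduplicated within
#' each read on identical `(b5, b3)` (a junction seen both as a `D` op and as
#' a split pair counts once per molecule). The attached attributes record the
#' sample id, size window, and the number of distinct deletion-bearing reads
#' — the heteroplasmy numerator, which counts molecules rather than events.
#'
#' @param reads Alignment tibble for one sample.
#' @param sample_id Sample label stored on the result.
#' @param min_len,max_len,merge_gap,max_read_gap See
#'   [deletions_from_cigar()] and [deletions_from_split()].
#' @param L Reference length.
#' @return Event tibble with attributes `sample_id`, `size_window`,
#'   `n_deletion_reads`.
#' @export
collect_sample_deletions <- function(reads, sample_id = "sample",
                                     min_len = 500L, max_len = 15000L,
                                     merge_gap = 0L, max_read_gap = 50L,
                                     L = 16569L) {
  cig <- deletions_from_cigar(reads, min_len, max_len, merge_gap)
  multi <- dplyr::filter(
    dplyr::add_count(reads, .data$read_id), .data$n > 1L
  )
  spl <- if (nrow(multi) > 0L) {
    multi |>
      dplyr::group_by(.data$read_id) |>
      dplyr::group_map(~ deletions_from_split(
        dplyr::mutate(.x, read_id = .y$read_id),
        min_len, max_len, max_read_gap, L
      )) |>
      dplyr::bind_rows()
  } else {
    empty_events()
  }
  ev <- dplyr::bind_rows(cig, spl) |>
    dplyr::arrange(.data$read_id, .data$b5, .data$b3, .data$evidence) |>
    dplyr::distinct(.data$read_id, .data$b5, .data$b3, .keep_all = TRUE)
  attr(ev, "sample_id") <- sample_id
  attr(ev, "size_window") <- c(min_len, max_len)
  attr(ev, "n_deletion_reads") <- dplyr::n_distinct(ev$read_id)
  ev
}

#' Number of distinct deletion-bearing reads
#'
#' @param events Event tibble.
#' @return Integer count of distinct `read_id`s.
#' @export
n_deletion_reads <- function(events) {
  dplyr::n_distinct(events$read_id)
}

#' Write deletion events as TSV and BEDPE
#'
#' @param events Event tibble from [collect_sample_deletions()].
#' @param path Output TSV path; a `.bedpe` sibling is written alongside
#'   (0-based half-open, one record per junction) when `bedpe = TRUE`.
#' @param contig Contig name for BEDPE.
#' @param L Reference length (for deletion names in the BEDPE name column).
#' @param bedpe Also write BEDPE? Default TRUE.
#' @return `path`, invisibly.
#' @export
write_deletion_events <- function(events, path, contig = "chrM", L = 16569L,
                                  bedpe = TRUE) {
  sample_id <- attr(events, "sample_id") %||% "sample"
  out <- dplyr::mutate(events, sample = sample_id, .before = 1L)
  readr::write_tsv(out, path)
  if (bedpe) {
    bp <- tibble::tibble(
      chrom1 = contig, start1 = events$b5 - 1L, end1 = events$b5,
      chrom2 = contig, start2 = events$b3 - 1L, end2 = events$b3,
      name = format_deletion_name(events$b5, events$b3, L = L),
      score = ".", strand1 = "+", strand2 = "+"
    )
    readr::write_tsv(bp, sub("\\.tsv$", ".bedpe", path), col_names = FALSE)
  }
  invisible(path)
}
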