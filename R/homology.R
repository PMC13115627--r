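#' Extract junction flanks for microhomology scoring
#'
#' For each breakpoint, the `2w` bases centred on it are extracted with
#' circular wrap: positions `[b - w, b + w - 1]`, so the first `w` bases are
#' retained (or deleted-side) context and the base at offset `w + 1` is the
#' breakpoint base itself.
#'
#' @param ref A [mito_reference()].
#' @param b5,b3 Breakpoint vectors (first deleted base / first retained
#'   base).
#' @param w Half-window in bp; default 20, giving 40-base flanks.
#' @return Tibble with columns `b5`, `b3`, `flank5`, `flank3`.
#' @export
extract_flanks <- function(ref, b5, b3, w = 20L) {
  stopifnot(length(b5) == length(b3))
  f <- function(b) {
    vapply(b, function(p) circular_substr(ref, p - w, 2L * w), character(1))
  }
  tibble::tibble(b5 = as.integer(b5), b3 = as.integer(b3),
                 flank5 = f(b5), flank3 = f(b3))
}

#' Microhomology length between two junction flanks
#'
#' The default rule is junction-anchored: count the run of position-wise
#' identical bases extending forward from the breakpoint base (offset
#' `w + 1`) plus the run extending backward from offset `w`, capped at the
#' window size `2w`. This is the repeat shared by the deleted-side and
#' retained-side junctions that deletion-formation models care about.
#' `method = "substring"` instead reports the longest common substring of
#' the two flanks at any offset (a looser reading that inflates lengths on
#' random sequence).
#'
#' @param flank5,flank3 Equal-length flank strings (vectorised).
#' @param w Half-window used to build the flanks.
#' @param method `"anchored"` (default) or `"substring"`.
#' @return Integer microhomology length(s), between 0 and `2w`.
#' @export
microhomology_length <- function(flank5, flank3, w = 20L,
                                 method = c("anchored", "substring")) {
  method <- match.arg(method)
  if (any(nchar(flank5) != nchar(flank3))) {
    stop("flank lengths differ")
  }
  if (any(nchar(flank5) != 2L * w)) {
    stop("flanks must be 2w bases long")
  }
  purrr::map2_int(flank5, flank3, function(a, b) {
    x <- strsplit(a, "", fixed = TRUE)[[1L]]
    y <- strsplit(b, "", fixed = TRUE)[[1L]]
    if (method == "substring") {
      return(longest_common_substring(x, y))
    }
    m <- x == y
    fwd <- 0L
    for (i in (w + 1L):(2L * w)) {
      if (!m[i]) break
      fwd <- fwd + 1L
    }
    bwd <- 0L
    for (i in w:1L) {
      if (!m[i]) break
      bwd <- bwd + 1L
    }
    min(fwd + bwd, 2L * w)
  })
}

longest_common_substring <- function(x, y) {
  best <- 0L
  n <- length(x)
  m <- length(y)
  prev <- integer(m)
  for (i in seq_len(n)) {
    cur <- integer(m)
    match_j <- which(y == x[i])
    for (j in match_j) {
      cur[j] <- if (j == 1L) 1L else prev[j - 1L] + 1L
      if (cur[j] > best) best <- cur[j]
    }
    prev <- cur
  }
  best
}

#' Score microhomology for a set of deletions
#'
#' Excludes deletions with a breakend in the D-loop (where the circular
#' control region confounds junction context), extracts flanks and scores
#' each junction.
#'
#' @param ref A [mito_reference()].
#' @param deletions Tibble with columns `b5`, `b3` (e.g. cluster
#'   representatives via `rep_b5`/`rep_b3`, renamed).
#' @param w Half-window (default 20).
#' @param method Match rule, see [microhomology_length()].
#' @param exclude_dloop Drop D-loop breakends? Default TRUE.
#' @return Input rows that survive the D-loop filter, with `flank5`,
#'   `flank3`, `mh_len` appended.
#' @export
score_microhomology <- function(ref, deletions, w = 20L,
                                method = "anchored", exclude_dloop = TRUE) {
  del <- tibble::as_tibble(deletions)
  if (exclude_dloop && nrow(del) > 0L) {
    del <- del[!in_dloop(del, ref), , drop = FALSE]
  }
  if (nrow(del) == 0L) {
    return(dplyr::mutate(del, flank5 = character(), flank3 = character(),
                         mh_len = integer()))
  }
  fl <- extract_flanks(ref, del$b5, del$b3, w)
  dplyr::mutate(del, flank5 = fl$flank5, flank3 = fl$flank3,
                mh_len = microhomology_length(fl$flank5, fl$flank3, w,
                                              method = method))
}

#' Microhomology distribution summary
#'
#' @param scored Tibble from [score_microhomology()], one row per unique
#'   deletion (cluster representative); an optional `source` column splits
#'   the summary (e.g. sample vs catalogue).
#' @return List with `fraction` (per source: `n`, `n_mh`, `pct_mh` — the
#'   percentage of deletions with microhomology >= 1 bp) and `histogram`
#'   (per source frequency of each `mh_len`).
#' @export
homology_summary <- function(scored) {
  if (nrow(scored) == 0L) {
    return(list(fraction = tibble::tibble(), histogram = tibble::tibble()))
  }
  scored <- dplyr::mutate(
    tibble::as_tibble(scored),
    source = if ("source" %in% names(scored)) .data$source else "sample"
  )
  fraction <- scored |>
    dplyr::group_by(.data$source) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_mh = sum(.data$mh_len >= 1L),
      pct_mh = round2(100 * .data$n_mh / .data$n),
      .groups = "drop"
    )
  histogram <- scored |>
    dplyr::count(.data$source, .data$mh_len, name = "n") |>
    dplyr::group_by(.data$source) |>
    dplyr::mutate(freq = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  list(fraction = fraction, histogram = histogram)
}

#' Load an external breakpoint catalogue
#'
#' Reads a TSV of deletion breakpoint pairs (MITOMAP- or MitoBreak-style
#' exports, or any two-column table). Column names per source are set in
#' `columns`; coordinates are 1-based breakpoints under this package's
#' convention unless `shift` adjusts them.
#'
#' @param path TSV file.
#' @param source Label stored on the records (`"MITOMAP"`, `"MitoBreak"`,
#'   `"custom"`).
#' @param columns Length-2 character vector naming the 5' and 3' breakpoint
#'   columns; default `c("b5", "b3")`.
#' @param L Genome length used for range validation.
#' @param shift Integer added to both coordinates (dialect adjustment).
#' @return Tibble `b5`, `b3`, `source`; out-of-range rows are dropped with
#'   a warning, and an empty result is an error.
#' @export
load_catalogue <- function(path, source = c("custom", "MITOMAP", "MitoBreak"),
                           columns = c("b5", "b3"), L = 16569L, shift = 0L) {
  source <- match.arg(source)
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(columns %in% names(raw))) {
    stop("catalogue lacks columns ", paste(columns, collapse = ", "))
  }
  rec <- tibble::tibble(
    b5 = suppressWarnings(as.integer(raw[[columns[[1L]]]])) + shift,
    b3 = suppressWarnings(as.integer(raw[[columns[[2L]]]])) + shift,
    source = source
  )
  ok <- !is.na(rec$b5) & !is.na(rec$b3) &
    rec$b5 >= 1L & rec$b5 <= L & rec$b3 >= 1L & rec$b3 <= L & rec$b5 != rec$b3
  if (any(!ok)) {
    warning(sum(!ok), " catalogue row(s) rejected (unparseable or out of [1, ",
            L, "])")
  }
  rec <- rec[ok, , drop = FALSE]
  if (nrow(rec) == 0L) {
    stop("no usable rows in catalogue ", path)
  }
  rec
}
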