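#' Circular mitochondrial reference
#'
#' Builds the reference object used throughout the package: a circular,
#' 1-based DNA sequence (position `L + 1` is position 1) together with named
#' region annotations. The regions that matter downstream are `MT-RNR2` (the
#' heteroplasmy denominator), `MT-ND4` (the ddPCR deletion probe) and the
#' `D-loop` control region, which crosses the coordinate origin.
#'
#' @param sequence Single DNA string (A/C/G/T/N), or a length-1
#'   [Biostrings::DNAStringSet].
#' @param name Contig name used in SAM headers and exports.
#' @param regions Tibble with columns `region`, `start`, `end`, `wraps`.
#'   Defaults to rCRS annotations via [default_regions()], rescaled when the
#'   sequence is not 16,569 bp (miniature test genomes).
#' @return An object of class `mito_reference`: a list with elements `name`,
#'   `sequence` (character), `length` and `regions` (tibble).
#' @examples
#' ref <- mito_reference(strrep("ACGT", 25), name = "toy")
#' ref$length
#' @export
mito_reference <- function(sequence, name = "chrM", regions = NULL) {
  if (inherits(sequence, "DNAStringSet")) {
    stopifnot(length(sequence) == 1L)
    sequence <- as.character(sequence[[1L]])
  }
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  bad <- gsub("[ACGTN]", "", sequence)
  if (nzchar(bad)) {
    stop("reference sequence contains non-ACGTN characters: ", substr(bad, 1, 10))
  }
  if (is.null(regions)) {
    regions <- default_regions(L)
  }
  regions <- validate_regions(regions, L)
  structure(
    list(name = name, sequence = sequence, length = L, regions = regions),
    class = "mito_reference"
  )
}

#' @export
print.mito_reference <- function(x, ...) {
  cat("<mito_reference> ", x$name, ": ", format(x$length, big.mark = ","),
      " bp circular\n", sep = "")
  print(x$regions, ...)
  invisible(x)
}

#' Default rCRS region annotations
#'
#' MT-RNR2 (1671-3229), MT-ND4 (10760-12137) and the origin-spanning D-loop
#' (16024-576). For a genome length other than 16,569 bp the coordinates are
#' scaled proportionally so miniature test references keep the same layout.
#'
#' @param L Genome length in bp.
#' @return Tibble with columns `region`, `start`, `end`, `wraps`.
#' @export
default_regions <- function(L = 16569L) {
  rcrs <- tibble::tibble(
    region = c("MT-RNR2", "MT-ND4", "D-loop"),
    start  = c(1671L, 10760L, 16024L),
    end    = c(3229L, 12137L, 576L),
    wraps  = c(FALSE, FALSE, TRUE)
  )
  if (L == 16569L) {
    return(rcrs)
  }
  scale_pos <- function(p) pmax(1L, pmin(L, as.integer(round(p / 16569 * L))))
  dplyr::mutate(rcrs, start = scale_pos(.data$start), end = scale_pos(.data$end))
}

validate_regions <- function(regions, L) {
  regions <- tibble::as_tibble(regions)
  needed <- c("region", "start", "end", "wraps")
  if (!all(needed %in% names(regions))) {
    stop("regions must have columns: ", paste(needed, collapse = ", "))
  }
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  if (any(regions$start < 1L | regions$start > L | regions$end < 1L | regions$end > L)) {
    stop("region coordinates must lie in [1, ", L, "]")
  }
  bad <- !regions$wraps & regions$end < regions$start
  if (any(bad)) {
    stop("non-wrapping region with end < start: ",
         paste(regions$region[bad], collapse = ", "))
  }
  regions
}

#' Load a mitochondrial reference from FASTA
#'
#' @param fasta Path to a FASTA file.
#' @param contig Contig to use; defaults to the first sequence. Missing
#'   contigs are an error.
#' @param regions Region annotation tibble; default [default_regions()]
#'   scaled to the contig length.
#' @return A [mito_reference()].
#' @export
load_reference <- function(fasta, contig = NULL, regions = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  if (is.null(contig)) {
    contig <- ids[[1L]]
  }
  idx <- match(contig, ids)
  if (is.na(idx)) {
    stop("contig '", contig, "' not found in ", fasta,
         " (available: ", paste(ids, collapse = ", "), ")")
  }
  mito_reference(as.character(seqs[[idx]]), name = contig, regions = regions)
}

#' Positions covered by a (possibly wrapping) region
#'
#' @param region One-row tibble or list with `start`, `end`, `wraps`.
#' @param L Genome length.
#' @return Integer vector of 1-based positions in region order.
#' @export
region_positions <- function(region, L) {
  start <- as.integer(region$start)
  end <- as.integer(region$end)
  if (isTRUE(region$wraps) || end < start) {
    c(start:L, 1:end)
  } else {
    start:end
  }
}

#' Number of deleted bases between two breakpoints on the circle
#'
#' A deletion is the half-open arc `[b5, b3)`: `b5` is the first deleted base
#' and `b3` the first retained base after the deletion. For the common
#' deletion `(8470, 13447)` this gives 4977 bp. Origin-spanning deletions
#' (`b3 < b5`) wrap through position 1.
#'
#' @param b5,b3 1-based breakpoint positions (vectorised).
#' @param L Genome length, default 16,569.
#' @return Integer vector of deletion lengths in bp.
#' @examples
#' circular_gap(8470, 13447) # 4977
#' @export
circular_gap <- function(b5, b3, L = 16569L) {
  b5 <- as.integer(b5)
  b3 <- as.integer(b3)
  if (any(b5 < 1L | b5 > L | b3 < 1L | b3 > L)) {
    stop("breakpoints must lie in [1, ", L, "]")
  }
  if (any(b5 == b3)) {
    stop("b5 == b3 would be a zero-length deletion")
  }
  ifelse(b3 > b5, b3 - b5, b3 - b5 + L)
}

in_interval_circular <- function(pos, start, end, wraps, L) {
  if (wraps || end < start) {
    pos >= start | pos <= end
  } else {
    pos >= start & pos <= end
  }
}

#' Does a deletion have a breakend in the D-loop?
#'
#' The microhomology analysis excludes deletions with either breakend inside
#' the control region, which spans the coordinate origin.
#'
#' @param events Tibble with columns `b5`, `b3`.
#' @param ref A [mito_reference()] whose regions include `D-loop`.
#' @return Logical vector, one per event.
#' @export
in_dloop <- function(events, ref) {
  dl <- dplyr::filter(ref$regions, .data$region == "D-loop")
  if (nrow(dl) == 0L) {
    stop("reference has no D-loop region annotation")
  }
  hit <- function(pos) {
    in_interval_circular(pos, dl$start[[1L]], dl$end[[1L]], dl$wraps[[1L]], ref$length)
  }
  hit(events$b5) | hit(events$b3)
}

#' HGVS-like deletion name under the half-open convention
#'
#' Formats a deletion as `m.{b5}_{b3-1}del{len}`: the label spans the first
#' and last deleted base inclusively, and the suffix is the deleted length.
#' Wrapping is applied to `b3 - 1` when `b3 == 1`.
#'
#' @param b5,b3 Breakpoints as in [circular_gap()] (vectorised).
#' @param L Genome length.
#' @return Character vector of names.
#' @examples
#' format_deletion_name(8470, 13447) # "m.8470_13446del4977"
#' @export
format_deletion_name <- function(b5, b3, L = 16569L) {
  len <- circular_gap(b5, b3, L)
  last_deleted <- ifelse(b3 == 1L, L, b3 - 1L)
  sprintf("m.%d_%ddel%d", as.integer(b5), as.integer(last_deleted), len)
}

#' Parse a deletion name back to breakpoints
#'
#' Inverse of [format_deletion_name()].
#'
#' @param name Character vector like `"m.8470_13446del4977"`.
#' @param L Genome length.
#' @return Tibble with columns `b5`, `b3`, `del_len`.
#' @export
parse_deletion_name <- function(name, L = 16569L) {
  m <- regmatches(name, regexec("^m\\.(\\d+)_(\\d+)del(\\d+)$", name))
  bad <- lengths(m) != 4L
  if (any(bad)) {
    stop("unparseable deletion name: ", name[bad][[1L]])
  }
  b5 <- vapply(m, function(x) as.integer(x[[2L]]), integer(1))
  last <- vapply(m, function(x) as.integer(x[[3L]]), integer(1))
  b3 <- ifelse(last == L, 1L, last + 1L)
  tibble::tibble(b5 = b5, b3 = as.integer(b3), del_len = circular_gap(b5, b3, L))
}

#' Extract circular subsequence
#'
#' @param ref A [mito_reference()].
#' @param start 1-based start position.
#' @param len Number of bases; the slice wraps through the origin as needed.
#' @return Character string of length `len`.
#' @keywords internal
circular_substr <- function(ref, start, len) {
  L <- ref$length
  idx <- ((start - 1L + seq_len(len) - 1L) %% L) + 1L
  paste(strsplit(ref$sequence, "", fixed = TRUE)[[1L]][idx], collapse = "")
}
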