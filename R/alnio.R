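#' Read long-read alignments on the mitochondrial contig
#'
#' Ingests a SAM or BAM file, keeps primary and supplementary alignments on
#' the requested contig with mapping quality at or above `min_mapq`, and
#' drops secondary and unmapped records. Supplementary records share their
#' `read_id` with the primary so split-read deletion pairing can group them
#' downstream. The mapq threshold together with the contig restriction is the
#' guard against reads of nuclear-embedded mitochondrial segments (NUMTs).
#'
#' @param path SAM or BAM file. SAM text is converted on the fly.
#' @param contig Reference contig name (e.g. `"chrM"` or `"NC_012920.1"`).
#' @param min_mapq Minimum mapping quality, default 10.
#' @return Tibble with columns `read_id`, `flag`, `ref_start`, `mapq`,
#'   `cigar`, `strand`, `is_supplementary`.
#' @export
read_mito_alignments <- function(path, contig = NULL, min_mapq = 10L) {
  if (!file.exists(path)) {
    stop("alignment file not found: ", path)
  }
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, indexDestination = FALSE,
                            overwrite = TRUE)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  if (is.null(contig)) {
    contig <- names(hdr)[[1L]]
  }
  if (!contig %in% names(hdr)) {
    stop("contig '", contig, "' absent from header of ", path)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag,
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "strand")
  )
  rec <- Rsamtools::scanBam(bam, param = param)[[1L]]
  keep <- !is.na(rec$rname) & as.character(rec$rname) == contig &
    !is.na(rec$mapq) & rec$mapq >= min_mapq
  tibble::tibble(
    read_id = rec$qname[keep],
    flag = as.integer(rec$flag[keep]),
    ref_start = as.integer(rec$pos[keep]),
    mapq = as.integer(rec$mapq[keep]),
    cigar = rec$cigar[keep],
    strand = as.character(rec$strand[keep]),
    is_supplementary = bitwAnd(as.integer(rec$flag[keep]), 2048L) != 0L
  )
}

#' Parse CIGAR strings into per-record operation tables
#'
#' @param cigar Character vector of CIGAR strings.
#' @return List of tibbles, one per input, with columns `op` and `len`.
#' @export
parse_cigar <- function(cigar) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
  purrr::map2(ops, lens, function(o, l) tibble::tibble(op = o, len = l))
}

ref_consumed <- function(cigar) {
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}

query_consumed <- function(cigar) {
  GenomicAlignments::cigarWidthAlongQuerySpace(cigar, after.soft.clipping = FALSE)
}

#' Per-base depth profile over the reference
#'
#' Depth counts aligned bases (CIGAR `M`, `=`, `X`) per reference position.
#' Deletion (`D`) and skip (`N`) gaps contribute zero depth, so a single
#' large-scale deletion at high heteroplasmy shows as a sharp coverage dip,
#' and mean MT-RNR2 depth counts only molecules physically covering MT-RNR2.
#'
#' @param reads Alignment tibble from [read_mito_alignments()] (or the
#'   simulator). Alignments must not individually wrap the origin; wrapping
#'   reads are expected as two supplementary segments.
#' @param L Reference length.
#' @return Tibble with columns `pos` (1..L) and `depth`.
#' @export
depth_profile <- function(reads, L) {
  if (nrow(reads) == 0L) {
    return(tibble::tibble(pos = seq_len(L), depth = 0L))
  }
  end <- reads$ref_start + ref_consumed(reads$cigar) - 1L
  if (any(end > L)) {
    stop("alignment extends past position ", L,
         "; origin-wrapping single records are not supported")
  }
  rg <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    reads$cigar, pos = reads$ref_start, ops = c("M", "=", "X")
  )
  cov <- IRanges::coverage(unlist(rg), width = L)
  tibble::tibble(pos = seq_len(L), depth = as.integer(cov))
}

#' Mean depth over a (possibly wrapping) region
#'
#' @param profile Depth tibble from [depth_profile()].
#' @param region One-row region spec (`start`, `end`, `wraps`), a region name
#'   looked up in `ref`, or omitted for the whole genome.
#' @param ref Optional [mito_reference()] for name lookup.
#' @return Mean depth (double).
#' @export
mean_region_coverage <- function(profile, region = NULL, ref = NULL) {
  L <- nrow(profile)
  if (is.null(region)) {
    return(mean(profile$depth))
  }
  if (is.character(region)) {
    stopifnot(!is.null(ref))
    region <- dplyr::filter(ref$regions, .data$region == !!region)
    if (nrow(region) == 0L) stop("unknown region name")
  }
  pos <- region_positions(region[1L, ], L)
  if (length(pos) == 0L) stop("zero-length region")
  mean(profile$depth[pos])
}

#' Mitochondrial DNA content estimate
#'
#' Copies of mtDNA per diploid cell, estimated from mean mitochondrial and
#' nuclear coverage as `2 * mt / n` (two nuclear copies per cell).
#'
#' @param mean_mt_cov Mean mtDNA coverage.
#' @param mean_n_cov Mean nuclear coverage; must be positive.
#' @return Estimated copy number (double).
#' @examples
#' estimate_mtdna_content(300, 15) # 40 copies
#' @export
estimate_mtdna_content <- function(mean_mt_cov, mean_n_cov) {
  if (any(mean_n_cov <= 0)) {
    stop("nuclear coverage must be positive; mtDNA content undefined")
  }
  2 * mean_mt_cov / mean_n_cov
}

#' Export a depth profile as bedGraph-style TSV
#'
#' Runs of equal depth are collapsed to `contig, start0, end0, depth` rows
#' (0-based half-open intervals).
#'
#' @param profile Depth tibble.
#' @param contig Contig name for the first column.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_coverage_bedgraph <- function(profile, contig, path) {
  r <- rle(profile$depth)
  end0 <- cumsum(r$lengths)
  out <- tibble::tibble(
    contig = contig,
    start0 = c(0L, end0[-length(end0)]),
    end0 = end0,
    depth = r$values
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}
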