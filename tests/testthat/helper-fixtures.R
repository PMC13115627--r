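# Shared fixture builders. Everything is generated in code; no stored data.

toy_reference <- function(L = 100L, seed = 11L) {
  seq <- withr::with_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  })
  mito_reference(seq, regions = default_regions(L))
}

# One alignment record as the tibble row shape the pipeline consumes.
make_read <- function(read_id, ref_start, cigar, flag = 0L, mapq = 60L,
                      strand = "+") {
  tibble::tibble(
    read_id = read_id, flag = as.integer(flag),
    ref_start = as.integer(ref_start), mapq = as.integer(mapq),
    cigar = cigar, strand = strand,
    is_supplementary = bitwAnd(as.integer(flag), 2048L) != 0L
  )
}

# Independent CIGAR walk: returns reference positions consumed per op kind.
# Used as the oracle against the package's extraction and depth code.
walk_cigar <- function(ref_start, cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  len <- as.integer(sub("[A-Z=]$", "", ops))
  op <- sub("^\\d+", "", ops)
  pos <- ref_start
  aligned <- integer()
  deleted <- list()
  for (i in seq_along(op)) {
    if (op[i] %in% c("M", "=", "X")) {
      aligned <- c(aligned, pos:(pos + len[i] - 1L))
      pos <- pos + len[i]
    } else if (op[i] %in% c("D", "N")) {
      deleted <- c(deleted, list(c(start = pos, len = len[i], is_del = op[i] == "D")))
      pos <- pos + len[i]
    }
  }
  list(aligned = aligned, deleted = deleted)
}

# Brute-force junction-anchored microhomology: run-length encode the
# position-wise match vector and add the runs touching the junction from
# either side.
oracle_mh <- function(flank5, flank3, w) {
  m <- strsplit(flank5, "")[[1L]] == strsplit(flank3, "")[[1L]]
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i5 <- which(starts <= w & ends >= w)
  i3 <- which(starts <= w + 1L & ends >= w + 1L)
  back <- if (r$values[i5]) w - starts[i5] + 1L else 0L
  fwd <- if (r$values[i3]) ends[i3] - w else 0L
  if (i5 == i3 && r$values[i5]) r$lengths[i5] else back + fwd
}

random_flanks <- function(w = 20L) {
  b <- c("A", "C", "G", "T")
  list(f5 = paste(sample(b, 2 * w, TRUE), collapse = ""),
       f3 = paste(sample(b, 2 * w, TRUE), collapse = ""))
}
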