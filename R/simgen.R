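#' Simulation configuration
#'
#' Describes a heteroplasmic molecule population: a circular genome carrying
#' zero or more deletion species at given molecule fractions, sequenced to a
#' target mean coverage with a lognormal read-length model (median about
#' 10 kb, the scale of HiFi inserts, truncated below at 1 kb and above at
#' the molecule length).
#'
#' @param deletions Tibble with columns `b5`, `b3`, `fraction` (may be
#'   empty for a deletion-negative sample). Fractions are molecule-level
#'   heteroplasmies and must sum to at most 1.
#' @param mean_coverage Target mean depth across the genome.
#' @param seed Integer seed; every downstream draw flows from it.
#' @param read_meanlog,read_sdlog Lognormal read-length parameters.
#' @param read_min Minimum read length in bp.
#' @param substitution_rate Per-base substitution probability in emitted
#'   read sequences (never indels); default 0, error-free reads.
#' @param linear_only If TRUE, confine read starts so no alignment crosses
#'   the reference origin (simple single-record fixtures; distorts regional
#'   coverage at long read lengths). Default FALSE: reads are placed
#'   uniformly on the circle and origin-crossing alignments are emitted as
#'   hard-clipped supplementary pairs.
#' @return A `sim_config` list.
#' @export
sim_config <- function(deletions = NULL, mean_coverage = 800, seed = 1L,
                       read_meanlog = log(10000), read_sdlog = 0.25,
                       read_min = 1000L, substitution_rate = 0,
                       linear_only = FALSE) {
  if (is.null(deletions)) {
    deletions <- tibble::tibble(b5 = integer(), b3 = integer(),
                                fraction = double())
  }
  deletions <- tibble::as_tibble(deletions)
  stopifnot(all(c("b5", "b3", "fraction") %in% names(deletions)))
  if (any(deletions$fraction < 0) || sum(deletions$fraction) > 1) {
    stop("deletion fractions must be non-negative and sum to at most 1")
  }
  if (mean_coverage <= 0) {
    stop("mean_coverage must be positive")
  }
  structure(
    list(deletions = deletions, mean_coverage = mean_coverage, seed = seed,
         read_meanlog = read_meanlog, read_sdlog = read_sdlog,
         read_min = as.integer(read_min),
         substitution_rate = substitution_rate, linear_only = linear_only),
    class = "sim_config"
  )
}

#' Simulate a circular reference sequence
#'
#' Uniform random A/C/G/T circle with the default region layout scaled to
#' the requested length; deterministic per seed.
#'
#' @param genome_len Length in bp (default 16,569; minimum 200).
#' @param seed Integer seed.
#' @param name Contig name.
#' @return A [mito_reference()].
#' @export
simulate_reference <- function(genome_len = 16569L, seed = 1L, name = "chrM") {
  if (genome_len < 200L) {
    stop("genome_len must be at least 200 bp")
  }
  seq <- withr::with_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), genome_len, replace = TRUE),
          collapse = "")
  })
  mito_reference(seq, name = name, regions = default_regions(genome_len))
}

set_bases <- function(chars, pos, values, L) {
  chars[((pos - 1L) %% L) + 1L] <- values
  chars
}

other_base <- function(b) {
  c(A = "C", C = "G", G = "T", T = "A", N = "A")[[b]]
}

#' Plant exact microhomology at a deletion junction
#'
#' Copies the `k` bases starting at `b3` onto the `k` bases starting at
#' `b5`, then forces mismatches immediately before the junction bases and
#' immediately after the copied run, so the junction-anchored microhomology
#' is exactly `k`. With `k = 0` the reference is returned untouched.
#'
#' @param ref A [mito_reference()].
#' @param b5,b3 Junction breakpoints.
#' @param k Desired homology length, 0 to 20.
#' @return Modified [mito_reference()].
#' @export
plant_microhomology <- function(ref, b5, b3, k) {
  if (k > 20L) {
    stop("k must be at most the 20 bp window")
  }
  if (k == 0L) {
    return(ref)
  }
  L <- ref$length
  chars <- strsplit(ref$sequence, "", fixed = TRUE)[[1L]]
  at <- function(p) chars[((p - 1L) %% L) + 1L]
  chars <- set_bases(chars, b5 + 0:(k - 1L), at(b3 + 0:(k - 1L)), L)
  # break the run one base past the copied region, and one base before it
  if (at(b5 + k) == at(b3 + k)) {
    chars <- set_bases(chars, b5 + k, other_base(at(b3 + k)), L)
  }
  if (at(b5 - 1L) == at(b3 - 1L)) {
    chars <- set_bases(chars, b5 - 1L, other_base(at(b3 - 1L)), L)
  }
  mito_reference(paste(chars, collapse = ""), name = ref$name,
                 regions = ref$regions)
}

retained_positions <- function(L, b5 = NULL, b3 = NULL) {
  if (is.null(b5)) {
    return(seq_len(L))
  }
  deleted <- ((b5 - 1L + seq_len(circular_gap(b5, b3, L)) - 1L) %% L) + 1L
  setdiff(seq_len(L), deleted)
}

# Split one read's ascending reference-position vector into SAM records:
# within a record, jumps forward become D ops; a wrap (position decrease)
# starts a new (supplementary) record.
build_records <- function(ref_pos) {
  jump <- diff(ref_pos)
  rec_break <- which(jump < 0L)
  rec_bounds <- cbind(c(1L, rec_break + 1L), c(rec_break, length(ref_pos)))
  records <- vector("list", nrow(rec_bounds))
  for (i in seq_len(nrow(rec_bounds))) {
    pos <- ref_pos[rec_bounds[i, 1L]:rec_bounds[i, 2L]]
    d <- diff(pos)
    run_end <- c(which(d > 1L), length(pos))
    run_start <- c(1L, which(d > 1L) + 1L)
    m_len <- run_end - run_start + 1L
    d_len <- if (length(pos) > 1L) d[d > 1L] - 1L else integer()
    cig <- character(2L * length(m_len) - 1L)
    cig[seq_along(m_len) * 2L - 1L] <- paste0(m_len, "M")
    if (length(d_len)) {
      cig[seq_along(d_len) * 2L] <- paste0(d_len, "D")
    }
    records[[i]] <- list(
      ref_start = pos[[1L]],
      cigar = paste(cig, collapse = ""),
      q_from = rec_bounds[i, 1L], q_to = rec_bounds[i, 2L],
      spans_junction = any(d_len > 0L)
    )
  }
  records
}

#' Simulate one sample's long-read alignments
#'
#' Draws molecules from the configured heteroplasmic population (class
#' probabilities weighted by molecule fraction times molecule length, as
#' shearing of longer molecules yields proportionally more fragments),
#' places reads uniformly on each circular molecule, and emits SAM-style
#' alignment records against the reference: a read spanning a deletion
#' junction carries the deletion as a CIGAR `D` operation; a read crossing
#' the reference origin is emitted as two hard-clipped supplementary
#' segments (unless `linear_only`).
#'
#' @param ref A [mito_reference()].
#' @param config A [sim_config()].
#' @return List with `reads` (alignment tibble with `seq`), `truth`
#'   (per-read `read_id`, `molecule`, `spans_junction`, `n_records`), and
#'   `truth_summary` (expected heteroplasmy and junction list).
#' @export
simulate_sample <- function(ref, config) {
  stopifnot(inherits(config, "sim_config"))
  L <- ref$length
  dels <- config$deletions
  classes <- c("intact", if (nrow(dels)) paste0("del", seq_len(nrow(dels))))
  retained <- c(
    list(retained_positions(L)),
    purrr::map(seq_len(nrow(dels)),
               ~ retained_positions(L, dels$b5[[.x]], dels$b3[[.x]]))
  )
  mol_len <- lengths(retained)
  weights <- c(1 - sum(dels$fraction), dels$fraction) * mol_len
  mean_len <- exp(config$read_meanlog + config$read_sdlog^2 / 2)
  n_reads <- max(1L, ceiling(config$mean_coverage * L / mean_len))
  chars <- strsplit(ref$sequence, "", fixed = TRUE)[[1L]]
  bases <- c("A", "C", "G", "T")

  withr::with_seed(config$seed, {
    # all placement randomness is drawn before any per-read error draws, so
    # the substitution rate never perturbs the alignments themselves
    cls <- sample.int(length(classes), n_reads, replace = TRUE, prob = weights)
    lens <- pmax(config$read_min,
                 round(stats::rlnorm(n_reads, config$read_meanlog,
                                     config$read_sdlog)))
    rs <- pmin(lens, mol_len[cls])
    n_starts <- if (config$linear_only) {
      mol_len[cls] - rs + 1L
    } else {
      mol_len[cls]
    }
    starts <- as.integer(floor(stats::runif(n_reads) * n_starts)) + 1L
    out_reads <- vector("list", n_reads)
    out_truth <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      M <- mol_len[[cls[i]]]
      r <- rs[[i]]
      s <- starts[[i]]
      mol_idx <- ((s - 1L + seq_len(r) - 1L) %% M) + 1L
      ref_pos <- retained[[cls[i]]][mol_idx]
      recs <- build_records(ref_pos)
      read_id <- sprintf("read_%05d", i)
      seq_full <- chars[ref_pos]
      if (config$substitution_rate > 0) {
        hit <- which(stats::runif(r) < config$substitution_rate)
        if (length(hit)) {
          seq_full[hit] <- vapply(seq_full[hit], function(b) {
            sample(setdiff(bases, b), 1L)
          }, character(1))
        }
      }
      total_q <- r
      out_reads[[i]] <- purrr::imap(recs, function(rec, j) {
        lead <- rec$q_from - 1L
        trail <- total_q - rec$q_to
        cig <- paste0(
          if (lead > 0L) paste0(lead, "H") else "",
          rec$cigar,
          if (trail > 0L) paste0(trail, "H") else ""
        )
        tibble::tibble(
          read_id = read_id,
          flag = if (j == 1L) 0L else 2048L,
          ref_start = rec$ref_start,
          mapq = 60L,
          cigar = cig,
          strand = "+",
          is_supplementary = j != 1L,
          seq = paste(seq_full[rec$q_from:rec$q_to], collapse = "")
        )
      }) |> dplyr::bind_rows()
      out_truth[[i]] <- tibble::tibble(
        read_id = read_id,
        molecule = classes[[cls[i]]],
        spans_junction = any(vapply(recs, `[[`, logical(1), "spans_junction")),
        n_records = length(recs)
      )
    }
    reads <- dplyr::bind_rows(out_reads)
    truth <- dplyr::bind_rows(out_truth)
    truth_summary <- list(
      expected_heteroplasmy_pct = 100 * sum(dels$fraction),
      junctions = dels,
      n_reads = n_reads,
      seed = config$seed
    )
    list(reads = reads, truth = truth, truth_summary = truth_summary)
  })
}

#' Write alignments as a SAM text file
#'
#' Coordinate-sorted SAM with a minimal header; records carry `*` base
#' qualities. Byte-identical output for identical input.
#'
#' @param reads Alignment tibble (with or without a `seq` column).
#' @param ref A [mito_reference()] for the `@SQ` line.
#' @param path Output `.sam` path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, ref, path) {
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    paste0("@SQ\tSN:", ref$name, "\tLN:", ref$length),
    "@PG\tID:mitodel\tPN:mitodel"
  )
  reads <- dplyr::arrange(reads, .data$ref_start, .data$read_id, .data$flag)
  seq <- if ("seq" %in% names(reads)) reads$seq else "*"
  body <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
    reads$read_id, reads$flag, ref$name, reads$ref_start, reads$mapq,
    reads$cigar, seq
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a reference as FASTA
#'
#' @param ref A [mito_reference()].
#' @param path Output `.fasta` path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(ref, path) {
  x <- Biostrings::DNAStringSet(ref$sequence)
  names(x) <- ref$name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Named simulation presets
#'
#' Three study-like scenarios on the full-size genome: `slsmd` (one
#' junction, the common deletion at 30% heteroplasmy), `mmd` (five
#' well-separated junctions totalling 25%), and `negative` (no deletions).
#'
#' @param name Preset name.
#' @param mean_coverage Target depth (default 800).
#' @param seed Integer seed.
#' @return A [sim_config()].
#' @export
sim_preset <- function(name = c("slsmd", "mmd", "negative"),
                       mean_coverage = 800, seed = 1L) {
  name <- match.arg(name)
  dels <- switch(
    name,
    slsmd = tibble::tibble(b5 = 8470L, b3 = 13447L, fraction = 0.30),
    mmd = tibble::tibble(
      b5 = c(6000L, 8470L, 9500L, 11000L, 13000L),
      b3 = c(9000L, 13447L, 14200L, 15500L, 15900L),
      fraction = c(0.05, 0.08, 0.04, 0.05, 0.03)
    ),
    negative = NULL
  )
  sim_config(deletions = dels, mean_coverage = mean_coverage, seed = seed)
}
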