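#' Simulate amplicon reads for fractionation samples
#'
#' Draws per-element counts with [sim_fraction_counts()] and emits one set
#' of reads per sample. Each read is `flank5 + insert + flank3`, optionally
#' padded with random bases to `read_len`; a configurable fraction of reads
#' is reverse-complemented and a configurable fraction is junk (random
#' sequence carrying no anchors). Reads are emitted already trimmed, with
#' constant Phred qualities; quality trimming upstream is a pass-through
#' hook (see [trim_reads()]).
#'
#' @param truth Ground-truth tibble (`element`, `base_abundance`,
#'   `log2_enrichment`).
#' @param spec A [library_spec()].
#' @param samples Sample sheet from [fraction_samples()].
#' @param dispersion Negative-binomial dispersion.
#' @param read_len Fixed read length; `NULL` (default) emits full amplicons
#'   with no padding. When given, must fit the longest amplicon.
#' @param rc_fraction Fraction of reads emitted reverse-complemented
#'   (default 0, single-orientation amplicon; at most 0.5).
#' @param junk_fraction Fraction of reads that are anchorless junk.
#' @param seed Integer seed.
#' @param dir If non-NULL, write one FASTQ (`<sample>.fastq`) per sample
#'   plus `truth.tsv` into this directory and return the paths.
#' @return Invisibly, a list with `reads` (named list of character vectors,
#'   or file paths when `dir` is given), `counts` (the underlying count
#'   tibble), and `truth`.
#' @export
sim_fraction_reads <- function(truth, spec, samples, dispersion = 0.02,
                               read_len = NULL, rc_fraction = 0,
                               junk_fraction = 0, seed = 1L, dir = NULL) {
  if (nrow(truth) == 0L) abort("truth table is empty")
  stopifnot(inherits(spec, "library_spec"))
  if (rc_fraction < 0 || rc_fraction > 0.5) {
    abort("rc_fraction must be in [0, 0.5]")
  }
  if (junk_fraction < 0 || junk_fraction >= 1) {
    abort("junk_fraction must be in [0, 1)")
  }
  amplicon_max <- nchar(spec$flank5) + spec$insert_len_max + nchar(spec$flank3)
  if (!is.null(read_len) && read_len < amplicon_max) {
    abort(sprintf("read_len must be >= %d (longest amplicon)", amplicon_max))
  }
  seed <- check_scalar_int(seed, "seed")
  counts <- sim_fraction_counts(
    truth,
    dplyr::mutate(samples, depth = round(.data$depth * (1 - junk_fraction))),
    dispersion = dispersion, seed = seed
  )
  withr::local_seed(seed + 1L)
  reads <- vector("list", nrow(samples))
  names(reads) <- samples$sample
  for (j in seq_len(nrow(samples))) {
    reads[[j]] <- build_sample_reads(
      counts, samples$sample[j], samples$depth[j], spec,
      read_len, rc_fraction, junk_fraction
    )
  }
  out <- list(reads = reads, counts = counts, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- character(nrow(samples))
    for (j in seq_along(reads)) {
      paths[j] <- file.path(dir, paste0(samples$sample[j], ".fastq"))
      write_fastq(reads[[j]], paths[j])
    }
    names(paths) <- samples$sample
    write_truth_tsv(truth, file.path(dir, "truth.tsv"))
    out$reads <- as.list(paths)
  }
  invisible(out)
}

build_sample_reads <- function(counts, sample, depth, spec, read_len,
                               rc_fraction, junk_fraction) {
  n_i <- counts[[sample]]
  reads <- paste0(spec$flank5, rep(counts$element, n_i), spec$flank3)
  if (!is.null(read_len)) {
    pad <- read_len - nchar(reads)
    need <- pad > 0L
    if (any(need)) {
      reads[need] <- paste0(
        reads[need], stringi::stri_rand_strings(sum(need), pad[need], "[ACGT]"))
    }
  }
  if (junk_fraction > 0) {
    n_junk <- round(depth * junk_fraction)
    junk_len <- if (is.null(read_len)) {
      nchar(spec$flank5) + spec$insert_len_max + nchar(spec$flank3)
    } else read_len
    reads <- c(reads, stringi::stri_rand_strings(n_junk, junk_len, "[ACGT]"))
  }
  if (rc_fraction > 0) {
    idx <- sample.int(length(reads), round(rc_fraction * length(reads)))
    reads[idx] <- revcomp(reads[idx])
  }
  reads[sample.int(length(reads))]
}

#' Simulate reads and count them, one sample at a time
#'
#' Memory-bounded end-to-end path: for each sample, reads are simulated,
#' inserts extracted against `spec`, and counts tallied before the reads
#' are discarded. Equivalent to [sim_fraction_reads()] followed by
#' [count_reads()], but never holds more than one sample's reads.
#'
#' @inheritParams sim_fraction_reads
#' @param whitelist Optional element whitelist passed to the counting step.
#' @return A count tibble as from [count_reads()].
#' @export
sim_and_count <- function(truth, spec, samples, dispersion = 0.02,
                          read_len = NULL, rc_fraction = 0,
                          junk_fraction = 0, seed = 1L, whitelist = NULL) {
  seed <- check_scalar_int(seed, "seed")
  counts <- sim_fraction_counts(
    truth,
    dplyr::mutate(samples, depth = round(.data$depth * (1 - junk_fraction))),
    dispersion = dispersion, seed = seed
  )
  withr::local_seed(seed + 1L)
  per_sample <- vector("list", nrow(samples))
  for (j in seq_len(nrow(samples))) {
    reads <- build_sample_reads(
      counts, samples$sample[j], samples$depth[j], spec,
      read_len, rc_fraction, junk_fraction
    )
    per_sample[[j]] <- tally_inserts(reads, spec, whitelist)
    rm(reads)
  }
  assemble_count_table(per_sample, samples, whitelist)
}

#' Quality-trimming pass-through hook
#'
#' Simulated reads are emitted clean (no adapters, uniform qualities), so
#' trimming is the identity; the hook exists so a real trimmer can be
#' slotted in front of [count_reads()].
#'
#' @param reads Character vector of reads.
#' @return The reads, unchanged.
#' @export
trim_reads <- function(reads) reads
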