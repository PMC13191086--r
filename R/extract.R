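#' Extract the inserted element from amplicon reads
#'
#' A read is valid if it contains the constant 10-bp flanking anchors: the
#' insert is the substring strictly between the first exact occurrence of
#' the 5' anchor and the first subsequent exact occurrence of the 3'
#' anchor, provided its length lies in the spec's range and it contains no
#' N. If the forward search fails, the reverse complement of the read is
#' searched once. Anchor matching is exact by default; `max_mismatch`
#' relaxes it.
#'
#' @param reads Character vector of reads (uppercase A/C/G/T/N).
#' @param spec A [library_spec()].
#' @param max_mismatch Anchor mismatches tolerated (default 0, exact).
#' @return Character vector: the insert per read, `NA` for invalid reads.
#' @examples
#' spec <- kmer_library_spec()
#' extract_insert(paste0(spec$flank5, "CGAAGG", spec$flank3), spec)
#' @export
extract_insert <- function(reads, spec, max_mismatch = 0L) {
  stopifnot(inherits(spec, "library_spec"))
  if (length(reads) == 0L) return(character())
  fwd <- extract_oriented(reads, spec, max_mismatch)
  miss <- is.na(fwd)
  if (any(miss)) {
    fwd[miss] <- extract_oriented(revcomp(reads[miss]), spec, max_mismatch)
  }
  fwd
}

extract_oriented <- function(reads, spec, max_mismatch) {
  out <- rep(NA_character_, length(reads))
  if (max_mismatch == 0L) {
    i5 <- regexpr(spec$anchor5, reads, fixed = TRUE, useBytes = TRUE)
    hit <- which(i5 > 0L)
    if (length(hit) == 0L) return(out)
    rest <- substr(reads[hit], i5[hit] + 10L, nchar(reads[hit]))
    i3 <- regexpr(spec$anchor3, rest, fixed = TRUE, useBytes = TRUE)
    len <- i3 - 1L
    ins <- substr(rest, 1L, len)
    ok <- i3 > 0L & len >= spec$insert_len_min & len <= spec$insert_len_max &
      !grepl("N", ins, fixed = TRUE)
    out[hit[ok]] <- ins[ok]
    return(out)
  }
  # mismatch-tolerant path via Biostrings
  subj <- Biostrings::DNAStringSet(reads)
  m5 <- Biostrings::vmatchPattern(spec$anchor5, subj, max.mismatch = max_mismatch)
  m3 <- Biostrings::vmatchPattern(spec$anchor3, subj, max.mismatch = max_mismatch)
  s5 <- Biostrings::startIndex(m5)
  s3 <- Biostrings::startIndex(m3)
  for (i in seq_along(reads)) {
    if (is.null(s5[[i]])) next
    a5 <- min(s5[[i]])
    cand <- s3[[i]][s3[[i]] >= a5 + 10L]
    if (length(cand) == 0L) next
    a3 <- min(cand)
    len <- a3 - (a5 + 10L)
    if (len < spec$insert_len_min || len > spec$insert_len_max) next
    ins <- substr(reads[i], a5 + 10L, a3 - 1L)
    if (!grepl("N", ins, fixed = TRUE)) out[i] <- ins
  }
  out
}

#' Count extracted inserts per fractionation sample
#'
#' Builds the raw count table from FASTQ files (or in-memory reads), one
#' row per distinct extracted insert. With a `whitelist`, rows are exactly
#' the whitelist elements; extracted inserts outside it are dropped and
#' tallied separately. Reads failing anchor extraction are tallied as
#' invalid per sample. The result is deterministic regardless of read
#' order (rows sorted by element).
#'
#' @param fastq Named character vector of FASTQ paths, one per sample, with
#'   names of the form `fraction_replicate` (e.g. `nuclear_1`).
#' @param spec A [library_spec()].
#' @param whitelist Optional character vector of allowed elements.
#' @param reads Alternative to `fastq`: named list of read vectors.
#' @param max_mismatch Passed to [extract_insert()].
#' @return Tibble with `element` plus one integer column per sample;
#'   attributes `samples` (parsed sample sheet), `invalid_reads` and
#'   `dropped_reads` (named per-sample tallies).
#' @export
count_reads <- function(fastq = NULL, spec, whitelist = NULL, reads = NULL,
                        max_mismatch = 0L) {
  stopifnot(inherits(spec, "library_spec"))
  if (is.null(fastq) == is.null(reads)) {
    abort("supply exactly one of `fastq` (paths) or `reads` (vectors)")
  }
  src <- if (is.null(reads)) fastq else reads
  if (is.null(names(src)) || any(names(src) == "")) {
    abort("samples must be named (fraction_replicate, e.g. nuclear_1)")
  }
  info <- parse_sample_names(names(src))
  if (!all(c("nuclear", "cytoplasmic") %in% info$fraction)) {
    abort("need at least one sample per fraction (nuclear and cytoplasmic)")
  }
  per_sample <- purrr::map(seq_along(src), function(j) {
    rd <- if (is.null(reads)) read_fastq(src[[j]]) else src[[j]]
    tally_inserts(rd, spec, whitelist, max_mismatch)
  })
  assemble_count_table(per_sample, info, whitelist)
}

tally_inserts <- function(rd, spec, whitelist = NULL, max_mismatch = 0L) {
  ins <- extract_insert(rd, spec, max_mismatch)
  invalid <- sum(is.na(ins))
  ins <- ins[!is.na(ins)]
  if (!is.null(whitelist)) {
    idx <- match(ins, whitelist)
    dropped <- sum(is.na(idx))
    counts <- tabulate(idx[!is.na(idx)], nbins = length(whitelist))
    names(counts) <- whitelist
  } else {
    dropped <- 0L
    tab <- table(ins)
    counts <- as.integer(tab)
    names(counts) <- names(tab)
  }
  list(counts = counts, invalid = invalid, dropped = dropped)
}

assemble_count_table <- function(per_sample, samples, whitelist = NULL) {
  elements <- if (!is.null(whitelist)) {
    sort(unique(whitelist))
  } else {
    sort(unique(unlist(lapply(per_sample, function(x) names(x$counts)))))
  }
  out <- tibble(element = elements)
  for (j in seq_along(per_sample)) {
    v <- per_sample[[j]]$counts[elements]
    v[is.na(v)] <- 0L
    out[[samples$sample[j]]] <- as.integer(v)
  }
  attr(out, "samples") <- samples
  attr(out, "invalid_reads") <-
    setNames(vapply(per_sample, `[[`, numeric(1), "invalid"), samples$sample)
  attr(out, "dropped_reads") <-
    setNames(vapply(per_sample, `[[`, numeric(1), "dropped"), samples$sample)
  out
}

#' Per-element sequencing coverage summary
#'
#' Fold-coverage of an element is its total raw count over all samples.
#'
#' @param ct Count tibble from [count_reads()].
#' @param threshold Coverage threshold; the reported fraction counts
#'   elements with total strictly greater than it.
#' @return One-row tibble: `n_elements`, `median_coverage`,
#'   `frac_above_threshold`, `threshold`.
#' @export
coverage_summary <- function(ct, threshold = 10) {
  if (nrow(ct) == 0L) abort("count table is empty")
  totals <- element_totals(ct)$total
  tibble(
    n_elements = nrow(ct),
    median_coverage = median(totals),
    frac_above_threshold = mean(totals > threshold),
    threshold = threshold
  )
}

#' @rdname coverage_summary
#' @return `element_totals`: tibble with `element`, `total`.
#' @export
element_totals <- function(ct) {
  tibble(element = ct$element,
         total = rowSums(as.matrix(ct[, sample_cols(ct), drop = FALSE])))
}

#' Write / read a count table as TSV
#'
#' First column `element`, one column per sample; invalid- and
#' dropped-read tallies are preserved as `#` comment header lines.
#'
#' @param ct Count tibble.
#' @param path File path.
#' @return `write_count_table` returns `path` invisibly.
#' @export
write_count_table <- function(ct, path) {
  hdr <- character()
  for (kind in c("invalid_reads", "dropped_reads")) {
    v <- attr(ct, kind)
    if (!is.null(v)) {
      hdr <- c(hdr, sprintf("# %s %s=%d", kind, names(v), as.integer(v)))
    }
  }
  writeLines(hdr, path)
  readr::write_tsv(ct, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  ct <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  hdr <- grep("^#", readLines(path, n = 200L), value = TRUE)
  for (kind in c("invalid_reads", "dropped_reads")) {
    m <- grep(paste0("^# ", kind, " "), hdr, value = TRUE)
    if (length(m) > 0L) {
      kv <- sub(paste0("^# ", kind, " "), "", m)
      parts <- strsplit(kv, "=", fixed = TRUE)
      attr(ct, kind) <- setNames(
        as.numeric(vapply(parts, `[[`, "", 2L)),
        vapply(parts, `[[`, "", 1L))
    }
  }
  attr(ct, "samples") <- parse_sample_names(sample_cols(ct))
  ct
}
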