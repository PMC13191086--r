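#' Random nucleotide reference sequence
#'
#' @param length Reference length in nt.
#' @param seed Integer seed.
#' @param ref_id Name of the reference.
#' @return Named character vector of length 1.
#' @export
sim_reference <- function(length = 8000L, seed = 1L, ref_id = "ref") {
  length <- check_scalar_int(length, "length", min = 1)
  seed <- check_scalar_int(seed, "seed")
  withr::local_seed(seed)
  setNames(stringi::stri_rand_strings(1L, length, "[ACGT]"), ref_id)
}

#' Simulate a random-fragment reporter library from a reference
#'
#' Fragments are sampled uniformly along the reference with lengths uniform
#' in `[len_min, len_max]` (defaulting to the 30-100 nt range of detected
#' fragments; the wider 75-150 nt amplified range is available by
#' argument). A fragment overlapping the union of `nuclear_regions` by at
#' least half its length is planted with `log2_enrichment = +effect_log2`;
#' all others are neutral. Identical sequences drawn more than once are
#' collapsed into one element with summed abundance.
#'
#' @param reference Named character vector of length 1 (the reference), or
#'   a path to a FASTA file.
#' @param n_fragments Number of fragment draws.
#' @param len_min,len_max Fragment length range (nt); `len_min >= 20`.
#' @param nuclear_regions Tibble with `start`, `end` (0-based half-open)
#'   within the reference, or `NULL` for no planted regions.
#' @param effect_log2 Planted enrichment for region fragments.
#' @param seed Integer seed.
#' @return Tibble with `element`, `ref_id`, `start`, `end`, `length`,
#'   `base_abundance`, `log2_enrichment`, `class_true`; attribute `delta`.
#' @examples
#' ref <- sim_reference(2000, seed = 1)
#' frags <- sim_fragment_library(ref, 500, seed = 1,
#'   nuclear_regions = tibble::tibble(start = 500, end = 700))
#' @export
sim_fragment_library <- function(reference, n_fragments, len_min = 30L,
                                 len_max = 100L, nuclear_regions = NULL,
                                 effect_log2 = 2, seed = 1L) {
  reference <- load_reference(reference)
  n_fragments <- check_scalar_int(n_fragments, "n_fragments", min = 1)
  len_min <- check_scalar_int(len_min, "len_min", min = 20)
  len_max <- check_scalar_int(len_max, "len_max", min = len_min)
  seed <- check_scalar_int(seed, "seed")
  L <- nchar(reference[[1L]])
  if (len_max > L) abort("len_max exceeds reference length")
  if (!is.null(nuclear_regions)) {
    stopifnot(all(c("start", "end") %in% names(nuclear_regions)))
    if (any(nuclear_regions$start < 0L) || any(nuclear_regions$end > L) ||
        any(nuclear_regions$start >= nuclear_regions$end)) {
      abort("nuclear_regions must be non-empty 0-based half-open intervals inside the reference")
    }
  }
  withr::local_seed(seed)
  len <- sample_range(len_min, len_max, n_fragments)
  start <- vapply(len, function(l) sample.int(L - l + 1L, 1L) - 1L, integer(1))
  end <- start + len
  abundance <- rlnorm(n_fragments, 0, 1)
  ovl <- numeric(n_fragments)
  if (!is.null(nuclear_regions)) {
    for (r in seq_len(nrow(nuclear_regions))) {
      ovl <- ovl + pmax(
        0L,
        pmin(end, nuclear_regions$end[r]) - pmax(start, nuclear_regions$start[r])
      )
    }
  }
  lfc <- if_else(ovl >= len / 2, effect_log2, 0)
  frags <- tibble(
    element = substring(reference[[1L]], start + 1L, end),
    ref_id = names(reference)[1L],
    start = start, end = end, length = len,
    base_abundance = abundance,
    log2_enrichment = lfc,
    class_true = if_else(lfc >= effect_log2, "nuclear", "neutral")
  )
  out <- frags %>%
    group_by(.data$element) %>%
    summarise(
      ref_id = .data$ref_id[1L], start = .data$start[1L],
      end = .data$end[1L], length = .data$length[1L],
      base_abundance = sum(.data$base_abundance),
      log2_enrichment = .data$log2_enrichment[1L],
      class_true = .data$class_true[1L], .groups = "drop"
    ) %>%
    arrange(.data$start, .data$end)
  attr(out, "delta") <- effect_log2
  out
}

load_reference <- function(reference) {
  if (is.character(reference) && length(reference) == 1L &&
      !grepl("^[ACGTN]+$", reference) && file.exists(reference)) {
    seqs <- Biostrings::readDNAStringSet(reference)
    reference <- setNames(as.character(seqs), names(seqs))
  }
  if (!is.character(reference) || length(reference) < 1L ||
      any(nchar(reference) == 0L)) {
    abort("reference must be a non-empty nucleotide string or FASTA path")
  }
  if (is.null(names(reference))) names(reference) <- paste0("ref", seq_along(reference))
  reference
}
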