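#' Ground-truth table for the saturating 6-mer library
#'
#' Generates one record per distinct 6-mer (4,096 in total) with a relative
#' library abundance and a planted true nuclear:cytoplasmic log2 enrichment:
#' `n_nuclear` randomly chosen 6-mers receive `+effect_log2`, `n_cyto`
#' receive `-effect_log2`, the rest are neutral. The default planting of
#' 110 nuclear and 49 cytoplasmic elements mirrors the scale of elements a
#' saturating screen recovers.
#'
#' @param n_nuclear,n_cyto Numbers of planted nuclear / cytoplasmic 6-mers.
#' @param effect_log2 Magnitude of the planted log2 enrichment (> 0).
#' @param seed Integer seed; generation is bit-reproducible.
#' @return Tibble with columns `element`, `base_abundance`,
#'   `log2_enrichment`, `class_true`; attribute `delta` holds the class
#'   threshold (equal to `effect_log2`).
#' @examples
#' truth <- sim_kmer_truth(110, 49, effect_log2 = 1, seed = 7)
#' dplyr::count(truth, class_true)
#' @export
sim_kmer_truth <- function(n_nuclear = 110L, n_cyto = 49L, effect_log2 = 1,
                           seed = 1L) {
  n_nuclear <- check_scalar_int(n_nuclear, "n_nuclear", min = 0)
  n_cyto <- check_scalar_int(n_cyto, "n_cyto", min = 0)
  if (n_nuclear + n_cyto > 4096L) {
    abort("n_nuclear + n_cyto must be <= 4096")
  }
  if (!is.numeric(effect_log2) || effect_log2 <= 0) {
    abort("effect_log2 must be > 0")
  }
  seed <- check_scalar_int(seed, "seed")
  elements <- all_kmers(6L)
  withr::local_seed(seed)
  abundance <- rlnorm(4096L, meanlog = 0, sdlog = 1)
  planted <- sample(elements, n_nuclear + n_cyto)
  lfc <- numeric(4096L)
  names(lfc) <- elements
  lfc[planted[seq_len(n_nuclear)]] <- effect_log2
  if (n_cyto > 0L) lfc[planted[n_nuclear + seq_len(n_cyto)]] <- -effect_log2
  out <- tibble(
    element = elements,
    base_abundance = abundance,
    log2_enrichment = unname(lfc),
    class_true = dplyr::case_when(
      lfc >= effect_log2 ~ "nuclear",
      lfc <= -effect_log2 ~ "cytoplasmic",
      TRUE ~ "neutral"
    )
  )
  attr(out, "delta") <- effect_log2
  out
}

#' Sample sheet for fractionation replicates
#'
#' @param replicates Number of biological replicates per fraction.
#' @param depth Sequencing depth (reads) per sample; recycled.
#' @param condition Optional condition prefix (e.g. "control"/"kd").
#' @return Tibble with `sample`, `fraction`, `replicate`, `depth`.
#' @export
fraction_samples <- function(replicates = 3L, depth = 5e6, condition = NULL) {
  replicates <- check_scalar_int(replicates, "replicates", min = 1)
  grid <- tidyr::expand_grid(
    fraction = c("nuclear", "cytoplasmic"),
    replicate = seq_len(replicates)
  )
  nm <- paste(grid$fraction, grid$replicate, sep = "_")
  if (!is.null(condition)) nm <- paste(condition, nm, sep = "_")
  tibble(
    sample = nm,
    fraction = grid$fraction,
    replicate = grid$replicate,
    depth = rep_len(depth, nrow(grid))
  )
}

#' Write / read a ground-truth table as TSV
#'
#' Truth tables round-trip losslessly through this tab-separated format.
#'
#' @param truth Tibble as returned by [sim_kmer_truth()] or the other
#'   generators.
#' @param path File path.
#' @return `write_truth_tsv` returns `path` invisibly; `read_truth_tsv`
#'   returns the tibble.
#' @export
write_truth_tsv <- function(truth, path) {
  readr::write_tsv(truth, path)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
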