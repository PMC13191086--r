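#' Simulate per-fraction element counts with negative-binomial noise
#'
#' The count-level core of the read simulator. For each sample, the expected
#' count of element *i* is `depth * p_i`, where `p_i` is the element's base
#' abundance tilted by `2^(+log2_enrichment/2)` in nuclear samples and
#' `2^(-log2_enrichment/2)` in cytoplasmic samples, normalised over the
#' library. The symmetric split keeps the marginal library composition
#' class-independent, and the expected nuclear:cytoplasmic CPM log-ratio of
#' each element equals its planted `log2_enrichment`. Counts are drawn
#' negative-binomial with variance `mu + dispersion * mu^2`
#' (`dispersion = 0` degenerates to Poisson).
#'
#' @param truth Ground-truth tibble (`element`, `base_abundance`,
#'   `log2_enrichment`), e.g. from [sim_kmer_truth()].
#' @param samples Sample sheet from [fraction_samples()].
#' @param dispersion Negative-binomial dispersion `alpha` (>= 0). The
#'   default 0.02 reflects the tight biological replication of deep
#'   amplicon sequencing of a transfected plasmid library.
#' @param seed Integer seed.
#' @return Count tibble: `element` column plus one integer column per
#'   sample; attribute `samples` carries the sample sheet.
#' @examples
#' truth <- sim_kmer_truth(10, 5, 1, seed = 1)
#' ct <- sim_fraction_counts(truth, fraction_samples(3, depth = 1e5), seed = 1)
#' @export
sim_fraction_counts <- function(truth, samples, dispersion = 0.02, seed = 1L) {
  if (nrow(truth) == 0L) abort("truth table is empty")
  if (!is.numeric(dispersion) || dispersion < 0) {
    abort("dispersion must be >= 0")
  }
  seed <- check_scalar_int(seed, "seed")
  withr::local_seed(seed)
  out <- tibble(element = truth$element)
  for (j in seq_len(nrow(samples))) {
    sgn <- if (samples$fraction[j] == "nuclear") +1 else -1
    w <- truth$base_abundance * 2^(sgn * truth$log2_enrichment / 2)
    mu <- samples$depth[j] * w / sum(w)
    out[[samples$sample[j]]] <- rnb_counts(mu, dispersion)
  }
  attr(out, "samples") <- samples
  out
}

# NB draw with variance mu + alpha*mu^2; alpha = 0 is Poisson
rnb_counts <- function(mu, alpha) {
  if (alpha < 1e-12) {
    rpois(length(mu), mu)
  } else {
    rnbinom(length(mu), mu = mu, size = 1 / alpha)
  }
}
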