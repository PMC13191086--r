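#' Simulate knockdown / control fraction count matrices
#'
#' Gene-level nuclear and cytoplasmic counts for a control and a knockdown
#' condition. Each gene's control nuclear:cytoplasmic log2 ratio is drawn
#' from a centred normal; in the knockdown, `n_shift_nuc` genes have that
#' ratio shifted by `+delta_log2` (shift to nuclear) and `n_shift_cyto` by
#' `-delta_log2`. Counts are negative-binomial at the stated dispersion,
#' with the ratio split symmetrically across the two fractions.
#'
#' @param n_genes Number of genes.
#' @param n_shift_nuc,n_shift_cyto Planted shifted genes per direction.
#' @param delta_log2 Planted knockdown shift in log2 units.
#' @param replicates Replicates per fraction per condition (>= 2; the
#'   downstream t-test needs at least two).
#' @param dispersion Negative-binomial dispersion.
#' @param depth Reads per sample; default gives a mean of ~500 counts/gene.
#' @param lfc_sd Standard deviation of the control log2 ratios.
#' @param seed Integer seed.
#' @return List with `control` and `kd` count tibbles (gene `element`
#'   column plus `condition_fraction_replicate` sample columns) and `truth`
#'   (`gene_id`, `lfc_control_true`, `delta_true`, `shift_true`).
#' @export
sim_kd_counts <- function(n_genes, n_shift_nuc, n_shift_cyto, delta_log2 = 2,
                          replicates = 3L, dispersion = 0.05, depth = NULL,
                          lfc_sd = 0.5, seed = 1L) {
  n_genes <- check_scalar_int(n_genes, "n_genes", min = 1)
  n_shift_nuc <- check_scalar_int(n_shift_nuc, "n_shift_nuc", min = 0)
  n_shift_cyto <- check_scalar_int(n_shift_cyto, "n_shift_cyto", min = 0)
  if (n_shift_nuc + n_shift_cyto > n_genes) {
    abort("n_shift_nuc + n_shift_cyto must be <= n_genes")
  }
  replicates <- check_scalar_int(replicates, "replicates", min = 2)
  seed <- check_scalar_int(seed, "seed")
  if (is.null(depth)) depth <- 500 * n_genes
  withr::local_seed(seed)
  genes <- sprintf("gene_%05d", seq_len(n_genes))
  abundance <- rlnorm(n_genes, 0, 1)
  lfc0 <- rnorm(n_genes, 0, lfc_sd)
  delta <- numeric(n_genes)
  planted <- sample.int(n_genes, n_shift_nuc + n_shift_cyto)
  if (delta_log2 != 0) {
    delta[planted[seq_len(n_shift_nuc)]] <- delta_log2
    if (n_shift_cyto > 0L) {
      delta[planted[n_shift_nuc + seq_len(n_shift_cyto)]] <- -delta_log2
    }
  }
  shift_true <- dplyr::case_when(
    delta > 0 ~ "to_nuclear",
    delta < 0 ~ "to_cytoplasm",
    TRUE ~ "none"
  )
  make_condition <- function(condition, lfc) {
    samples <- fraction_samples(replicates, depth = depth, condition = condition)
    out <- tibble(element = genes)
    for (j in seq_len(nrow(samples))) {
      sgn <- if (samples$fraction[j] == "nuclear") +1 else -1
      w <- abundance * 2^(sgn * lfc / 2)
      mu <- samples$depth[j] * w / sum(w)
      out[[samples$sample[j]]] <- rnb_counts(mu, dispersion)
    }
    attr(out, "samples") <- samples
    out
  }
  list(
    control = make_condition("control", lfc0),
    kd = make_condition("kd", lfc0 + delta),
    truth = tibble(gene_id = genes, lfc_control_true = lfc0,
                   delta_true = delta, shift_true = shift_true)
  )
}
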