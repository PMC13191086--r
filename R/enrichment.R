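#' Counts-per-million normalization
#'
#' Scales each sample column by its total count so columns sum to 1e6.
#'
#' @param ct Count tibble (`element` plus sample columns).
#' @return Tibble of the same shape with CPM values.
#' @export
cpm_normalize <- function(ct) {
  out <- ct
  for (s in sample_cols(ct)) {
    tot <- sum(ct[[s]])
    if (tot <= 0) abort(sprintf("sample %s has zero total count", s))
    out[[s]] <- ct[[s]] * 1e6 / tot
  }
  out
}

#' Nuclear retention score
#'
#' The NRS of an element is the log2 ratio of its nuclear to cytoplasmic
#' counts per million, with a pseudocount guarding zeros:
#' `log2((cpm_nuc + c) / (cpm_cyt + c))`. Positive values indicate nuclear
#' retention, negative values nuclear export.
#'
#' @param cpm_nuc,cpm_cyt Mean CPM per fraction (vectors).
#' @param pseudocount Pseudocount `c` in CPM units (default 0.5).
#' @return Numeric vector of NRS values.
#' @examples
#' compute_nrs(200, 100, pseudocount = 0)
#' @export
compute_nrs <- function(cpm_nuc, cpm_cyt, pseudocount = 0.5) {
  stopifnot(all(cpm_nuc >= 0), all(cpm_cyt >= 0), pseudocount >= 0)
  log2((cpm_nuc + pseudocount) / (cpm_cyt + pseudocount))
}

#' Enrichment-calling configuration
#'
#' Thresholds follow the screen's published rule: an element is
#' nuclear-enriched when `NRS >= 0.58` with `p < 0.05`, and
#' cytoplasm-enriched when `NRS <= -0.58` with `p < 0.05` (0.58 is
#' log2(1.5) truncated to two decimals). The p-value threshold applies to
#' the raw Wald p by default; `use_adjusted_p` switches to the BH-adjusted
#' value.
#'
#' @param nrs_cut NRS magnitude threshold (boundary-inclusive).
#' @param p_cut P-value threshold (strict).
#' @param pseudocount CPM pseudocount for the NRS (the test itself uses the
#'   NB model, not the pseudocount).
#' @param use_adjusted_p Classify on BH-adjusted p-values instead of raw.
#' @param nrs_aggregate `"mean_cpm"` (average replicate CPMs per fraction,
#'   then one ratio) or `"per_replicate"` (ratio per replicate pair, then
#'   average).
#' @return A list of class `test_config`.
#' @export
test_config <- function(nrs_cut = 0.58, p_cut = 0.05, pseudocount = 0.5,
                        use_adjusted_p = FALSE,
                        nrs_aggregate = c("mean_cpm", "per_replicate")) {
  stopifnot(nrs_cut > 0, p_cut > 0, p_cut < 1, pseudocount >= 0)
  structure(
    list(nrs_cut = nrs_cut, p_cut = p_cut, pseudocount = pseudocount,
         use_adjusted_p = use_adjusted_p,
         nrs_aggregate = match.arg(nrs_aggregate)),
    class = "test_config"
  )
}

#' Negative-binomial Wald test of nuclear vs cytoplasmic counts
#'
#' Differential-abundance test across replicates, in the style of NB count
#' models for sequencing data: (i) sample size factors by median-of-ratios
#' against the geometric-mean pseudo-reference (elements with any zero
#' count are excluded from the reference); (ii) per-element dispersion by
#' method of moments on normalized counts, floored at 1e-8; (iii) log2
#' fold change (nuclear over cytoplasmic) from normalized group means with
#' a pseudocount; (iv) Wald statistic `log2FC / SE`, with the SE obtained
#' from the NB variance model `mu + alpha*mu^2` via the delta method;
#' (v) a two-sided p-value; (vi) Benjamini-Hochberg adjustment over all
#' elements as one family.
#'
#' Because the per-element dispersion is estimated from few replicates
#' without shrinkage, the Wald statistic is referred to a t distribution
#' with `n - 2` degrees of freedom rather than a normal: with triplicate
#' designs the normal reference is strongly anticonservative, while the t
#' reference keeps the type-I error at its nominal level (see the methods
#' vignette).
#'
#' @param ct Count tibble with >= 2 replicates per fraction.
#' @param pseudocount Pseudocount (normalized-count units) in the fold
#'   change.
#' @param dispersion_floor Lower bound for the dispersion estimate.
#' @return Tibble: `element`, `base_mean`, `log2fc_test`, `se`,
#'   `wald_stat`, `p_value`, `p_adjusted`, `dispersion`.
#' @export
nb_wald_test <- function(ct, pseudocount = 0.5, dispersion_floor = 1e-8) {
  nuc <- fraction_cols(ct, "nuclear")
  cyt <- fraction_cols(ct, "cytoplasmic")
  if (length(nuc) < 2L || length(cyt) < 2L) {
    abort("nb_wald_test needs at least 2 replicates per fraction")
  }
  K <- as.matrix(ct[, c(nuc, cyt), drop = FALSE])
  sf <- size_factors(K)
  Kn <- sweep(K, 2L, sf, "/")
  i1 <- seq_along(nuc)
  i2 <- length(nuc) + seq_along(cyt)
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(Kn[, i1, drop = FALSE])
  m2 <- rowMeans(Kn[, i2, drop = FALSE])
  v1 <- matrixStats_rowVars(Kn[, i1, drop = FALSE])
  v2 <- matrixStats_rowVars(Kn[, i2, drop = FALSE])
  w <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
  mbar <- rowMeans(Kn)
  xi <- mean(1 / sf)
  disp <- pmax((w - mbar * xi) / mbar^2, dispersion_floor)
  disp[!is.finite(disp)] <- dispersion_floor
  lfc <- log2((m1 + pseudocount) / (m2 + pseudocount))
  var_m1 <- m1 * mean(1 / sf[i1]) / n1 + disp * m1^2 / n1
  var_m2 <- m2 * mean(1 / sf[i2]) / n2 + disp * m2^2 / n2
  se <- sqrt(var_m1 / (m1 + pseudocount)^2 + var_m2 / (m2 + pseudocount)^2) /
    log(2)
  wald <- if_else(se > 0, lfc / se, 0)
  p <- 2 * pt(-abs(wald), df = n1 + n2 - 2L)
  p[se == 0] <- 1
  tibble(
    element = ct$element, base_mean = mbar, log2fc_test = lfc, se = se,
    wald_stat = wald, p_value = p,
    p_adjusted = p.adjust(p, method = "BH"), dispersion = disp
  )
}

#' Median-of-ratios size factors
#'
#' @param K Integer count matrix (elements x samples).
#' @return Numeric vector of per-sample size factors.
#' @export
size_factors <- function(K) {
  keep <- rowSums(K == 0) == 0L
  if (!any(keep)) {
    abort("no element has all-positive counts; cannot form the pseudo-reference")
  }
  logref <- rowMeans(log(K[keep, , drop = FALSE]))
  apply(K[keep, , drop = FALSE], 2L, function(col) {
    exp(median(log(col) - logref))
  })
}

matrixStats_rowVars <- function(M) {
  n <- ncol(M)
  mu <- rowMeans(M)
  rowSums((M - mu)^2) / (n - 1L)
}

#' Classify elements as nuclear- or cytoplasm-enriched
#'
#' Nuclear iff `nrs >= nrs_cut` and `p < p_cut`; cytoplasmic iff
#' `nrs <= -nrs_cut` and `p < p_cut`; else neutral. Boundary inclusivity is
#' exactly as stated: inclusive on the NRS cut, strict on the p-value.
#'
#' @param records Tibble carrying `nrs` and `p_value` (and `p_adjusted`).
#' @param config A [test_config()].
#' @return `records` with a `class` column.
#' @export
classify_elements <- function(records, config = test_config()) {
  p <- if (isTRUE(config$use_adjusted_p)) records$p_adjusted else records$p_value
  mutate(records, class = dplyr::case_when(
    records$nrs >= config$nrs_cut & p < config$p_cut ~ "nuclear",
    records$nrs <= -config$nrs_cut & p < config$p_cut ~ "cytoplasmic",
    TRUE ~ "neutral"
  ))
}

#' Score a count table: CPM, NRS, NB Wald test, and enrichment class
#'
#' The main per-element scoring pipeline: CPM-normalize, average replicate
#' CPMs per fraction, compute the NRS, run [nb_wald_test()], and classify
#' with the configured thresholds.
#'
#' @param ct Count tibble with >= 2 replicates per fraction.
#' @param config A [test_config()].
#' @return Tibble: `element`, `cpm_nuclear`, `cpm_cytoplasmic`, `nrs`,
#'   `log2fc_test`, `wald_stat`, `p_value`, `p_adjusted`, `class`;
#'   attribute `config`.
#' @examples
#' truth <- sim_kmer_truth(20, 10, 1, seed = 1)
#' ct <- sim_fraction_counts(truth, fraction_samples(3, 2e5), seed = 2)
#' head(score_elements(ct))
#' @export
score_elements <- function(ct, config = test_config()) {
  cpmt <- cpm_normalize(ct)
  nuc <- fraction_cols(ct, "nuclear")
  cyt <- fraction_cols(ct, "cytoplasmic")
  cpm_nuc <- rowMeans(as.matrix(cpmt[, nuc, drop = FALSE]))
  cpm_cyt <- rowMeans(as.matrix(cpmt[, cyt, drop = FALSE]))
  if (config$nrs_aggregate == "mean_cpm") {
    nrs <- compute_nrs(cpm_nuc, cpm_cyt, config$pseudocount)
  } else {
    info <- parse_sample_names(c(nuc, cyt))
    reps <- sort(intersect(info$replicate[info$fraction == "nuclear"],
                           info$replicate[info$fraction == "cytoplasmic"]))
    ratios <- vapply(reps, function(r) {
      cn <- info$sample[info$fraction == "nuclear" & info$replicate == r]
      cc <- info$sample[info$fraction == "cytoplasmic" & info$replicate == r]
      compute_nrs(cpmt[[cn]], cpmt[[cc]], config$pseudocount)
    }, numeric(nrow(ct)))
    nrs <- rowMeans(ratios)
  }
  test <- nb_wald_test(ct)
  out <- tibble(
    element = ct$element,
    cpm_nuclear = cpm_nuc, cpm_cytoplasmic = cpm_cyt, nrs = nrs
  ) %>%
    left_join(select(test, "element", "log2fc_test", "wald_stat",
                     "p_value", "p_adjusted"), by = "element") %>%
    classify_elements(config)
  attr(out, "config") <- config
  out
}

#' Base-composition contrast between two element sets
#'
#' Pools base counts within each set and tests each base with a 2x2 Fisher
#' exact test (base vs not-base, set A vs set B). Used to contrast
#' nuclear-enriched against cytoplasm-enriched elements, where
#' nuclear-retained 6-mers are expected to be GC-rich and exported ones
#' AT-rich.
#'
#' @param set_a,set_b Non-empty character vectors of equal-length
#'   sequences.
#' @return Tibble with one row per base: `base`, `count_a`, `count_b`,
#'   `freq_a`, `freq_b`, `diff` (freq_a - freq_b), `p_value`; attributes
#'   `gc_a`, `gc_b` give the GC fraction of each set.
#' @export
composition_contrast <- function(set_a, set_b) {
  if (length(set_a) == 0L || length(set_b) == 0L) {
    abort("both sets must be non-empty")
  }
  len <- unique(nchar(c(set_a, set_b)))
  if (length(len) != 1L) abort("all elements must have equal length")
  bases <- c("A", "C", "G", "T")
  count_bases <- function(set) {
    vapply(bases, function(b) {
      sum(stringi::stri_count_fixed(set, b))
    }, numeric(1))
  }
  ca <- count_bases(set_a)
  cb <- count_bases(set_b)
  ta <- sum(ca); tb <- sum(cb)
  p <- vapply(bases, function(b) {
    fisher.test(matrix(c(ca[b], ta - ca[b], cb[b], tb - cb[b]), 2L))$p.value
  }, numeric(1))
  out <- tibble(
    base = bases, count_a = unname(ca), count_b = unname(cb),
    freq_a = unname(ca / ta), freq_b = unname(cb / tb),
    diff = unname(ca / ta - cb / tb), p_value = unname(p)
  )
  attr(out, "gc_a") <- unname((ca["G"] + ca["C"]) / ta)
  attr(out, "gc_b") <- unname((cb["G"] + cb["C"]) / tb)
  out
}

#' Write / read a per-element NRS table as TSV
#'
#' Run parameters are echoed as `#` header lines.
#'
#' @param records Scored tibble from [score_elements()].
#' @param path File path.
#' @param config The [test_config()] used (defaults to the one attached to
#'   `records`).
#' @return `write_nrs_table` returns `path` invisibly.
#' @export
write_nrs_table <- function(records, path, config = attr(records, "config")) {
  hdr <- character()
  if (!is.null(config)) {
    hdr <- sprintf("# %s=%s",
                   c("nrs_cut", "p_cut", "pseudocount", "use_adjusted_p",
                     "nrs_aggregate"),
                   c(config$nrs_cut, config$p_cut, config$pseudocount,
                     config$use_adjusted_p, config$nrs_aggregate))
  }
  writeLines(hdr, path)
  readr::write_tsv(records, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_nrs_table
#' @export
read_nrs_table <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}
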