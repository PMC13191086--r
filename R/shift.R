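#' Knockdown-induced shift in subcellular distribution
#'
#' For each gene, the nuclear:cytoplasmic log2 ratio is formed per
#' replicate (CPM within each sample, nuclear and cytoplasmic samples
#' paired by replicate index), averaged per condition, and the change on
#' knockdown is `delta = lfc_kd - lfc_ctrl`. A two-sample two-sided
#' Student t-test (equal variance by default) compares the per-replicate
#' ratios between conditions. Shift classes follow the published strict
#' thresholds: shift to nuclear when `delta > delta_cut` with
#' `p < p_cut`, shift to cytoplasm when `delta < -delta_cut` with
#' `p < p_cut`, otherwise none.
#'
#' @param ctrl,kd Count tibbles (`element` = gene id plus
#'   `condition_fraction_replicate` or `fraction_replicate` sample
#'   columns), aligned on genes, >= 2 replicates per fraction each.
#' @param delta_cut Threshold on `delta` (strict inequality).
#' @param p_cut P-value threshold (strict).
#' @param pseudocount CPM pseudocount in the per-replicate ratios.
#' @param pairing `"by_replicate"` pairs fractions by replicate index;
#'   `"all_pairs"` forms ratios for every nuclear x cytoplasmic replicate
#'   combination.
#' @param var_equal Equal-variance Student t-test (default); `FALSE` for
#'   Welch.
#' @return Tibble: `gene_id`, `lfc_ctrl`, `lfc_kd`, `delta`, `t_stat`,
#'   `p_value`, `shift_class`.
#' @export
shift_test <- function(ctrl, kd, delta_cut = 0.58, p_cut = 0.05,
                       pseudocount = 0.5,
                       pairing = c("by_replicate", "all_pairs"),
                       var_equal = TRUE) {
  pairing <- match.arg(pairing)
  if (!identical(ctrl$element, kd$element)) {
    off <- union(setdiff(ctrl$element, kd$element),
                 setdiff(kd$element, ctrl$element))
    if (length(off) > 0L) {
      abort(sprintf("gene sets differ between conditions: %s%s",
                    paste(head(off, 5L), collapse = ", "),
                    if (length(off) > 5L) ", ..." else ""))
    }
    abort("genes must be in the same order in both conditions")
  }
  rc <- replicate_ratios(ctrl, pseudocount, pairing)
  rk <- replicate_ratios(kd, pseudocount, pairing)
  n1 <- ncol(rc); n2 <- ncol(rk)
  if (n1 < 2L || n2 < 2L) abort("need >= 2 replicates per fraction per condition")
  m1 <- rowMeans(rc); m2 <- rowMeans(rk)
  v1 <- matrixStats_rowVars(rc); v2 <- matrixStats_rowVars(rk)
  if (var_equal) {
    sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2L, length(m1))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  }
  tstat <- if_else(se > 0, (m2 - m1) / se, 0)
  p <- 2 * pt(-abs(tstat), df = df)
  p[se == 0] <- 1
  delta <- m2 - m1
  tibble(
    gene_id = ctrl$element,
    lfc_ctrl = m1, lfc_kd = m2, delta = delta,
    t_stat = tstat, p_value = p,
    shift_class = dplyr::case_when(
      delta > delta_cut & p < p_cut ~ "to_nuclear",
      delta < -delta_cut & p < p_cut ~ "to_cytoplasm",
      TRUE ~ "none"
    )
  )
}

# per-gene log2 nuclear:cytoplasmic CPM ratio, one column per replicate pair
replicate_ratios <- function(ct, pseudocount, pairing) {
  cpmt <- cpm_normalize(ct)
  info <- parse_sample_names(sample_cols(ct))
  nuc <- filter(info, .data$fraction == "nuclear") %>% arrange(.data$replicate)
  cyt <- filter(info, .data$fraction == "cytoplasmic") %>% arrange(.data$replicate)
  pairs <- if (pairing == "by_replicate") {
    shared <- intersect(nuc$replicate, cyt$replicate)
    tibble(n = nuc$sample[match(shared, nuc$replicate)],
           c = cyt$sample[match(shared, cyt$replicate)])
  } else {
    tidyr::expand_grid(n = nuc$sample, c = cyt$sample)
  }
  out <- vapply(seq_len(nrow(pairs)), function(k) {
    compute_nrs(cpmt[[pairs$n[k]]], cpmt[[pairs$c[k]]], pseudocount)
  }, numeric(nrow(ct)))
  matrix(out, nrow = nrow(ct))
}

#' Volcano table with 2-D density grid
#'
#' Plotting data for a knockdown shift volcano: one point per gene
#' (`delta`, `-log10 p`, class) plus binned 2-D counts over the plane.
#'
#' @param records Tibble from [shift_test()].
#' @param bins Number of bins per axis.
#' @return Tibble of points (`delta`, `neg_log10_p`, `shift_class`,
#'   `density`), with the full grid in attribute `grid` (`delta_mid`,
#'   `p_mid`, `n`).
#' @export
volcano_table <- function(records, bins = 50L) {
  if (nrow(records) == 0L) {
    out <- tibble(delta = numeric(), neg_log10_p = numeric(),
                  shift_class = character(), density = integer())
    attr(out, "grid") <- tibble(delta_mid = numeric(), p_mid = numeric(),
                                n = integer())
    return(out)
  }
  pts <- tibble(delta = records$delta,
                neg_log10_p = -log10(pmax(records$p_value, 1e-300)),
                shift_class = records$shift_class)
  brx <- seq(min(pts$delta), max(pts$delta), length.out = bins + 1L)
  bry <- seq(min(pts$neg_log10_p), max(pts$neg_log10_p), length.out = bins + 1L)
  ix <- findInterval(pts$delta, brx, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(pts$neg_log10_p, bry, rightmost.closed = TRUE,
                     all.inside = TRUE)
  grid <- count(tibble(ix = ix, iy = iy), .data$ix, .data$iy) %>%
    mutate(delta_mid = (brx[.data$ix] + brx[.data$ix + 1L]) / 2,
           p_mid = (bry[.data$iy] + bry[.data$iy + 1L]) / 2) %>%
    select("delta_mid", "p_mid", "n")
  dens <- count(tibble(ix = ix, iy = iy), .data$ix, .data$iy, name = "density")
  pts <- left_join(mutate(pts, ix = ix, iy = iy), dens,
                   by = c("ix", "iy")) %>%
    select(-"ix", -"iy")
  attr(pts, "grid") <- grid
  pts
}
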