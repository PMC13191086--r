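# shared fixtures and independent oracles, built in code at test time

# a flat NRS table: every 6-mer scores 0 except those listed
nrs_table_with <- function(nuclear = character(), cytoplasmic = character(),
                           effect = 1) {
  tab <- tibble::tibble(element = all_kmers(6L), nrs = 0)
  tab$nrs[tab$element %in% nuclear] <- effect
  tab$nrs[tab$element %in% cytoplasmic] <- -effect
  tab
}

# shift-closed 6-mer families: consecutive windows of a (CG)n / (AT)n run
# are all inside the family, so clustered plantings form contiguous
# high-score regions
cg_family <- c("CGCGCG", "GCGCGC")
at_family <- c("ATATAT", "TATATA")

# interval Jaccard for 0-based half-open intervals
jaccard <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2))
  inter / ((e1 - s1) + (e2 - s2) - inter)
}

# brute-force per-nucleotide window average (independent of the package's
# cumulative-sum implementation)
brute_window_average <- function(raw, L) {
  vapply(seq_len(L), function(p) {
    js <- Filter(function(j) j <= p && p <= j + 5L, seq_len(L - 5L))
    mean(raw[js])
  }, numeric(1))
}

# brute-force threshold-run caller: scan positions, collect maximal runs,
# merge gaps <= max_gap unless a forbidden position intervenes, drop short
brute_runs <- function(mask, max_gap, min_len, forbid = rep(FALSE, length(mask))) {
  runs <- list()
  i <- 1L
  n <- length(mask)
  while (i <= n) {
    if (mask[i]) {
      j <- i
      while (j < n && mask[j + 1L]) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(runs) == 0L) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  merged <- list(runs[[1L]])
  for (r in runs[-1L]) {
    last <- merged[[length(merged)]]
    gap <- r[1L] - last[2L] - 1L
    gap_pos <- if (gap > 0L) (last[2L] + 1L):(r[1L] - 1L) else integer()
    if (gap <= max_gap && !any(forbid[gap_pos])) {
      merged[[length(merged)]] <- c(last[1L], r[2L])
    } else {
      merged[[length(merged) + 1L]] <- r
    }
  }
  keep <- Filter(function(r) r[2L] - r[1L] + 1L >= min_len, merged)
  tibble::tibble(start = vapply(keep, `[[`, integer(1), 1L) - 1L,
                 end = vapply(keep, `[[`, integer(1), 2L))
}

# pairwise-concordance AUROC oracle: P(score_pos > score_neg) + 0.5 ties
concordance_auroc <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}
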