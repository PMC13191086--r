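#' Reverse-complement nucleotide strings
#'
#' Vectorised reverse complement over the DNA alphabet (A/C/G/T, with N
#' preserved).
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of the same length.
#' @examples
#' revcomp(c("ACGT", "AANTT"))
#' @export
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", stringi::stri_reverse(x))
}

#' Enumerate all k-mers over A/C/G/T
#'
#' @param k Word length.
#' @return Character vector of length `4^k`, in lexicographic order.
#' @examples
#' length(all_kmers(3))
#' @export
all_kmers <- function(k) {
  stopifnot(is.numeric(k), k >= 1, k <= 12)
  bases <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid, c(rep(list(bases), k), stringsAsFactors = FALSE))
  # expand.grid varies the first factor fastest; reverse for lexicographic order
  sort(do.call(paste0, grid[, rev(seq_len(k)), drop = FALSE]))
}

# uniform integer draws in [lo, hi]; safe when lo == hi (unlike sample())
sample_range <- function(lo, hi, n = 1L) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

check_acgt <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    abort(sprintf("%s must contain only A/C/G/T (offender: %s)",
                  what, x[which(bad)[1L]]))
  }
  invisible(x)
}

check_scalar_int <- function(x, name, min = NULL) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x)) {
    abort(sprintf("`%s` must be a single integer", name))
  }
  if (!is.null(min) && x < min) {
    abort(sprintf("`%s` must be >= %s", name, min))
  }
  invisible(as.integer(x))
}

#' Maximal runs of TRUE positions with gap merging
#'
#' Finds maximal runs of `TRUE` in a logical mask, merges consecutive runs
#' separated by at most `max_gap` positions, then drops merged runs shorter
#' than `min_len`. Optionally a `forbid` mask marks positions a merge may
#' never bridge (used to keep intervals of opposite sign from overlapping).
#'
#' @param mask Logical vector.
#' @param max_gap Maximum gap (in positions) bridged when merging runs.
#' @param min_len Minimum interval length kept.
#' @param forbid Optional logical vector; gaps containing a `TRUE` position
#'   are never merged across.
#' @return Tibble with `start`, `end` (0-based, half-open).
#' @keywords internal
mask_runs <- function(mask, max_gap = 0L, min_len = 1L, forbid = NULL) {
  empty <- tibble(start = integer(), end = integer())
  if (length(mask) == 0L || !any(mask)) return(empty)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run_s <- starts[r$values]
  run_e <- ends[r$values]
  # merge runs across small gaps
  ms <- run_s[1L]
  me <- run_e[1L]
  out_s <- integer()
  out_e <- integer()
  if (length(run_s) > 1L) {
    for (i in seq(2L, length(run_s))) {
      gap_lo <- me + 1L
      gap_hi <- run_s[i] - 1L
      gap <- run_s[i] - me - 1L
      blocked <- !is.null(forbid) && gap > 0L && any(forbid[gap_lo:gap_hi])
      if (gap <= max_gap && !blocked) {
        me <- run_e[i]
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- run_s[i]; me <- run_e[i]
      }
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  keep <- (out_e - out_s + 1L) >= min_len
  tibble(start = out_s[keep] - 1L, end = out_e[keep])
}

#' Parse `fraction_replicate` style sample names
#'
#' Sample columns are named `fraction_replicate` (e.g. `nuclear_1`) or
#' `condition_fraction_replicate` (e.g. `control_nuclear_2`).
#'
#' @param x Character vector of sample names.
#' @return Tibble with `sample`, `condition` (NA when absent), `fraction`,
#'   `replicate`.
#' @export
parse_sample_names <- function(x) {
  parts <- strsplit(x, "_", fixed = TRUE)
  bad <- lengths(parts) < 2L | lengths(parts) > 3L
  if (any(bad)) {
    abort(sprintf(
      "sample name %s is not of the form [condition_]fraction_replicate",
      x[which(bad)[1L]]))
  }
  out <- purrr::map2_dfr(parts, x, function(p, nm) {
    if (length(p) == 2L) {
      tibble(sample = nm, condition = NA_character_,
             fraction = p[1L], replicate = suppressWarnings(as.integer(p[2L])))
    } else {
      tibble(sample = nm, condition = p[1L],
             fraction = p[2L], replicate = suppressWarnings(as.integer(p[3L])))
    }
  })
  if (any(is.na(out$replicate)) ||
      !all(out$fraction %in% c("nuclear", "cytoplasmic"))) {
    abort("sample names must use fractions 'nuclear'/'cytoplasmic' and integer replicates")
  }
  out
}

sample_cols <- function(ct) setdiff(names(ct), "element")

fraction_cols <- function(ct, fraction) {
  info <- parse_sample_names(sample_cols(ct))
  info$sample[info$fraction == fraction]
}
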