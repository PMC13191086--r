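#' Assign 6-mer NRS values along a transcript by sliding window
#'
#' Every 6-nt window (1-nt step) receives the NRS of its 6-mer, giving the
#' raw vector of length `L - 5` (window-start indexed). The averaged
#' vector assigns each nucleotide the mean NRS over all windows covering
#' it (positions near the ends average only the existing windows, no
#' padding). Windows containing a non-A/C/G/T character score 0 and are
#' flagged in the mask.
#'
#' @param sequence Transcript sequence (>= 6 nt).
#' @param nrs_table NRS lookup: tibble with `element` and `nrs`, or a
#'   named numeric vector covering all 4,096 6-mers.
#' @param transcript_id Identifier stored in the profile.
#' @return An object of class `nrs_profile`: list with `transcript_id`,
#'   `sequence`, `raw` (length L-5), `averaged` (length L), `mask`
#'   (valid-window flags, length L-5).
#' @examples
#' tab <- tibble::tibble(element = all_kmers(6), nrs = 0)
#' p <- assign_nrs("ACGTACGTACGT", tab)
#' length(p$raw)
#' @export
assign_nrs <- function(sequence, nrs_table, transcript_id = "transcript") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  L <- nchar(sequence)
  if (L < 6L) abort("sequence must be at least 6 nt")
  v <- as_nrs_vector(nrs_table)
  win <- substring(sequence, seq_len(L - 5L), seq_len(L - 5L) + 5L)
  raw <- unname(v[win])
  mask <- !is.na(raw)
  invalid_window <- grepl("[^ACGT]", win)
  if (any(!mask & !invalid_window)) {
    abort(sprintf("NRS table is missing 6-mer %s",
                  win[which(!mask & !invalid_window)[1L]]))
  }
  raw[!mask] <- 0
  structure(
    list(transcript_id = transcript_id, sequence = sequence,
         raw = raw, averaged = window_average(raw, L), mask = mask),
    class = "nrs_profile"
  )
}

# per-nucleotide mean over covering 6-nt windows, cumulative-sum based
window_average <- function(raw, L) {
  s <- c(0, cumsum(raw))
  p <- seq_len(L)
  lo <- pmax(1L, p - 5L)
  hi <- pmin(p, L - 5L)
  (s[hi + 1L] - s[lo]) / (hi - lo + 1L)
}

as_nrs_vector <- function(nrs_table) {
  if (is.numeric(nrs_table) && !is.null(names(nrs_table))) return(nrs_table)
  if (is.data.frame(nrs_table) && all(c("element", "nrs") %in% names(nrs_table))) {
    return(setNames(nrs_table$nrs, nrs_table$element))
  }
  abort("nrs_table must be a named numeric vector or a tibble with element/nrs")
}

#' @export
print.nrs_profile <- function(x, ...) {
  cat(sprintf("<nrs_profile> %s: %d nt, raw NRS in [%.2f, %.2f]\n",
              x$transcript_id, nchar(x$sequence), min(x$raw), max(x$raw)))
  invisible(x)
}

#' @export
as_tibble.nrs_profile <- function(x, ...) {
  tibble(transcript_id = x$transcript_id,
         pos = seq_len(nchar(x$sequence)) - 1L,
         averaged = x$averaged)
}

#' Profiles for a set of transcripts
#'
#' @param transcripts Tibble with `transcript_id` and `sequence`.
#' @param nrs_table NRS lookup (see [assign_nrs()]).
#' @return Named list of `nrs_profile` objects.
#' @export
assign_nrs_all <- function(transcripts, nrs_table) {
  v <- as_nrs_vector(nrs_table)
  out <- purrr::map2(transcripts$sequence, transcripts$transcript_id,
                     function(s, id) assign_nrs(s, v, id))
  setNames(out, transcripts$transcript_id)
}

#' Randomize an NRS table
#'
#' Permutes the NRS values among the 6-mers: the value multiset (hence the
#' score distribution) is preserved while the sequence-to-score map is
#' destroyed. Used as the matched negative control for NRS-guided
#' analyses.
#'
#' @param nrs_table Tibble with `element`, `nrs`.
#' @param seed Integer seed.
#' @return Tibble of the same shape with permuted `nrs`.
#' @export
randomize_nrs <- function(nrs_table, seed = 1L) {
  seed <- check_scalar_int(seed, "seed")
  withr::local_seed(seed)
  mutate(nrs_table, nrs = sample(.data$nrs))
}

#' Call NRS peaks on a transcript profile
#'
#' Maximal runs of the averaged per-nucleotide NRS at or above `nrs_cut`
#' (nuclear) or at or below `-nrs_cut` (cytoplasmic). Same-class runs
#' separated by at most `max_gap` nt are merged (never across a position
#' qualifying for the opposite class), and intervals shorter than
#' `min_len` are dropped, so peaks of opposite class never overlap.
#'
#' @param profile An `nrs_profile`.
#' @param nrs_cut Threshold (inclusive; default 0.5 as used for
#'   localization peaks).
#' @param min_len Minimum peak length (nt).
#' @param max_gap Maximum merged gap (nt).
#' @param on `"averaged"` (default; nucleotide coordinates) or `"raw"`
#'   (window-start coordinates).
#' @return Tibble: `transcript_id`, `start`, `end` (0-based half-open),
#'   `mean_nrs`, `class`.
#' @export
call_peaks <- function(profile, nrs_cut = 0.5, min_len = 6L, max_gap = 3L,
                       on = c("averaged", "raw")) {
  stopifnot(inherits(profile, "nrs_profile"))
  on <- match.arg(on)
  v <- profile[[on]]
  masks <- list(nuclear = v >= nrs_cut, cytoplasmic = v <= -nrs_cut)
  out <- purrr::map_dfr(names(masks), function(cl) {
    other <- setdiff(names(masks), cl)
    runs <- mask_runs(masks[[cl]], max_gap = max_gap, min_len = min_len,
                      forbid = masks[[other]])
    if (nrow(runs) == 0L) return(empty_peaks())
    mutate(runs,
           transcript_id = profile$transcript_id, class = cl,
           mean_nrs = purrr::map2_dbl(.data$start, .data$end,
                                      ~ mean(v[(.x + 1L):.y]))) %>%
      select("transcript_id", "start", "end", "mean_nrs", "class")
  })
  if (nrow(out) == 0L) empty_peaks() else arrange(out, .data$start)
}

empty_peaks <- function() {
  tibble(transcript_id = character(), start = integer(), end = integer(),
         mean_nrs = numeric(), class = character())
}

#' @rdname call_peaks
#' @param profiles Named list of `nrs_profile` objects.
#' @param ... Passed on to [call_peaks()].
#' @export
call_peaks_all <- function(profiles, ...) {
  out <- purrr::map_dfr(profiles, call_peaks, ...)
  if (nrow(out) == 0L) empty_peaks() else out
}

#' Metagene NRS profile around peak centers
#'
#' For each peak, the averaged-NRS values at offsets
#' `-half_window..+half_window` from the peak midpoint are collected
#' (offsets falling outside the transcript are skipped) and averaged
#' column-wise, separately per peak class.
#'
#' @param profiles Named list of `nrs_profile` objects (names =
#'   transcript ids).
#' @param peaks Peak tibble from [call_peaks_all()].
#' @param half_window Half-width of the window (nt).
#' @return Tibble: `class`, `offset`, `mean_nrs`, `n`.
#' @export
metagene <- function(profiles, peaks, half_window = 50L) {
  if (nrow(peaks) == 0L) abort("no peaks supplied")
  offs <- seq(-half_window, half_window)
  purrr::map_dfr(unique(peaks$class), function(cl) {
    pk <- filter(peaks, .data$class == cl)
    acc <- numeric(length(offs))
    cnt <- integer(length(offs))
    for (k in seq_len(nrow(pk))) {
      prof <- profiles[[pk$transcript_id[k]]]
      L <- length(prof$averaged)
      center <- (pk$start[k] + pk$end[k]) %/% 2L
      pos <- center + offs + 1L
      inb <- pos >= 1L & pos <= L
      acc[inb] <- acc[inb] + prof$averaged[pos[inb]]
      cnt[inb] <- cnt[inb] + 1L
    }
    tibble(class = cl, offset = offs,
           mean_nrs = if_else(cnt > 0L, acc / pmax(cnt, 1L), NA_real_),
           n = cnt)
  })
}

#' Peak counts by class and transcript biotype
#'
#' @param peaks Peak tibble.
#' @param biotypes Tibble with `transcript_id`, `biotype`.
#' @return Tibble: `class`, `biotype`, `n`, `pct` (percent within class).
#' @export
peak_origin_summary <- function(peaks, biotypes) {
  if (nrow(peaks) == 0L) {
    return(tibble(class = character(), biotype = character(),
                  n = integer(), pct = numeric()))
  }
  peaks %>%
    left_join(biotypes, by = "transcript_id") %>%
    count(.data$class, .data$biotype) %>%
    group_by(.data$class) %>%
    mutate(pct = 100 * .data$n / sum(.data$n)) %>%
    ungroup()
}

#' Write a transcript profile as bedGraph (transcript coordinates)
#'
#' @param profile An `nrs_profile`.
#' @param path Output path.
#' @param which `"averaged"` or `"raw"`.
#' @return `path`, invisibly.
#' @export
write_profile_bedgraph <- function(profile, path, which = c("averaged", "raw")) {
  which <- match.arg(which)
  v <- profile[[which]]
  track <- tibble(ref_id = profile$transcript_id,
                  pos = seq_along(v) - 1L, value = v)
  write_bedgraph(track, path)
}

#' Write peaks as BED6 (class in the name field)
#'
#' @param peaks Peak tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  write_regions_bed(
    rename(peaks, ref_id = "transcript_id"), path)
}

#' Extract peak sequences as FASTA (ready for motif discovery)
#'
#' @param peaks Peak tibble.
#' @param transcripts Tibble with `transcript_id`, `sequence`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_peak_fasta <- function(peaks, transcripts, path) {
  seqs <- purrr::pmap_chr(
    list(peaks$transcript_id, peaks$start, peaks$end),
    function(id, s, e) {
      substr(transcripts$sequence[transcripts$transcript_id == id][1L],
             s + 1L, e)
    })
  names(seqs) <- sprintf("%s:%d-%d:%s", peaks$transcript_id, peaks$start,
                         peaks$end, peaks$class)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
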