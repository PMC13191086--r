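#' Simulate transcripts with planted localization 6-mers
#'
#' Random-background transcripts in two labelled classes. Each
#' nuclear-labelled transcript carries `copies_per_transcript` occurrences
#' of 6-mers drawn from `planted_nuc_6mers` at random non-overlapping
#' positions; cytoplasmic transcripts symmetrically from
#' `planted_cyto_6mers`. The planted lists must be disjoint.
#'
#' @param n_per_class Transcripts per class.
#' @param len_min,len_max Transcript length range (nt).
#' @param planted_nuc_6mers,planted_cyto_6mers Character vectors of 6-mers.
#' @param copies_per_transcript Planted occurrences per transcript (0 for a
#'   null set with no signal).
#' @param placement `"random"` scatters the copies at random
#'   non-overlapping positions; `"clustered"` places them back-to-back as
#'   one contiguous block at a random position, emulating the clustering
#'   of localization elements within a discrete transcript region (as
#'   region-level screens observe) so that planted transcripts carry a
#'   contiguous high-score region rather than isolated spikes.
#' @param seed Integer seed.
#' @param dir If non-NULL, write `transcripts.fasta` and `labels.tsv` here.
#' @return Tibble with `transcript_id`, `label`, `sequence`.
#' @export
sim_transcripts <- function(n_per_class, len_min = 200L, len_max = 400L,
                            planted_nuc_6mers, planted_cyto_6mers,
                            copies_per_transcript = 10L,
                            placement = c("random", "clustered"), seed = 1L,
                            dir = NULL) {
  n_per_class <- check_scalar_int(n_per_class, "n_per_class", min = 1)
  len_min <- check_scalar_int(len_min, "len_min", min = 6)
  len_max <- check_scalar_int(len_max, "len_max", min = len_min)
  copies <- check_scalar_int(copies_per_transcript, "copies_per_transcript",
                             min = 0)
  placement <- match.arg(placement)
  seed <- check_scalar_int(seed, "seed")
  check_acgt(planted_nuc_6mers, "planted_nuc_6mers")
  check_acgt(planted_cyto_6mers, "planted_cyto_6mers")
  stopifnot(all(nchar(planted_nuc_6mers) == 6L),
            all(nchar(planted_cyto_6mers) == 6L))
  if (length(intersect(planted_nuc_6mers, planted_cyto_6mers)) > 0L) {
    abort("planted 6-mer lists must be disjoint between classes")
  }
  if (copies > 0L && len_min < 6L * copies) {
    abort("transcripts too short for the requested number of non-overlapping copies")
  }
  withr::local_seed(seed)
  make_class <- function(label, pool) {
    purrr::map_dfr(seq_len(n_per_class), function(i) {
      L <- sample_range(len_min, len_max)
      s <- stringi::stri_rand_strings(1L, L, "[ACGT]")
      if (copies > 0L) {
        kmers <- sample(pool, copies, replace = TRUE)
        pos <- if (placement == "clustered") {
          sample.int(L - 6L * copies + 1L, 1L) - 1L + 6L * (seq_len(copies) - 1L)
        } else {
          plant_positions(L, copies)
        }
        ch <- strsplit(s, "", fixed = TRUE)[[1L]]
        for (k in seq_len(copies)) {
          ch[(pos[k] + 1L):(pos[k] + 6L)] <- strsplit(kmers[k], "", fixed = TRUE)[[1L]]
        }
        s <- paste(ch, collapse = "")
      }
      tibble(transcript_id = sprintf("tx_%s_%03d", substr(label, 1, 3), i),
             label = label, sequence = s)
    })
  }
  out <- bind_rows(
    make_class("nuclear", planted_nuc_6mers),
    make_class("cytoplasmic", planted_cyto_6mers)
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    seqs <- Biostrings::DNAStringSet(setNames(out$sequence, out$transcript_id))
    Biostrings::writeXStringSet(seqs, file.path(dir, "transcripts.fasta"))
    readr::write_tsv(select(out, "transcript_id", "label"),
                     file.path(dir, "labels.tsv"))
  }
  out
}

# c non-overlapping 6-nt slots in [0, L-6]: sorted distinct draws shifted by
# 6*(rank-1) guarantee pairwise spacing >= 6
plant_positions <- function(L, c) {
  hi <- L - 6L - 6L * (c - 1L)
  x <- sort(sample.int(hi + 1L, c) - 1L)
  x + 6L * (seq_len(c) - 1L)
}
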