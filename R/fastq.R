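#' Read a FASTQ file into a character vector of reads
#'
#' Thin wrapper over Biostrings' FASTQ parser (plain or gzip). A malformed
#' record raises an error naming the file and, when it can be located, the
#' index of the first offending record.
#'
#' @param path FASTQ file path.
#' @return Character vector of read sequences.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTQ file not found: %s", path))
  bad <- locate_bad_fastq_record(path)
  if (!is.na(bad)) {
    abort(sprintf("malformed FASTQ record in %s (record %d)", path, bad))
  }
  res <- tryCatch(
    as.character(Biostrings::readDNAStringSet(path, format = "fastq")),
    error = function(e) {
      abort(sprintf("malformed FASTQ record in %s: %s", path,
                    conditionMessage(e)))
    }
  )
  unname(res)
}

# chunked structural scan: 4-line records with @/+ markers and matching
# sequence/quality lengths; returns the first bad record index or NA
locate_bad_fastq_record <- function(path, chunk_records = 1e6) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con), add = TRUE)
  offset <- 0L
  repeat {
    lines <- readLines(con, n = 4L * chunk_records, warn = FALSE)
    if (length(lines) == 0L) return(NA_integer_)
    n_rec <- length(lines) %/% 4L
    if (n_rec > 0L) {
      i1 <- 4L * (seq_len(n_rec) - 1L)
      ok <- startsWith(lines[i1 + 1L], "@") &
        startsWith(lines[i1 + 3L], "+") &
        nchar(lines[i1 + 2L]) == nchar(lines[i1 + 4L])
      if (!all(ok)) return(offset + which(!ok)[1L])
    }
    if (length(lines) %% 4L != 0L) return(offset + n_rec + 1L)
    offset <- offset + n_rec
  }
}

#' Write reads to a FASTQ file with constant qualities
#'
#' @param reads Character vector of read sequences.
#' @param path Output path (`.gz` for gzip).
#' @param qual_char Single Phred+33 quality character applied to every base.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, qual_char = "I") {
  stopifnot(nchar(qual_char) == 1L)
  seqs <- Biostrings::DNAStringSet(reads)
  names(seqs) <- sprintf("read_%d", seq_along(reads))
  quals <- Biostrings::BStringSet(strrep(qual_char, nchar(reads)))
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
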