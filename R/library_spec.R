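#' Reporter library design: constant flanks and insert length model
#'
#' A `library_spec` describes the fixed sequence context of the variable
#' insert in the reporter construct. Reads are considered valid when they
#' contain the constant 10-bp flanking regions; the last 10 nt of `flank5`
#' and the first 10 nt of `flank3` are the anchors used for matching.
#'
#' @param flank5 Constant sequence 5' of the insert (>= 10 nt, A/C/G/T).
#' @param flank3 Constant sequence 3' of the insert (>= 10 nt, A/C/G/T).
#' @param insert_len_min,insert_len_max Allowed insert length range in nt.
#' @return An object of class `library_spec`.
#' @examples
#' spec <- kmer_library_spec()
#' spec$anchor5
#' @export
library_spec <- function(flank5, flank3, insert_len_min, insert_len_max) {
  stopifnot(is.character(flank5), length(flank5) == 1L,
            is.character(flank3), length(flank3) == 1L)
  check_acgt(flank5, "flank5")
  check_acgt(flank3, "flank3")
  if (nchar(flank5) < 10L || nchar(flank3) < 10L) {
    abort("flanks must be at least 10 nt (the constant anchor length)")
  }
  insert_len_min <- check_scalar_int(insert_len_min, "insert_len_min", min = 1)
  insert_len_max <- check_scalar_int(insert_len_max, "insert_len_max", min = 1)
  if (insert_len_min > insert_len_max) {
    abort("insert_len_min must be <= insert_len_max")
  }
  structure(
    list(
      flank5 = flank5,
      flank3 = flank3,
      anchor5 = substr(flank5, nchar(flank5) - 9L, nchar(flank5)),
      anchor3 = substr(flank3, 1L, 10L),
      insert_len_min = insert_len_min,
      insert_len_max = insert_len_max
    ),
    class = "library_spec"
  )
}

#' @export
print.library_spec <- function(x, ...) {
  cat("<library_spec>\n")
  cat("  5' anchor:", x$anchor5, " 3' anchor:", x$anchor3, "\n")
  cat("  insert length:", x$insert_len_min, "-", x$insert_len_max, "nt\n")
  invisible(x)
}

#' Default spec for the saturating 6-mer insert library
#'
#' Fixed flanks emulating the reporter 3' UTR cloning context, with inserts
#' of exactly 6 nt (the 4,096-member 6-mer library).
#'
#' @return A `library_spec` with `insert_len_min = insert_len_max = 6`.
#' @export
kmer_library_spec <- function() {
  library_spec(
    flank5 = "TCAGACGGCA",
    flank3 = "GTCCTAAGCT",
    insert_len_min = 6L,
    insert_len_max = 6L
  )
}

#' Default spec for the random-fragment library
#'
#' Same constant anchors as [kmer_library_spec()], with inserts in the
#' detected fragment-length range (30-100 nt by default).
#'
#' @param insert_len_min,insert_len_max Fragment length range in nt.
#' @return A `library_spec`.
#' @export
fragment_library_spec <- function(insert_len_min = 30L, insert_len_max = 100L) {
  library_spec(
    flank5 = "TCAGACGGCA",
    flank3 = "GTCCTAAGCT",
    insert_len_min = insert_len_min,
    insert_len_max = insert_len_max
  )
}
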