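# shared low-level helpers

#' Normalize a nucleotide string to the internal DNA alphabet
#'
#' Uppercases and converts U to T. The internal alphabet is DNA throughout
#' the package; sequences are converted back to RNA only on export.
#'
#' @param seq character vector of nucleotide strings
#' @return normalized character vector
#' @export
normalize_seq <- function(seq) {
  toupper(chartr("uU", "TT", seq))
}

#' Reverse complement of a DNA string
#'
#' @param seq character vector over A,C,G,T,N
#' @return reverse-complemented character vector
#' @export
revcomp <- function(seq) {
  vapply(seq, function(s) {
    r <- chartr("ACGT", "TGCA", s)
    paste(rev(strsplit(r, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# truncation (not rounding) to 2 decimals; the reporting convention used for
# all GC/AMFE/MFEI values (42.55*100/107 = 39.766 is reported as 39.76)
truncate2 <- function(x) {
  floor(x * 100 + 1e-9) / 100
}

assert_alphabet <- function(seq, what = "sequence") {
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop(what, " contains characters outside {A,C,G,T,N} (ambiguity codes ",
         "other than N are not supported): ",
         paste(utils::head(which(bad), 3L), collapse = ", "))
  }
  invisible(TRUE)
}
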