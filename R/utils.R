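# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @noRd
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(strsplit(x, ""), function(s) {
    paste(rev(s), collapse = "")
  }, character(1)))
}

#' Random DNA sequences
#' @noRd
random_dna <- function(n, len) {
  if (length(len) == 1L) len <- rep(len, n)
  vapply(len, function(l) {
    paste(sample(DNA_BASES, l, replace = TRUE), collapse = "")
  }, character(1))
}

#' Check a DNA alphabet
#' @noRd
assert_dna <- function(x, allow_n = TRUE, arg = "sequence") {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    abort(sprintf("%s contains characters outside the DNA alphabet (first: '%s')",
                  arg, x[which(bad)[1]]))
  }
  invisible(x)
}

#' All k-mers of a string (positions 1..n-k+1)
#' @noRd
kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  substring(x, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

#' Columns check with a readable error
#' @noRd
assert_cols <- function(df, cols, arg = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  arg, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
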