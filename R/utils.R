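## small shared helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement a character vector of DNA sequences
#' @param x character vector over A/C/G/T/N
#' @return character vector
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Round half away from zero to a fixed number of decimals
#'
#' Percentage tables are reported with conventional half-up rounding rather
#' than banker's rounding, so 79.15 prints as 79.2.
#' @param x numeric vector
#' @param digits decimal places
#' @return numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Generate random DNA
#' @param n number of sequences
#' @param len length (recycled)
#' @return character vector
#' @keywords internal
random_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(len, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
}

n_distinct_nt <- function(seqs) {
  vapply(strsplit(seqs, ""), function(ch) length(unique(ch)), integer(1))
}

## stop unless all conditions hold, with a compact message
check_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
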