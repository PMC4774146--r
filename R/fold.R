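#' Fold a candidate precursor into a single stem-loop
#'
#' Purpose-built dynamic program restricted to the structure class a miRNA
#' precursor is expected to adopt: one ladder of nested base pairs closed by a
#' single terminal loop, with bounded bulges and internal loops between
#' consecutive pairs. Pairs are scored GC = 3, AU = 2, GU = 1 and every
#' interior loop event is penalised, so the returned score is a comparable
#' stability proxy (and `mfe_proxy = -score` orders candidates like a free
#' energy would). The program is not a thermodynamic partition function; a
#' thermodynamic engine could be swapped in behind the same contract.
#'
#' @param seq nucleotide string, 40-200 nt, A/C/G/T/U
#' @param min_stem minimum number of base pairs for a foldable call
#' @param loop_range allowed terminal-loop size, inclusive
#' @param max_gap maximum unpaired bases per side between consecutive pairs
#' @param loop_open,loop_ext interior-loop penalty: `loop_open + loop_ext * size`
#' @return an object of class `hairpin_fold`: `foldable`, `score`,
#'   `mfe_proxy`, `stem_length` (base-pair count), `pairing` (1-based partner
#'   index, 0 = unpaired), `dotbracket`, `terminal_loop_size`, `bulge_sizes`,
#'   `internal_loop_sizes`, and the outer/loop pair coordinates. When no
#'   structure meets the constraints, `foldable` is `FALSE` and the structure
#'   fields are `NA`.
#' @examples
#' arm <- "GCGGCAUUGCAUCCAGGCUAAGCGC"
#' hp  <- paste0(arm, "GAAUUC", as.character(
#'   Biostrings::reverseComplement(Biostrings::RNAString(arm))))
#' fold_hairpin(hp)
#' @export
fold_hairpin <- function(seq, min_stem = 16, loop_range = c(3, 20),
                         max_gap = 4, loop_open = 4, loop_ext = 1) {
  check_that(is.character(seq) && length(seq) == 1, "seq must be one string")
  s <- toupper(gsub("U", "T", seq))
  check_that(grepl("^[ACGT]+$", s), "invalid alphabet: only A/C/G/T/U allowed")
  n <- nchar(s)
  check_that(n >= 40 && n <= 200, "sequence length must be in [40, 200]")
  res <- fold_hairpin_cpp(s, loop_range[1], loop_range[2],
                          max_gap, loop_open, loop_ext)
  out <- list(seq = seq, foldable = FALSE, score = NA_integer_,
              mfe_proxy = NA_real_, stem_length = NA_integer_,
              pairing = NULL, dotbracket = NA_character_,
              terminal_loop_size = NA_integer_,
              bulge_sizes = integer(0), internal_loop_sizes = integer(0),
              outer = c(NA_integer_, NA_integer_),
              loop_pair = c(NA_integer_, NA_integer_))
  class(out) <- "hairpin_fold"
  if (is.na(res$score[1]) || is.null(res$n_pairs)) return(out)
  out$score <- res$score
  out$mfe_proxy <- -res$score
  out$stem_length <- res$n_pairs
  out$pairing <- res$partner
  out$terminal_loop_size <- res$terminal_loop
  out$bulge_sizes <- res$bulge_sizes
  out$internal_loop_sizes <- res$internal_loop_sizes
  out$outer <- c(res$outer_i, res$outer_j)
  out$loop_pair <- c(res$loop_i, res$loop_j)
  db <- rep(".", n)
  paired <- which(res$partner > 0)
  db[paired[paired < res$partner[paired]]] <- "("
  db[paired[paired > res$partner[paired]]] <- ")"
  out$dotbracket <- paste(db, collapse = "")
  out$foldable <- res$n_pairs >= min_stem
  out
}

#' @export
print.hairpin_fold <- function(x, ...) {
  cat("hairpin_fold:", nchar(x$seq), "nt,",
      if (x$foldable) "foldable" else "not foldable", "\n")
  if (!is.na(x$score)) {
    cat("  score", x$score, "| pairs", x$stem_length,
        "| terminal loop", x$terminal_loop_size, "\n")
    cat(" ", x$seq, "\n ", x$dotbracket, "\n")
  }
  invisible(x)
}

## arm membership of window positions, from a fold:
## "5p" outer..loop_i, "3p" loop_j..outer, "loop" inside terminal loop,
## "outside" beyond the outer pair
fold_arms <- function(fold, n) {
  arm <- rep("outside", n)
  if (!isTRUE(fold$stem_length > 0) || is.na(fold$outer[1])) return(arm)
  arm[fold$outer[1]:fold$loop_pair[1]] <- "5p"
  arm[fold$loop_pair[2]:fold$outer[2]] <- "3p"
  if (fold$loop_pair[2] - fold$loop_pair[1] > 1)
    arm[(fold$loop_pair[1] + 1):(fold$loop_pair[2] - 1)] <- "loop"
  arm
}
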