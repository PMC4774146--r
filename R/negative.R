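## Hairpin-free negative control: the prediction stage run over a
## base-shuffled genome with the observed unique sequences placed at random.

#' Shuffle a genome base-by-base
#'
#' Permutes the bases of every chromosome independently, preserving length
#' and composition while destroying all planted structure.
#'
#' @param genome named DNAStringSet or named character vector
#' @param seed integer seed
#' @return named DNAStringSet
#' @export
shuffle_genome <- function(genome, seed = 1) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  set.seed(seed)
  s <- vapply(as.character(genome), function(x) {
    paste(sample(strsplit(x, "")[[1]]), collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(setNames(s, names(genome)))
}

#' Prediction negative control on a shuffled genome
#'
#' Places each unique sequence at a uniform random position and strand on
#' the shuffled genome (its placement interval stands in for an alignment),
#' builds loci and runs the hairpin prediction. With no real hairpins
#' present, high-confidence predictions here would be false positives of
#' the scoring scheme.
#'
#' @param uniques unique-sequence table (with `seq_id`, `seq`,
#'   `pooled_count`)
#' @param genome the original genome (shuffled internally)
#' @param seed integer seed for shuffling and placement
#' @param merge_gap locus merge gap
#' @param cfg a [scoring_config()]
#' @return list with `predictions`, `loci` and the shuffled `genome`
#' @export
negative_control <- function(uniques, genome, seed = 1, merge_gap = 70,
                             cfg = scoring_config()) {
  sh <- shuffle_genome(genome, seed)
  set.seed(seed + 1)
  n <- nrow(uniques)
  w <- nchar(uniques$seq)
  ci <- sample.int(length(sh), n, replace = TRUE)
  maxs <- Biostrings::width(sh)[ci] - w
  start <- floor(runif(n) * maxs)
  aln <- data.frame(seq_id = uniques$seq_id, seq = uniques$seq,
                    chrom = names(sh)[ci], start = start,
                    end = start + w,
                    strand = sample(c("+", "-"), n, replace = TRUE),
                    n_total_hits = 1L,
                    pooled_count = uniques$pooled_count,
                    stringsAsFactors = FALSE)
  bl <- build_loci(aln, merge_gap = merge_gap)
  preds <- predict_loci(bl$loci, bl$alignments, sh, cfg)
  list(predictions = preds, loci = bl$loci, genome = sh)
}
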