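## Cross-genome conservation of mature miRNA sequences: ungapped matching
## with a small substitution allowance, presence calls and breadth summary.

#' Scan one genome for a mature miRNA sequence
#'
#' All ungapped occurrences with at most `max_mismatch` substitutions, on
#' both strands.
#'
#' @param mature nucleotide string (18-28 nt)
#' @param genome named DNAStringSet or named character vector
#' @param max_mismatch substitution allowance (0-3, default 2)
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `mismatches`
#' @export
scan_genome <- function(mature, genome, max_mismatch = 2) {
  check_that(nchar(mature) >= 18 && nchar(mature) <= 28,
             "mature length must be in [18, 28]")
  check_that(max_mismatch >= 0 && max_mismatch <= 3,
             "max_mismatch must be in [0, 3]")
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  pat <- Biostrings::DNAString(gsub("U", "T", toupper(mature)))
  out <- NULL
  for (ci in seq_along(genome)) {
    for (strand in c("+", "-")) {
      p <- if (strand == "+") pat else Biostrings::reverseComplement(pat)
      mm <- Biostrings::matchPattern(p, genome[[ci]],
                                     max.mismatch = max_mismatch)
      mm <- mm[BiocGenerics::start(mm) >= 1 &
                 BiocGenerics::end(mm) <= length(genome[[ci]])]
      if (length(mm) == 0) next
      nmis <- vapply(seq_along(mm), function(k) {
        sum(strsplit(as.character(mm[[k]]), "")[[1]] !=
              strsplit(as.character(p), "")[[1]])
      }, numeric(1))
      out <- rbind(out, data.frame(
        chrom = names(genome)[ci],
        start = BiocGenerics::start(mm) - 1L,
        end = BiocGenerics::end(mm), strand = strand,
        mismatches = as.integer(nmis)))
    }
  }
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatches = integer())
  out
}

#' Conservation profiles of matures across a genome panel
#'
#' @param matures named character vector of mature sequences
#' @param panel named list of genomes (DNAStringSet / named character), or a
#'   named character vector of FASTA paths
#' @param max_mismatch substitution allowance per hit
#' @return data.frame of class `conservation_profiles`: one row per
#'   (miRNA, genome) with `n_hits`, `min_mismatches`, `present`, plus a
#'   `breadth` attribute-free summary via [summarize_conservation()]
#' @export
conservation_profiles <- function(matures, panel, max_mismatch = 2) {
  check_that(length(matures) > 0 && !is.null(names(matures)),
             "matures must be a non-empty named vector")
  if (is.character(panel))
    panel <- lapply(setNames(panel, names(panel)),
                    Biostrings::readDNAStringSet)
  out <- NULL
  for (g in names(panel)) {
    for (m in names(matures)) {
      h <- scan_genome(matures[[m]], panel[[g]], max_mismatch)
      out <- rbind(out, data.frame(
        mirna = m, genome = g, n_hits = nrow(h),
        min_mismatches = if (nrow(h)) min(h$mismatches) else NA_integer_,
        present = nrow(h) > 0, stringsAsFactors = FALSE))
    }
  }
  class(out) <- c("conservation_profiles", class(out))
  out
}

#' Breadth distribution and per-genome presence summary
#'
#' @param profiles output of [conservation_profiles()]
#' @return list with `breadth` (data.frame: `n_genomes` k = 0..panel size,
#'   `n_mirnas`, `percentage`) and `per_genome` (data.frame: `genome`,
#'   `n_present`, `percentage`); percentages are half-up rounded to one
#'   decimal
#' @export
summarize_conservation <- function(profiles) {
  check_that(nrow(profiles) > 0, "empty profile list")
  genomes <- unique(profiles$genome)
  breadth <- tapply(profiles$present, profiles$mirna, sum)
  n <- length(breadth)
  ks <- 0:length(genomes)
  bn <- vapply(ks, function(k) sum(breadth == k), integer(1))
  per <- vapply(genomes, function(g) {
    sum(profiles$present[profiles$genome == g])
  }, integer(1))
  list(
    breadth = data.frame(n_genomes = ks, n_mirnas = bn,
                         percentage = round_half_up(100 * bn / n, 1)),
    per_genome = data.frame(genome = genomes, n_present = per,
                            percentage = round_half_up(100 * per / n, 1),
                            row.names = NULL))
}
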