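## Programmatic fixtures shared across tests.

## a perfect hairpin: arm + loop + reverse complement of the arm.
## The arm ends in C and the loop is all A so the stem cannot extend into
## the loop.
make_hairpin <- function(arm_len = 25, loop = "AAAAAA", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  arm <- paste0("G", paste(sample(c("A", "C", "G", "T"), arm_len - 2,
                                  replace = TRUE), collapse = ""), "C")
  paste0(arm, loop, rc_chr(arm))
}

## a toy single-chromosome genome with a sequence planted at fixed spots
plant_in_genome <- function(insert, positions, chrom_len = 20000,
                            seed = 1) {
  set.seed(seed)
  g <- paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
             collapse = "")
  for (p in positions)
    substr(g, p + 1, p + nchar(insert)) <- insert
  g
}

## archetype scoring fixture: a canonical precursor with read stacks.
## Returns everything score_prediction needs. The dominant read is a 22-mer
## on the 5p arm (85% of counts share its 5' end) and a star read sits on
## the 3p arm.
make_archetype <- function(dominant_len = 22, seed = 3) {
  set.seed(seed)
  hp <- make_hairpin(arm_len = 28, loop = "AAAAAA")
  flank_l <- 300; chrom_len <- 1000
  genome <- plant_in_genome(hp, flank_l, chrom_len, seed = seed + 1)
  ws <- flank_l; we <- flank_l + nchar(hp)
  dom_start <- ws
  members <- data.frame(
    seq_id = c("m1", "m2", "m3"),
    seq = c(substr(hp, 1, dominant_len), substr(hp, 1, dominant_len + 1),
            substr(hp, nchar(hp) - 21, nchar(hp))),
    chrom = "toy",
    start = c(dom_start, dom_start, we - 22),
    end = c(dom_start + dominant_len, dom_start + dominant_len + 1, we),
    strand = "+", n_total_hits = 1L,
    pooled_count = c(70L, 15L, 15L), stringsAsFactors = FALSE)
  locus <- data.frame(locus_id = "L1", chrom = "toy",
                      start = min(members$start), end = max(members$end),
                      strand = "+", n_members = 3L, n_sequences = 3L,
                      total_count = 100L,
                      dominant_seq = members$seq[1],
                      dominant_start = members$start[1],
                      dominant_end = members$end[1],
                      stringsAsFactors = FALSE)
  list(genome = setNames(genome, "toy"), hairpin = hp, locus = locus,
       members = members, window = list(start = ws, end = we))
}

## small somatic/gonadal library pair on a tiny simulated study
small_sim <- function(seed = 1, n_reads = 4000) {
  sim_dataset(sim_genome_config(n_chrom = 2, chrom_len = 30000,
                                n_hairpins = 10),
              default_library_specs(n_reads = n_reads,
                                    base_seed = seed * 37),
              seed = seed)
}
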