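test_that("a sequence planted once yields exactly one alignment", {
  set.seed(5)
  sq <- paste(sample(c("A", "C", "G", "T"), 22, replace = TRUE),
              collapse = "")
  g <- c(chrA = plant_in_genome(sq, 5000, 20000, seed = 6))
  mp <- map_exact(data.frame(seq_id = "u1", seq = sq, pooled_count = 10L), g)
  expect_equal(nrow(mp$alignments), 1)
  expect_equal(mp$alignments$start, 5000)
  expect_equal(mp$alignments$strand, "+")
})

test_that("sequences over the repetitiveness cap are excluded entirely", {
  set.seed(7)
  sq <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
              collapse = "")
  pos <- seq(100, by = 600, length.out = 16)
  g <- c(chrA = plant_in_genome(sq, pos, 20000, seed = 8))
  mp <- map_exact(data.frame(seq_id = "u1", seq = sq, pooled_count = 5L),
                  g, max_hits = 15)
  expect_equal(nrow(mp$alignments), 0)
  expect_equal(mp$repetitive$seq_id, "u1")
  expect_gte(mp$repetitive$n_hits, 16)
  ## with a higher cap all occurrences are reported
  mp2 <- map_exact(data.frame(seq_id = "u1", seq = sq, pooled_count = 5L),
                   g, max_hits = 50)
  expect_gte(nrow(mp2$alignments), 16)
})

test_that("non-ACGT sequences are skipped with a warning", {
  g <- c(chrA = plant_in_genome("ACGT", 10, 2000, seed = 9))
  expect_warning(
    mp <- map_exact(data.frame(seq_id = c("u1", "u2"),
                               seq = c("ACGTNACGTACGTACGTACG",
                                       strrep("ACGT", 5)),
                               pooled_count = 1L), g),
    "non-ACGT")
  expect_equal(mp$skipped, "u1")
})

test_that("mapping equals a naive scan of every position on both strands", {
  set.seed(10)
  g_chr <- list(c1 = plant_in_genome("G", 1, 8000, seed = 11),
                c2 = plant_in_genome("G", 1, 6000, seed = 12))
  ## mix planted and random queries, both strands
  seqs <- character(30)
  for (i in 1:30) {
    w <- sample(16:26, 1)
    if (i <= 15) {
      cn <- sample(names(g_chr), 1)
      p <- sample(nchar(g_chr[[cn]]) - w, 1)
      s <- substr(g_chr[[cn]], p, p + w - 1)
      if (i %% 2 == 0) s <- rc_chr(s)
      seqs[i] <- s
    } else {
      seqs[i] <- paste(sample(c("A", "C", "G", "T"), w, replace = TRUE),
                       collapse = "")
    }
  }
  seqs <- unique(seqs)
  mp <- map_exact(data.frame(seq_id = paste0("u", seq_along(seqs)),
                             seq = seqs, pooled_count = 1L),
                  unlist(g_chr), max_hits = 1000)
  oracle <- oracle_map(seqs, g_chr)
  key <- function(d) sort(paste(d$seq, d$chrom, d$start, d$end, d$strand))
  expect_equal(key(mp$alignments), key(oracle))
})

test_that("locus merging follows the 70-nt inclusive gap rule", {
  mk <- function(s1, s2) data.frame(
    seq_id = c("a", "b"), seq = c(strrep("A", 22), strrep("C", 22)),
    chrom = "c1", start = c(s1, s2), end = c(s1 + 22, s2 + 22),
    strand = "+", n_total_hits = 1L, pooled_count = c(10L, 5L))
  expect_equal(nrow(build_loci(mk(100, 172), 70)$loci), 1)  # gap 50
  expect_equal(nrow(build_loci(mk(100, 192), 70)$loci), 1)  # gap 70
  expect_equal(nrow(build_loci(mk(100, 193), 70)$loci), 2)  # gap 71
  ## overlapping stacks on opposite strands stay apart
  opp <- mk(100, 110)
  opp$strand <- c("+", "-")
  expect_equal(nrow(build_loci(opp, 70)$loci), 2)
})

test_that("locus coordinates and dominant sequence are aggregated", {
  aln <- data.frame(
    seq_id = c("a", "b", "c"),
    seq = c(strrep("A", 20), strrep("C", 22), strrep("G", 21)),
    chrom = "c1", start = c(100, 110, 400), end = c(120, 132, 421),
    strand = "+", n_total_hits = 1L, pooled_count = c(5L, 50L, 7L))
  bl <- build_loci(aln, 70)
  expect_equal(nrow(bl$loci), 2)
  expect_equal(bl$loci$start[1], 100)
  expect_equal(bl$loci$end[1], 132)
  expect_equal(bl$loci$dominant_seq[1], strrep("C", 22))
  expect_equal(bl$loci$total_count, c(55L, 7L))
  ## every alignment belongs to exactly one locus
  expect_false(any(is.na(bl$alignments$locus_id)))
  ## stack profile sums counts over covered positions
  depth <- locus_stack_profile(bl$loci[1, ], bl$alignments)
  expect_equal(length(depth), 32)
  expect_equal(max(depth), 55)     # overlap of both stacks
  expect_equal(sum(depth), 5 * 20 + 50 * 22)
})

test_that("merging matches a quadratic union-find on random alignments", {
  set.seed(13)
  for (rep in 1:30) {
    n <- sample(5:40, 1)
    start <- sample(0:3000, n, replace = TRUE)
    w <- sample(16:28, n, replace = TRUE)
    aln <- data.frame(seq_id = paste0("u", 1:n), seq = strrep("A", w),
                      chrom = sample(c("c1", "c2"), n, replace = TRUE),
                      start = start, end = start + w,
                      strand = sample(c("+", "-"), n, replace = TRUE),
                      n_total_hits = 1L,
                      pooled_count = sample(1:50, n, replace = TRUE))
    gap <- sample(c(0, 10, 70), 1)
    bl <- build_loci(aln, gap)
    got <- bl$alignments[order(bl$alignments$seq_id), ]
    oracle <- oracle_merge(aln, gap)[order(aln$seq_id)]
    expect_true(same_partition(got$locus_id, oracle))
    ## idempotence: rebuilding from locus intervals yields the same loci
    re <- build_loci(bl$alignments, gap)
    expect_equal(re$loci[, c("chrom", "start", "end", "strand")],
                 bl$loci[, c("chrom", "start", "end", "strand")])
    ## order invariance
    sh <- build_loci(aln[sample(n), ], gap)
    expect_equal(sh$loci, bl$loci)
  }
})
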