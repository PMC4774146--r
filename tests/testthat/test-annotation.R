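dna <- function(x) Biostrings::DNAStringSet(x)

test_that("database merging tracks provenance and collapses duplicates", {
  db1 <- dna(c(a = strrep("ACGT", 6), shared = strrep("GATC", 6)))
  db2 <- dna(c(b = strrep("TTGA", 6), other = strrep("GATC", 6)))
  m <- merge_mirna_dbs(db1, db2)
  expect_equal(length(m), 3)
  src <- setNames(S4Vectors::mcols(m)$source, names(m))
  expect_equal(unname(src[c("a", "shared", "b")]),
               c("db1", "both", "db2"))
  expect_equal(S4Vectors::mcols(m)$alt_id[names(m) == "shared"], "other")
  expect_error(merge_mirna_dbs(dna(c(x = "ACGTACGT", x = "ACGTACGA")),
                               db2), "duplicate")
})

test_that("database hits honour identity and coverage thresholds", {
  set.seed(21)
  mature <- paste(sample(c("A", "C", "G", "T"), 22, replace = TRUE),
                  collapse = "")
  prec <- paste0(strrep("GGCA", 5), mature, strrep("TTGC", 5))
  dbs <- list(mirna_merged = dna(c(mir1 = mature)))
  h <- annotate_against_dbs(c(p1 = prec), dbs)
  expect_equal(nrow(h), 1)
  expect_equal(h$identity, 1)

  ## three mismatches over a 22-mer: identity 19/22 < 0.9, no hit
  mut <- mature
  for (p in c(3, 10, 17))
    substr(mut, p, p) <- setdiff(c("A", "C", "G", "T"),
                                 substr(mut, p, p))[1]
  prec_mut <- paste0(strrep("GGCA", 5), mut, strrep("TTGC", 5))
  h2 <- annotate_against_dbs(c(p2 = prec_mut), dbs)
  expect_equal(nrow(h2), 0)

  ## reverse-complement copies are still found
  h3 <- annotate_against_dbs(c(p3 = rc_chr(prec)), dbs)
  expect_equal(nrow(h3), 1)
})

test_that("repeat matches require a perfect full-length occurrence", {
  set.seed(22)
  rep_el <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
                  collapse = "")
  dbs <- list("repeat" = dna(c(r1 = rep_el)))
  inside <- substr(rep_el, 30, 95)      # precursor inside the element
  h <- annotate_against_dbs(c(p1 = inside), dbs)
  expect_equal(h$db_name, "repeat")
  ## one mismatch breaks the perfect-match requirement
  near <- inside
  substr(near, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                  substr(near, 10, 10))[1]
  expect_equal(nrow(annotate_against_dbs(c(p2 = near), dbs)), 0)
})

test_that("prediction partition follows the documented precedence", {
  mk_hits <- function(id, dbs) {
    if (length(dbs) == 0) return(NULL)
    data.frame(query_id = id, db_name = dbs, subject_id = "s",
               identity = 1, aligned_fraction = 1, mismatches = 0L)
  }
  hits <- rbind(mk_hits("q_rep", "repeat"),
                mk_hits("q_other", "other_ncrna"),
                mk_hits("q_multi", c("mirna_merged", "other_ncrna")),
                mk_hits("q_mir", "mirna_merged"),
                mk_hits("q_repmir", c("repeat", "mirna_merged")))
  ids <- c("q_rep", "q_other", "q_multi", "q_mir", "q_repmir", "q_novel")
  part <- partition_predictions(ids, hits)
  got <- setNames(part$categories$category, part$categories$query_id)
  expect_equal(unname(got[ids]),
               c("repeat", "other_ncrna", "mirna_multi", "mirna_only",
                 "repeat", "novel"))
  a <- part$accounting
  expect_equal(a$n_predictions,
               a$n_discarded + a$n_mirna_annotated + a$n_novel)
})

test_that("the partition is exhaustive and disjoint over all hit patterns", {
  dbs <- c("repeat", "rrna", "trna", "other_ncrna", "mirna_merged")
  ids <- character(0); hits <- NULL
  for (mask in 0:31) {
    present <- dbs[bitwAnd(mask, 2^(0:4)) > 0]
    id <- paste0("q", mask)
    ids <- c(ids, id)
    if (length(present))
      hits <- rbind(hits, data.frame(query_id = id, db_name = present,
                                     subject_id = "s", identity = 1,
                                     aligned_fraction = 1,
                                     mismatches = 0L))
  }
  part <- partition_predictions(ids, hits)
  expect_equal(sort(part$categories$query_id), sort(ids))
  expect_false(any(is.na(part$categories$category)))
  counts <- table(part$categories$category)
  expect_equal(sum(counts), 32)
  ## precedence spot checks from the bit patterns
  get <- function(id) part$categories$category[
    part$categories$query_id == id]
  expect_equal(get("q0"), "novel")
  expect_equal(get("q1"), "repeat")            # repeat only
  expect_equal(get("q16"), "mirna_only")       # miRNA only
  expect_equal(get("q18"), "mirna_multi")      # miRNA + rRNA
  expect_equal(get("q2"), "other_ncrna")       # rRNA only
})

test_that("miRNA-only provenance splits into both/db1/db2", {
  db1 <- dna(c(m1 = strrep("ACGT", 6), m2 = strrep("GGCA", 6)))
  db2 <- dna(c(m3 = strrep("ACGT", 6), m4 = strrep("TTCA", 6)))
  merged <- merge_mirna_dbs(db1, db2)
  hits <- data.frame(
    query_id = c("a", "b", "c"),
    db_name = "mirna_merged",
    subject_id = c("m1", "m2", "m4"),
    identity = 1, aligned_fraction = 1, mismatches = 0L)
  part <- partition_predictions(c("a", "b", "c"), hits, merged)
  src <- setNames(part$categories$mirna_source, part$categories$query_id)
  expect_equal(unname(src[c("a", "b", "c")]),
               c("both_dbs", "db1_only", "db2_only"))
  expect_equal(part$accounting$n_mirna_both_dbs, 1)
  expect_equal(part$accounting$n_mirna_db1_only, 1)
  expect_equal(part$accounting$n_mirna_db2_only, 1)
})

test_that("structural classification applies UTR > exon > intron", {
  gm <- GenomicRanges::GRanges(
    "c1",
    IRanges::IRanges(c(1001, 1001, 2001, 3501, 1001, 3901),
                     c(4000, 1400, 2400, 4000, 1100, 4000)),
    strand = "+",
    type = c("gene", "exon", "exon", "exon", "five_prime_UTR",
             "three_prime_UTR"))
  iv <- data.frame(
    chrom = "c1",
    start = c(4500, 1500, 2100, 1020, 3950, 1390),
    end   = c(4570, 1570, 2170, 1090, 3990, 1460))
  got <- annotate_structural(iv, gm)
  expect_equal(got, c("intergenic", "intron", "exon", "utr5", "utr3",
                      "exon"))
  ## gene-model strand is ignored
  S4Vectors::mcols(gm)$type <- as.character(gm$type)
  BiocGenerics::strand(gm) <- "-"
  expect_equal(annotate_structural(iv, gm), got)
})

test_that("structural percentages reproduce half-up one-decimal rounding", {
  t1 <- summarize_structural(c(intergenic = 352, intron = 85,
                               utr_exon = 8))
  expect_equal(t1$percentage[t1$category == "intergenic"], 79.1)
  expect_equal(t1$percentage[t1$category == "intron"], 19.1)
  expect_equal(t1$percentage[t1$category == "utr_exon"], 1.8)
  t2 <- summarize_structural(c(intergenic = 2043, intron = 416,
                               exon = 42))
  expect_equal(t2$percentage, c(81.7, 16.6, 1.7))
  expect_equal(summarize_structural(c(a = 1))$percentage, 100.0)
  expect_lte(abs(sum(t2$percentage) - 100), 0.2)
  expect_error(summarize_structural(c(a = 0)), "total")
})
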