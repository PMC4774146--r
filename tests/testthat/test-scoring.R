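cfg <- scoring_config()

## independent recomputation of the five sub-scores from first principles,
## kept as a plain transcription of the documented formulas
oracle_subscores <- function(fold, n, dom_len, arm_frac, read_paired,
                             duplex_ev, duplex_gap, duplex_gu,
                             f5, multi, star, cfg) {
  rmp <- function(x, r) min(1, max(0, (x - r[1]) / (r[2] - r[1])))
  ev <- length(c(fold$bulge_sizes, fold$internal_loop_sizes))
  s1 <- cfg$w_structure * rmp(fold$stem_length,
                              c(cfg$stem_base, cfg$stem_full)) *
    rmp(2 * fold$stem_length / n, cfg$paired_frac_range) *
    min(1, max(0, 1 - max(0, ev - cfg$free_events) /
                 cfg$event_factor_scale))
  d <- max(0, cfg$size_range[1] - n, n - cfg$size_range[2])
  s2 <- cfg$w_size * min(1, max(0, 1 - d / cfg$size_decay))
  big <- sum(c(fold$bulge_sizes, fold$internal_loop_sizes) >
               cfg$big_loop_size)
  t_ok <- fold$terminal_loop_size >= cfg$terminal_range[1] &&
    fold$terminal_loop_size <= cfg$terminal_range[2]
  s3 <- max(0, cfg$w_geometry - cfg$big_loop_penalty * big -
              cfg$terminal_penalty * !t_ok -
              cfg$event_penalty * max(0, ev - cfg$free_events)) *
    rmp(fold$stem_length, c(cfg$stem_base, cfg$stem_full))
  ok4 <- dom_len >= cfg$dominant_size[1] &&
    dom_len <= cfg$dominant_size[2] && arm_frac >= cfg$arm_min_frac &&
    duplex_ev <= cfg$free_events && duplex_gap <= cfg$duplex_loop_max &&
    duplex_gu <= cfg$duplex_gu_max
  s4 <- if (ok4) cfg$w_dominant * rmp(read_paired,
                                      cfg$dominant_paired_range) else 0
  s5 <- (if (multi) cfg$w_precision * rmp(f5, cfg$precision_range) else 0) +
    (if (star) cfg$w_star else 0)
  c(s1, s2, s3, s4, s5)
}

test_that("the canonical archetype scores at or above the threshold", {
  ar <- make_archetype()
  fold <- fold_hairpin(ar$hairpin)
  sc <- score_prediction(ar$locus, ar$members, fold, ar$window, cfg)
  expect_gte(sc$score, 800)
  expect_equal(classify_confidence(sc$score, cfg), "high")
  expect_true(sc$star_support)
  expect_equal(sc$dominant_arm, "5p")
  expect_equal(unname(sc$f5), 0.85)
  ## cross-check every sub-score against the independent transcription
  n <- ar$window$end - ar$window$start
  exp_sub <- oracle_subscores(fold, n, dom_len = 22, arm_frac = 1,
                              read_paired = 1, duplex_ev = 0,
                              duplex_gap = 0, duplex_gu = 0,
                              f5 = 0.85, multi = TRUE, star = TRUE, cfg)
  expect_equal(unname(sc$sub_scores[c("structure", "size", "geometry",
                                      "dominant_read")]),
               exp_sub[1:4], tolerance = 1e-6)
  expect_equal(unname(sc$sub_scores[["precision"]] +
                        sc$sub_scores[["star"]]), exp_sub[5],
               tolerance = 1e-6)
})

test_that("an oversized dominant read forfeits criterion four and the
          threshold", {
  ar <- make_archetype(dominant_len = 27)
  fold <- fold_hairpin(ar$hairpin)
  sc <- score_prediction(ar$locus, ar$members, fold, ar$window, cfg)
  expect_equal(unname(sc$sub_scores[["dominant_read"]]), 0)
  expect_lt(sc$score, 800)
  expect_equal(classify_confidence(sc$score, cfg), "low")
})

test_that("confidence classification is inclusive at the threshold", {
  expect_equal(classify_confidence(c(800, 799, 1293, 0), cfg),
               c("high", "low", "high", "low"))
})

test_that("degrading the archetype never increases the score", {
  ar <- make_archetype()
  fold <- fold_hairpin(ar$hairpin)
  base <- score_prediction(ar$locus, ar$members, fold, ar$window, cfg)$score

  ## scatter the 5' ends of supporting reads
  scat <- ar$members
  scat$start <- scat$start + c(0, 3, 0)
  sc1 <- score_prediction(ar$locus, scat, fold, ar$window, cfg)$score
  expect_lte(sc1, base)

  ## remove the star read
  nostar <- ar$members[1:2, ]
  loc2 <- ar$locus
  sc2 <- score_prediction(loc2, nostar, fold, ar$window, cfg)$score
  expect_lte(sc2, base)

  ## weaken the stem: mutate bases in the 3' arm and refold
  hp <- ar$hairpin
  for (p in c(40, 46, 52)) substr(hp, p, p) <- "A"
  fold3 <- fold_hairpin(hp)
  if (fold3$foldable) {
    sc3 <- score_prediction(ar$locus, ar$members, fold3, ar$window, cfg)$score
    expect_lte(sc3, base)
  }
})

test_that("candidate windows always contain the stack and respect edges", {
  ar <- make_archetype()
  wins <- extract_windows(ar$locus, chrom_len = 1000, cfg)
  expect_gt(nrow(wins), 0)
  expect_true(all(wins$start <= ar$locus$dominant_start))
  expect_true(all(wins$end >= ar$locus$dominant_end))
  expect_true(all(wins$end - wins$start >= cfg$scan_range[1]))
  expect_true(all(wins$end - wins$start <= cfg$scan_range[2]))
  ## a locus near the chromosome start is clipped at zero
  loc <- ar$locus
  loc$start <- loc$dominant_start <- 5
  loc$end <- loc$dominant_end <- 27
  wins2 <- extract_windows(loc, chrom_len = 1000, cfg)
  expect_true(all(wins2$start >= 0))
})

test_that("prediction over a planted genome recovers the planted window", {
  ar <- make_archetype()
  bl <- build_loci(ar$members, 70)
  pr <- predict_loci(bl$loci, bl$alignments, ar$genome, cfg)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$confidence, "high")
  ## the chosen window covers the planted hairpin closely
  expect_lt(abs(pr$start - ar$window$start), 10)
  expect_lt(abs(pr$end - ar$window$end), 10)
  ## deterministic: same inputs, same prediction
  pr2 <- predict_loci(bl$loci, bl$alignments, ar$genome, cfg)
  expect_identical(pr, pr2)
})
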