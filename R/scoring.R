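## Candidate-precursor window extraction and the five-criterion composite
## score on the 0-1300 scale with the 800 high-confidence threshold.

#' Scoring configuration for hairpin prediction
#'
#' The composite score is a weighted sum of five criteria scaled to a
#' maximum of 1300: (1) structure quality (stem length and paired fraction),
#' (2) precursor size (full points inside `size_range`, linear decay
#' outside), (3) loop geometry (penalties for oversized bulges/internal
#' loops and an out-of-range terminal loop), (4) dominant-read placement
#' (full points when the most-represented sequence is 20-24 nt and lies at
#' least `arm_min_frac` of its span on one stem arm, zero otherwise), and
#' (5) expression profile (graded processing-precision credit for reads
#' sharing the dominant 5' end, plus star-read support on the opposite arm).
#' The weights were calibrated once against the canonical archetype: a clean
#' 28-bp stem with a 22-nt dominant read and star support scores above the
#' high-confidence threshold, the same locus with a 27-nt dominant read
#' falls below it, and scattered-read non-hairpin loci fall below 250.
#'
#' @param w_structure,w_size,w_geometry,w_dominant,w_precision,w_star
#'   criterion maxima (sum 1300)
#' @param size_range precursor size giving full size points (nt)
#' @param size_decay nt outside `size_range` over which size points reach 0
#' @param dominant_size dominant-read length window (nt)
#' @param arm_min_frac minimum fraction of the dominant read on one stem arm
#' @param precision_range 5'-homogeneity fractions mapped linearly onto
#'   0..`w_precision`
#' @param dominant_paired_range ramp on the paired fraction of the
#'   dominant-read span (a genuine mature aligns against the stem)
#' @param duplex_loop_max largest interior loop (unpaired bases summed over
#'   both duplex sides) tolerated under the dominant read; point
#'   substitutions open size-2 loops, larger loops disrupt processing
#' @param duplex_gu_max G:U wobbles tolerated under the dominant read; a
#'   mature arm is a near-Watson-Crick reverse complement of its star,
#'   whereas chance stems carry a heavy wobble load
#' @param stem_full,stem_base pair counts mapped linearly onto structure
#'   points (`stem_base` pairs score 0, `stem_full` full)
#' @param paired_frac_range paired-fraction ramp for structure points
#' @param event_factor_scale interior-loop events beyond `free_events`
#'   linearly quench the structure points over this many extra events
#' @param big_loop_size,big_loop_penalty interior loops larger than
#'   `big_loop_size` nt cost `big_loop_penalty` geometry points each
#' @param terminal_range,terminal_penalty allowed terminal-loop size and the
#'   cost of leaving it
#' @param free_events,event_penalty interior-loop events beyond
#'   `free_events` cost `event_penalty` each
#' @param high_conf_threshold score at or above which a prediction is
#'   high-confidence (default 800)
#' @param scan_range,len_step,pos_step window lengths scanned and the length
#'   and position steps
#' @param max_locus_span loci longer than this are windowed around the
#'   dominant stack only
#' @param min_stem,loop_range,max_gap folding constraints (see
#'   [fold_hairpin()])
#' @return list of class `scoring_config`
#' @export
scoring_config <- function(w_structure = 400, w_size = 100, w_geometry = 100,
                           w_dominant = 550, w_precision = 100, w_star = 50,
                           size_range = c(60, 80), size_decay = 20,
                           dominant_size = c(20, 24), arm_min_frac = 0.9,
                           precision_range = c(0.5, 0.8),
                           dominant_paired_range = c(0.6, 0.85),
                           duplex_loop_max = 2, duplex_gu_max = 2,
                           stem_full = 28, stem_base = 14,
                           paired_frac_range = c(0.5, 0.85),
                           event_factor_scale = 4,
                           big_loop_size = 3, big_loop_penalty = 30,
                           terminal_range = c(3, 15), terminal_penalty = 25,
                           free_events = 2, event_penalty = 5,
                           high_conf_threshold = 800,
                           scan_range = c(50, 90), len_step = 2,
                           pos_step = 3, max_locus_span = 200,
                           min_stem = 16, loop_range = c(3, 20),
                           max_gap = 4) {
  cfg <- as.list(environment())
  check_that(all(unlist(cfg[c("w_structure", "w_size", "w_geometry",
                              "w_dominant", "w_precision", "w_star")]) >= 0),
             "criterion weights must be >= 0")
  max_score <- w_structure + w_size + w_geometry + w_dominant +
    w_precision + w_star
  check_that(high_conf_threshold <= max_score,
             "high_conf_threshold must be within the attainable score range")
  cfg$max_score <- max_score
  class(cfg) <- "scoring_config"
  cfg
}

clamp01 <- function(x) pmin(1, pmax(0, x))
ramp <- function(x, range) clamp01((x - range[1]) / (range[2] - range[1]))

#' Candidate precursor windows for a locus
#'
#' Windows of every length in `scan_range` (step `len_step`) positioned so
#' that the dominant read stack lies within the window (position step
#' `pos_step`), clipped at chromosome ends. Loci longer than
#' `max_locus_span` are anchored on the dominant stack alone.
#'
#' @param locus one row of the loci table from [build_loci()]
#' @param chrom_len length of the locus chromosome
#' @param cfg a [scoring_config()]
#' @return data.frame of `start`, `end` (0-based half-open)
#' @export
extract_windows <- function(locus, chrom_len, cfg = scoring_config()) {
  ds <- locus$dominant_start; de <- locus$dominant_end
  out <- NULL
  for (L in seq(cfg$scan_range[1], cfg$scan_range[2], by = cfg$len_step)) {
    if (L < de - ds) next
    lo <- max(0L, de - L)
    hi <- min(ds, chrom_len - L)
    if (hi < lo) next
    starts <- seq(lo, hi, by = cfg$pos_step)
    if (starts[length(starts)] != hi) starts <- c(starts, hi)
    out <- rbind(out, data.frame(start = starts, end = starts + L))
  }
  if (is.null(out)) data.frame(start = integer(), end = integer()) else out
}

## window sequence on the locus strand; genome_chr is a named list of
## plain character chromosomes (cached once per run)
window_seq <- function(genome_chr, chrom, start, end, strand) {
  s <- substr(genome_chr[[chrom]], start + 1, end)
  if (strand == "-") intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", s))))
  else s
}

#' Score one candidate window
#'
#' @param locus locus row; `members` its alignment rows; `fold` the window's
#'   [fold_hairpin()] result; `window` a list/row with `start`, `end`
#' @param members alignments of the locus (with `pooled_count`)
#' @param fold `hairpin_fold` for the window sequence (locus strand)
#' @param window list with `start` and `end` (0-based)
#' @param cfg a [scoring_config()]
#' @return list with `score`, `sub_scores` (named numeric),
#'   `dominant_arm`, `dominant_len`, `star_support`, `f5`
#' @export
score_prediction <- function(locus, members, fold, window,
                             cfg = scoring_config()) {
  check_that(isTRUE(fold$foldable), "fold must be foldable")
  n <- window$end - window$start
  arms <- fold_arms(fold, n)
  rel <- function(s, e) {
    if (locus$strand == "+") c(s - window$start + 1, e - window$start)
    else c(window$end - e + 1, window$end - s)
  }
  arm_frac <- function(s, e) {
    r <- rel(s, e)
    r <- c(max(1, r[1]), min(n, r[2]))
    if (r[1] > r[2]) return(c(`5p` = 0, `3p` = 0, loop = 0))
    a <- arms[r[1]:r[2]]
    len <- e - s
    c(`5p` = sum(a == "5p") / len, `3p` = sum(a == "3p") / len,
      loop = sum(a == "loop") / len)
  }

  dom <- members[order(-members$pooled_count, members$start,
                       members$seq), ][1, ]
  dom_len <- dom$end - dom$start
  fr <- arm_frac(dom$start, dom$end)
  dom_arm <- if (max(fr[c("5p", "3p")]) == 0) {
    if (fr["loop"] > 0) "loop" else "outside"
  } else names(which.max(fr[c("5p", "3p")]))

  ## (1) structure: stem length, paired fraction of the window, and a
  ## clean-stem factor that decays with interior-loop events (random
  ## sequence only reaches high pair counts through many interior loops)
  events_all <- c(fold$bulge_sizes, fold$internal_loop_sizes)
  paired_frac <- 2 * fold$stem_length / n
  s1 <- cfg$w_structure *
    ramp(fold$stem_length, c(cfg$stem_base, cfg$stem_full)) *
    ramp(paired_frac, cfg$paired_frac_range) *
    clamp01(1 - max(0, length(events_all) - cfg$free_events) /
              cfg$event_factor_scale)

  ## (2) precursor size
  d <- max(0, cfg$size_range[1] - n, n - cfg$size_range[2])
  s2 <- cfg$w_size * clamp01(1 - d / cfg$size_decay)

  ## (3) loop geometry, judged relative to a credible stem: a short chance
  ## stem with incidentally clean loops is not a pre-miRNA, so geometry
  ## credit scales with the stem-length ramp
  events <- events_all
  s3 <- cfg$w_geometry -
    cfg$big_loop_penalty * sum(events > cfg$big_loop_size) -
    cfg$terminal_penalty * !(fold$terminal_loop_size >= cfg$terminal_range[1] &&
                             fold$terminal_loop_size <= cfg$terminal_range[2]) -
    cfg$event_penalty * max(0, length(events) - cfg$free_events)
  s3 <- max(0, s3) * ramp(fold$stem_length, c(cfg$stem_base, cfg$stem_full))

  ## (4) dominant read placement: correct size, at least `arm_min_frac` of
  ## its span on one stem arm, and that span well paired (a genuine mature
  ## aligns against the stem, not across bulged or unpaired sequence)
  on_arm <- dom_arm %in% c("5p", "3p") &&
    max(fr[c("5p", "3p")]) >= cfg$arm_min_frac
  in_size <- dom_len >= cfg$dominant_size[1] && dom_len <= cfg$dominant_size[2]
  rdom <- rel(dom$start, dom$end)
  rdom <- c(max(1, rdom[1]), min(n, rdom[2]))
  read_paired <- if (rdom[1] > rdom[2]) 0 else
    sum(fold$pairing[rdom[1]:rdom[2]] > 0) / dom_len
  wchars <- strsplit(toupper(gsub("U", "T", fold$seq)), "")[[1]]
  de <- if (rdom[1] <= rdom[2])
    duplex_events(fold$pairing, rdom[1], rdom[2], wchars)
  else c(99L, 99L, 99L)
  duplex_ok <- de[1] <= cfg$free_events &&
    de[2] <= cfg$duplex_loop_max && de[3] <= cfg$duplex_gu_max
  s4 <- if (on_arm && in_size && duplex_ok)
    cfg$w_dominant * ramp(read_paired, cfg$dominant_paired_range) else 0

  ## (5) expression profile: processing precision + star support
  five_prime <- if (locus$strand == "+") members$start else members$end
  dom5 <- if (locus$strand == "+") dom$start else dom$end
  f5 <- sum(members$pooled_count[five_prime == dom5]) /
    sum(members$pooled_count)
  multi <- length(unique(members$seq_id)) >= 2
  s5a <- if (multi) cfg$w_precision * ramp(f5, cfg$precision_range) else 0
  opp <- setdiff(c("5p", "3p"), dom_arm)
  star <- FALSE
  if (length(opp) == 1 && nrow(members) > 1) {
    others <- members[members$seq_id != dom$seq_id, , drop = FALSE]
    for (i in seq_len(nrow(others))) {
      of <- arm_frac(others$start[i], others$end[i])
      if (of[opp] >= 0.5) { star <- TRUE; break }
    }
  }
  s5b <- if (star) cfg$w_star else 0

  sub <- c(structure = s1, size = s2, geometry = s3, dominant_read = s4,
           precision = s5a, star = s5b)
  list(score = round(sum(sub)), sub_scores = round(sub, 1),
       dominant_arm = dom_arm, dominant_len = dom_len,
       dominant_seq = dom$seq, star_support = star, f5 = f5)
}

#' Classify a prediction score as high or low confidence
#'
#' @param score integer score(s)
#' @param cfg a [scoring_config()]
#' @return character vector, "high" (score at or above the threshold) or
#'   "low"
#' @export
classify_confidence <- function(score, cfg = scoring_config()) {
  ifelse(score >= cfg$high_conf_threshold, "high", "low")
}

#' Predict hairpin precursors for a set of loci
#'
#' For every locus, scans candidate windows, folds each into a single
#' stem-loop, scores the foldable ones and keeps the best window (ties
#' broken by longer stem, then precursor length closest to 70 nt, then
#' leftmost window). Loci with no foldable window yield no prediction.
#'
#' @param loci,alignments output of [build_loci()]
#' @param genome named DNAStringSet
#' @param cfg a [scoring_config()]
#' @return data.frame of predictions: locus id and coordinates, window
#'   coordinates, precursor sequence and dot-bracket structure, composite
#'   score and sub-scores, confidence, dominant-read fields, `star_support`
#' @export
predict_loci <- function(loci, alignments, genome, cfg = scoring_config()) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  chrom_len <- setNames(Biostrings::width(genome), names(genome))
  genome_chr <- setNames(as.list(as.character(genome)), names(genome))
  member_split <- split(alignments, alignments$locus_id)
  ovl <- function(a1, a2, b1, b2) max(0, min(a2, b2) - max(a1, b1) + 1)
  preds <- vector("list", nrow(loci))
  for (li in seq_len(nrow(loci))) {
    locus <- loci[li, ]
    members <- member_split[[locus$locus_id]]
    wins <- extract_windows(locus, chrom_len[[locus$chrom]], cfg)

    ## window-independent locus features, as plain vectors
    ms <- members$start; me <- members$end; cnt <- members$pooled_count
    dom_i <- order(-cnt, ms, members$seq)[1]
    plus <- locus$strand == "+"
    five <- if (plus) ms else me
    f5 <- sum(cnt[five == five[dom_i]]) / sum(cnt)
    multi <- length(unique(members$seq_id)) >= 2
    dlen <- me[dom_i] - ms[dom_i]
    s5a <- if (multi) cfg$w_precision * ramp(f5, cfg$precision_range) else 0
    in_size <- dlen >= cfg$dominant_size[1] && dlen <= cfg$dominant_size[2]

    best <- NULL
    for (wi in seq_len(nrow(wins))) {
      ws <- wins$start[wi]; we <- wins$end[wi]
      n <- we - ws
      seq <- window_seq(genome_chr, locus$chrom, ws, we, locus$strand)
      f <- fold_hairpin_cpp(seq, cfg$loop_range[1], cfg$loop_range[2],
                            cfg$max_gap, 4, 1)
      if (is.na(f$score[1]) || f$n_pairs < cfg$min_stem) next
      oi <- f$outer_i; oj <- f$outer_j; lp <- f$loop_i; lq <- f$loop_j
      r1 <- if (plus) ms - ws + 1 else we - me + 1
      r2 <- if (plus) me - ws else we - ms
      c1 <- pmax(1, r1); c2 <- pmin(n, r2)
      fr5 <- ovl(c1[dom_i], c2[dom_i], oi, lp) / dlen
      fr3 <- ovl(c1[dom_i], c2[dom_i], lq, oj) / dlen
      arm_max <- max(fr5, fr3)
      dom_arm <- if (fr5 >= fr3) "5p" else "3p"
      events <- c(f$bulge_sizes, f$internal_loop_sizes)
      s1 <- cfg$w_structure *
        ramp(f$n_pairs, c(cfg$stem_base, cfg$stem_full)) *
        ramp(2 * f$n_pairs / n, cfg$paired_frac_range) *
        clamp01(1 - max(0, length(events) - cfg$free_events) /
                  cfg$event_factor_scale)
      d <- max(0, cfg$size_range[1] - n, n - cfg$size_range[2])
      s2 <- cfg$w_size * clamp01(1 - d / cfg$size_decay)
      s3 <- max(0, cfg$w_geometry -
                  cfg$big_loop_penalty * sum(events > cfg$big_loop_size) -
                  cfg$terminal_penalty *
                    !(f$terminal_loop >= cfg$terminal_range[1] &&
                      f$terminal_loop <= cfg$terminal_range[2]) -
                  cfg$event_penalty * max(0, length(events) -
                                            cfg$free_events)) *
        ramp(f$n_pairs, c(cfg$stem_base, cfg$stem_full))
      read_paired <- if (c1[dom_i] > c2[dom_i]) 0 else
        sum(f$partner[c1[dom_i]:c2[dom_i]] > 0) / dlen
      de <- if (c1[dom_i] <= c2[dom_i])
        duplex_events(f$partner, c1[dom_i], c2[dom_i],
                      strsplit(seq, "")[[1]])
      else c(99L, 99L, 99L)
      duplex_ok <- de[1] <= cfg$free_events &&
        de[2] <= cfg$duplex_loop_max && de[3] <= cfg$duplex_gu_max
      s4 <- if (in_size && arm_max >= cfg$arm_min_frac && duplex_ok)
        cfg$w_dominant * ramp(read_paired, cfg$dominant_paired_range)
      else 0
      star <- FALSE
      if (length(ms) > 1 && arm_max > 0) {
        a1 <- if (dom_arm == "5p") lq else oi
        a2 <- if (dom_arm == "5p") oj else lp
        for (k in seq_along(ms)) {
          if (members$seq_id[k] == members$seq_id[dom_i]) next
          if (c1[k] <= c2[k] &&
              ovl(c1[k], c2[k], a1, a2) / (me[k] - ms[k]) >= 0.5) {
            star <- TRUE; break
          }
        }
      }
      score <- round(s1 + s2 + s3 + s4 + s5a + (if (star) cfg$w_star else 0))
      key <- c(score, f$n_pairs, -abs(n - 70), -ws)
      if (is.null(best) || key_beats(key, best$key))
        best <- list(key = key, w = list(start = ws, end = we), seq = seq)
    }
    if (is.null(best)) next
    ## re-derive the winner through the reference single-window scorer
    fold <- fold_hairpin(best$seq, min_stem = cfg$min_stem,
                         loop_range = cfg$loop_range, max_gap = cfg$max_gap)
    best$fold <- fold
    best$sc <- score_prediction(locus, members, fold, best$w, cfg)
    preds[[li]] <- data.frame(
      locus_id = locus$locus_id, chrom = locus$chrom,
      start = best$w$start, end = best$w$end, strand = locus$strand,
      precursor_seq = best$seq, dotbracket = best$fold$dotbracket,
      stem_length = best$fold$stem_length,
      terminal_loop = best$fold$terminal_loop_size,
      mfe_proxy = best$fold$mfe_proxy,
      score = best$sc$score,
      s_structure = best$sc$sub_scores[["structure"]],
      s_size = best$sc$sub_scores[["size"]],
      s_geometry = best$sc$sub_scores[["geometry"]],
      s_dominant = best$sc$sub_scores[["dominant_read"]],
      s_precision = best$sc$sub_scores[["precision"]],
      s_star = best$sc$sub_scores[["star"]],
      confidence = classify_confidence(best$sc$score, cfg),
      dominant_seq = best$sc$dominant_seq,
      dominant_len = best$sc$dominant_len,
      dominant_arm = best$sc$dominant_arm,
      star_support = best$sc$star_support,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, preds[!vapply(preds, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(locus_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), precursor_seq = character(),
                      score = integer(), confidence = character())
  rownames(out) <- NULL
  out
}

## duplex statistics along the pairing path under a read span: interior
## loop events (any unpaired gap on either side between consecutive paired
## read positions, with size summed over both sides) and G:U wobble count.
## A genuine mature forms a near-contiguous, near-Watson-Crick duplex with
## the opposite arm: point substitutions open size-2 internal loops or
## single wobbles, while chance stems in random sequence are held together
## by large asymmetric loops and a high wobble load.
## Returns c(n_events, max_size, n_wobbles).
duplex_events <- function(partner, a, b, chars = NULL) {
  p <- which(partner[a:b] > 0) + a - 1L
  if (length(p) == 0) return(c(0L, 0L, 0L))
  wob <- if (is.null(chars)) 0L else {
    x <- chars[p]; y <- chars[partner[p]]
    sum((x == "G" & y == "T") | (x == "T" & y == "G"))
  }
  if (length(p) < 2) return(c(0L, 0L, wob))
  gaps <- (p[-1] - p[-length(p)] - 1L) +
    (abs(partner[p[-length(p)]] - partner[p[-1]]) - 1L)
  c(sum(gaps > 0), max(0L, gaps), wob)
}

## lexicographic "key a beats key b": TRUE iff at the first differing
## position a exceeds b
key_beats <- function(a, b) {
  d <- which(a != b)
  length(d) > 0 && a[d[1]] > b[d[1]]
}
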