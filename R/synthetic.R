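## Synthetic small-RNA study generator.
##
## Emits a toy genome with planted miRNA precursors, gene models, decoy
## ncRNA/repeat elements, reference databases and per-tissue FASTQ libraries
## carrying the statistical structure the analysis assumes: a 22-nt modal
## insert length with a second 27-nt mode in gonadal libraries, isomiR end
## shifts of 1-2 nt, a small set of dominant families, and
## specific/predominant/ubiquitous tissue profiles.

#' Configuration for the synthetic genome
#'
#' @param n_chrom,chrom_len chromosome count and length (nt)
#' @param n_hairpins planted miRNA precursors
#' @param frac_intergenic,frac_intronic,frac_exonic structural placement mix
#'   (largest-remainder allocation so counts are exact)
#' @param frac_known fraction of hairpins present in the toy known-miRNA
#'   databases; the rest exercise the novel-prediction path
#' @param arm_range,loop_len_range stem-arm and terminal-loop lengths used to
#'   build precursors (precursor length stays within 60-80 nt)
#' @param max_arm_mut substitutions introduced in the 3' arm (imperfect stems)
#' @param n_genes_per_chrom toy gene models per chromosome
#' @param n_decoy_rrna,n_decoy_trna,n_decoy_other decoy ncRNA elements planted
#'   once each; decoys carry an embedded hairpin so loci built on their
#'   fragments are foldable and reach the annotation stage
#' @param repeat_copies_frequent copies of the high-copy repeat element
#'   (fragments exceed the mapping repetitiveness cap)
#' @param repeat_copies_sparse copies of the low-copy repeat element
#'   (fragments form loci that annotate as repeat)
#' @param mirna_in_other_db also place one known precursor in the
#'   other-ncRNA database to exercise the multi-annotation category
#' @param margin minimum distance between planted features (nt)
#' @param max_attempts placement attempts per feature before erroring
#' @return a list of class `sim_genome_config`
#' @export
sim_genome_config <- function(n_chrom = 3, chrom_len = 50000, n_hairpins = 20,
                              frac_intergenic = 0.8, frac_intronic = 0.15,
                              frac_exonic = 0.05, frac_known = 0.7,
                              arm_range = c(26, 30), loop_len_range = c(6, 12),
                              max_arm_mut = 2, n_genes_per_chrom = 2,
                              n_decoy_rrna = 2, n_decoy_trna = 2,
                              n_decoy_other = 2,
                              repeat_copies_frequent = 18,
                              repeat_copies_sparse = 2,
                              mirna_in_other_db = TRUE,
                              margin = 200, max_attempts = 200) {
  cfg <- as.list(environment())
  fr <- c(frac_intergenic, frac_intronic, frac_exonic)
  check_that(all(fr >= 0) && abs(sum(fr) - 1) < 1e-8,
             "structural fractions must be non-negative and sum to 1")
  class(cfg) <- "sim_genome_config"
  cfg
}

## largest-remainder integer allocation of n into shares
allocate_counts <- function(n, shares) {
  raw <- n * shares
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

## build one imperfect hairpin precursor; returns list(seq, mature coords).
## mlen_fixed pins the mature length (used for the dominant families, whose
## real-world archetypes miR-21/miR-146 are canonical 22-mers)
build_precursor <- function(cfg, mlen_fixed = NULL) {
  repeat {
    s <- sample(cfg$arm_range[1]:cfg$arm_range[2], 1)
    l <- sample(cfg$loop_len_range[1]:cfg$loop_len_range[2], 1)
    if (2 * s + l >= 60 && 2 * s + l <= 80) break
  }
  arm5 <- random_dna(1, s)
  arm3 <- revcomp(arm5)
  nmut <- sample(0:cfg$max_arm_mut, 1)
  if (nmut > 0 && s > 8) {
    pos <- sample(4:(s - 3), nmut)
    ch <- strsplit(arm3, "")[[1]]
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    arm3 <- paste(ch, collapse = "")
  }
  prec <- paste0(arm5, random_dna(1, l), arm3)
  n <- nchar(prec)
  arm <- sample(c("5p", "3p"), 1)
  ## canonical mature length distribution peaks sharply at 22 nt
  mlen <- mlen_fixed %||%
    sample(20:24, 1, prob = c(0.04, 0.14, 0.62, 0.14, 0.06))
  off <- sample(0:2, 1)
  if (arm == "5p") {
    ms <- 1 + off; me <- off + mlen
  } else {
    me <- n - off; ms <- n - off - mlen + 1
  }
  ## star: mirrored interval on the opposite arm
  if (arm == "5p") {
    ss <- n - off - mlen + 1; se <- n - off
  } else {
    ss <- 1 + off; se <- off + mlen
  }
  list(seq = prec, arm = arm, mstart = ms, mend = me, sstart = ss, send = se)
}

## sequence with an embedded perfect hairpin at its centre (used for decoys)
hairpin_bearing_seq <- function(total_len, arm = 24, loop = 7) {
  core <- paste0(a5 <- random_dna(1, arm), random_dna(1, loop), revcomp(a5))
  pad <- total_len - nchar(core)
  left <- pad %/% 2
  paste0(random_dna(1, left), core, random_dna(1, pad - left))
}

#' Generate a synthetic genome with planted miRNA loci and databases
#'
#' Chromosomes are uniform random DNA into which toy gene models, miRNA
#' precursors, decoy ncRNAs and repeat elements are planted without overlap
#' (minimum separation `cfg$margin`). Every planted precursor is verified to
#' fold into a single stem-loop before emission, so recovery tests are
#' well-posed. Known matures are split across two overlapping databases to
#' exercise database merging and provenance tracking.
#'
#' @param cfg a [sim_genome_config()]
#' @param seed integer random seed
#' @return a list of class `sim_genome`: `genome` (DNAStringSet), `genes`
#'   (GRanges with a `type` column: gene/exon/five_prime_UTR/three_prime_UTR),
#'   `truth` (data.frame of planted loci, 0-based half-open coordinates),
#'   `known_db1`/`known_db2` (mature miRNA DNAStringSets), `rrna_db`,
#'   `trna_db`, `other_db`, `repeat_db`, `decoy_positions`, `config`
#' @export
sim_genome <- function(cfg = sim_genome_config(), seed = 1) {
  set.seed(seed)
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  seqs <- random_dna(cfg$n_chrom, cfg$chrom_len)
  names(seqs) <- chroms

  ## --- toy gene models -------------------------------------------------
  feats <- list()
  for (ci in seq_len(cfg$n_chrom)) {
    slots <- floor(cfg$chrom_len / (cfg$n_genes_per_chrom + 0.5))
    for (g in seq_len(cfg$n_genes_per_chrom)) {
      gstart <- (g - 1) * slots + sample(500:1500, 1)        # 0-based
      strand <- sample(c("+", "-"), 1)
      ex_len <- sample(250:400, 3, replace = TRUE)
      int_len <- sample(700:1200, 2, replace = TRUE)
      e1s <- gstart
      e1e <- e1s + ex_len[1]
      e2s <- e1e + int_len[1]; e2e <- e2s + ex_len[2]
      e3s <- e2e + int_len[2]; e3e <- e3s + ex_len[3]
      gid <- sprintf("gene_%d_%d", ci, g)
      feats[[length(feats) + 1]] <- data.frame(
        chrom = chroms[ci],
        start = c(e1s, e1s, e2s, e3s, e1s, e3e - 120),
        end   = c(e3e, e1e, e2e, e3e, e1s + 80, e3e),
        strand = strand,
        type = c("gene", "exon", "exon", "exon",
                 "five_prime_UTR", "three_prime_UTR"),
        id = c(gid, paste0(gid, ".e", 1:3), paste0(gid, ".u5"),
               paste0(gid, ".u3")))
    }
  }
  feats <- do.call(rbind, feats)

  ## --- compartment regions (0-based half-open) -------------------------
  genes <- feats[feats$type == "gene", ]
  exons <- feats[feats$type == "exon", ]
  regions <- list(intergenic = NULL, intron = NULL, exon = NULL)
  for (ci in seq_len(cfg$n_chrom)) {
    g <- genes[genes$chrom == chroms[ci], ]
    g <- g[order(g$start), ]
    bounds <- c(cfg$margin, as.vector(rbind(g$start - cfg$margin,
                                            g$end + cfg$margin)),
                cfg$chrom_len - cfg$margin)
    ig <- matrix(bounds, ncol = 2, byrow = TRUE)
    regions$intergenic <- rbind(regions$intergenic,
      data.frame(chrom = chroms[ci], start = ig[, 1], end = ig[, 2]))
    for (k in seq_len(nrow(g))) {
      e <- exons[exons$chrom == chroms[ci] & exons$start >= g$start[k] &
                   exons$end <= g$end[k], ]
      e <- e[order(e$start), ]
      regions$intron <- rbind(regions$intron, data.frame(
        chrom = chroms[ci], start = e$end[-nrow(e)] + 10,
        end = e$start[-1] - 10))
      mid <- e[2, ]                     # middle exon, clear of UTRs
      regions$exon <- rbind(regions$exon, data.frame(
        chrom = chroms[ci], start = mid$start + 5, end = mid$end - 5))
    }
  }

  occupied <- data.frame(chrom = character(), start = integer(),
                         end = integer())
  place_in <- function(regs, len) {
    w <- regs$end - regs$start - len
    ok <- which(w > 0)
    for (a in seq_len(cfg$max_attempts)) {
      ri <- ok[sample.int(length(ok), 1, prob = w[ok])]
      st <- regs$start[ri] + sample.int(w[ri], 1)
      hit <- occupied$chrom == regs$chrom[ri] &
        occupied$start < st + len + cfg$margin &
        occupied$end > st - cfg$margin
      if (!any(hit)) {
        occupied <<- rbind(occupied, data.frame(
          chrom = regs$chrom[ri], start = st, end = st + len))
        return(list(chrom = regs$chrom[ri], start = st))
      }
    }
    stop("could not place a planted feature without overlap; ",
         "reduce feature count or enlarge the genome", call. = FALSE)
  }
  plant <- function(chrom, start0, seq, strand) {
    ins <- if (strand == "+") seq else revcomp(seq)
    substr(seqs[[chrom]], start0 + 1, start0 + nchar(seq)) <<- ins
  }

  ## --- hairpins ---------------------------------------------------------
  n_cat <- allocate_counts(cfg$n_hairpins, c(cfg$frac_intergenic,
                                             cfg$frac_intronic,
                                             cfg$frac_exonic))
  cats <- rep(c("intergenic", "intron", "exon"), n_cat)
  truth <- NULL
  for (i in seq_along(cats)) {
    hp <- NULL
    mfix <- if (cfg$n_hairpins >= 5 && i <= 5) 22L else NULL
    for (a in seq_len(cfg$max_attempts)) {
      cand <- build_precursor(cfg, mlen_fixed = mfix)
      if (fold_hairpin(cand$seq)$foldable) { hp <- cand; break }
    }
    check_that(!is.null(hp), "failed to build a foldable precursor")
    pos <- place_in(regions[[cats[i]]], nchar(hp$seq))
    strand <- sample(c("+", "-"), 1)
    plant(pos$chrom, pos$start, hp$seq, strand)
    truth <- rbind(truth, data.frame(
      locus_id = sprintf("mir_t%02d", i), chrom = pos$chrom,
      start = pos$start, end = pos$start + nchar(hp$seq), strand = strand,
      precursor_seq = hp$seq, mature_arm = hp$arm,
      mature_start = hp$mstart, mature_end = hp$mend,
      star_start = hp$sstart, star_end = hp$send,
      mature_seq = substr(hp$seq, hp$mstart, hp$mend),
      star_seq = substr(hp$seq, hp$sstart, hp$send),
      structural_class = cats[i], stringsAsFactors = FALSE))
  }
  if (!is.null(truth)) {
    ## families: two dominant multi-locus families, the rest singleton
    n <- nrow(truth)
    fam <- paste0("fam-", sprintf("%02d", seq_len(n)))
    if (n >= 5) {
      fam[1:3] <- "mir-A"
      fam[4:5] <- "mir-B"
    }
    truth$family <- fam
    nk <- allocate_counts(n, c(cfg$frac_known, 1 - cfg$frac_known))[1]
    truth$is_known <- seq_len(n) %in% sample.int(n, nk)
  } else {
    truth <- data.frame(locus_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        strand = character(), precursor_seq = character(),
                        mature_arm = character(), mature_start = integer(),
                        mature_end = integer(), star_start = integer(),
                        star_end = integer(), mature_seq = character(),
                        star_seq = character(),
                        structural_class = character(),
                        family = character(), is_known = logical())
  }

  ## --- decoys and repeats ----------------------------------------------
  decoy_pos <- NULL
  plant_decoy <- function(seq, id, db) {
    pos <- place_in(regions$intergenic, nchar(seq))
    plant(pos$chrom, pos$start, seq, "+")
    decoy_pos <<- rbind(decoy_pos, data.frame(
      id = id, db = db, chrom = pos$chrom, start = pos$start,
      end = pos$start + nchar(seq)))
  }
  mk_db <- function(n, len, prefix, db) {
    if (n == 0) return(Biostrings::DNAStringSet())
    s <- vapply(seq_len(n), function(i) hairpin_bearing_seq(len),
                character(1))
    names(s) <- paste0(prefix, seq_len(n))
    for (i in seq_len(n)) plant_decoy(s[i], names(s)[i], db)
    Biostrings::DNAStringSet(s)
  }
  rrna_db <- mk_db(cfg$n_decoy_rrna, 200, "rRNA_", "rrna")
  trna_db <- mk_db(cfg$n_decoy_trna, 75, "tRNA_", "trna")
  other_db <- mk_db(cfg$n_decoy_other, 120, "snoRNA_", "other_ncrna")

  rep_seqs <- c(rep_hi = random_dna(1, 150),
                rep_lo = hairpin_bearing_seq(150))
  repeat_db <- Biostrings::DNAStringSet(rep_seqs)
  for (k in seq_len(cfg$repeat_copies_frequent))
    plant_decoy(rep_seqs[["rep_hi"]], "rep_hi", "repeat")
  for (k in seq_len(cfg$repeat_copies_sparse))
    plant_decoy(rep_seqs[["rep_lo"]], "rep_lo", "repeat")

  ## --- known-miRNA databases -------------------------------------------
  known <- truth[truth$is_known, , drop = FALSE]
  db1 <- db2 <- character()
  if (nrow(known)) {
    memb <- sample(c("both", "db1", "db2"), nrow(known), replace = TRUE,
                   prob = c(0.6, 0.2, 0.2))
    nm <- paste0("omy-", known$family, "-", known$locus_id)
    db1 <- setNames(known$mature_seq[memb != "db2"], nm[memb != "db2"])
    db2 <- setNames(known$mature_seq[memb != "db1"], nm[memb != "db1"])
  }
  other_extra <- Biostrings::DNAStringSet()
  if (cfg$mirna_in_other_db && nrow(known) > 0) {
    other_extra <- Biostrings::DNAStringSet(
      setNames(known$precursor_seq[1],
               paste0("snoRNA_like_", known$locus_id[1])))
  }

  out <- list(
    genome = Biostrings::DNAStringSet(seqs),
    genes = GenomicRanges::GRanges(
      feats$chrom, IRanges::IRanges(feats$start + 1, feats$end),
      strand = feats$strand, type = feats$type, ID = feats$id),
    truth = truth,
    known_db1 = Biostrings::DNAStringSet(db1),
    known_db2 = Biostrings::DNAStringSet(db2),
    rrna_db = rrna_db, trna_db = trna_db,
    other_db = c(other_db, other_extra),
    repeat_db = repeat_db,
    decoy_positions = decoy_pos,
    config = cfg, seed = seed)
  class(out) <- "sim_genome"
  out
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("sim_genome:", length(x$genome), "chromosomes,",
      nrow(x$truth), "planted miRNA loci,",
      length(x$known_db1), "+", length(x$known_db2),
      "known matures in the two databases\n")
  invisible(x)
}

#' Default library specifications for a six-tissue study
#'
#' Four somatic and two gonadal libraries. Gonadal libraries carry a
#' piRNA-like 26-28 nt read population so the insert-length histogram is
#' bimodal (modes 22 and 27); all libraries carry filter-rejected noise and
#' a small decoy-ncRNA read component.
#'
#' @param n_reads reads per library
#' @param noise_fraction fraction of reads rejected by the cleaning filters
#' @param pirna_fraction gonadal piRNA-like read fraction
#' @param decoy_fraction decoy ncRNA/repeat fragment read fraction
#' @param base_seed per-library seeds are `base_seed + library index`
#' @return data.frame of library specifications
#' @export
default_library_specs <- function(n_reads = 50000, noise_fraction = 0.1,
                                  pirna_fraction = 0.45,
                                  decoy_fraction = 0.05, base_seed = 100) {
  tissues <- c("brain", "muscle", "liver", "skin", "testis", "ovary")
  gon <- tissues %in% c("testis", "ovary")
  data.frame(
    name = paste0("lib_", tissues), tissue = tissues, is_gonadal = gon,
    n_reads = n_reads, pirna_fraction = ifelse(gon, pirna_fraction, 0),
    noise_fraction = noise_fraction, decoy_fraction = decoy_fraction,
    seed = base_seed + seq_along(tissues), stringsAsFactors = FALSE)
}

#' Assign expected per-library counts to planted loci
#'
#' Loci receive a family weight (the two dominant families take ~30% and
#' ~15% of pooled signal, emulating the strong family skew of real small-RNA
#' data) and a tissue profile shape: tissue-specific (one library),
#' tissue-predominant (~70% in one library) or ubiquitous. Expected counts
#' are `weight * shape * signal depth`; gonad-specific loci prefer gonadal
#' libraries.
#'
#' @param sim a [sim_genome()]
#' @param lib_specs data.frame from [default_library_specs()]
#' @param profile_mix proportions of specific/predominant/ubiquitous loci
#' @param family_shares pooled count share of the two dominant families
#' @param seed integer seed
#' @return matrix of expected counts, loci x libraries
#' @export
assign_expression <- function(sim, lib_specs,
                              profile_mix = c(specific = 0.4,
                                              predominant = 0.3,
                                              ubiquitous = 0.3),
                              family_shares = c(0.30, 0.15), seed = 1) {
  set.seed(seed)
  truth <- sim$truth
  n <- nrow(truth)
  nl <- nrow(lib_specs)
  lam <- matrix(0, n, nl, dimnames = list(truth$locus_id, lib_specs$name))
  if (n == 0) return(lam)
  w <- numeric(n)
  famA <- truth$family == "mir-A"
  famB <- truth$family == "mir-B"
  if (any(famA)) w[famA] <- family_shares[1] / sum(famA)
  if (any(famB)) w[famB] <- family_shares[2] / sum(famB)
  rest <- !(famA | famB)
  if (any(rest)) w[rest] <- (1 - sum(w)) / sum(rest)

  ## dominant families are broadly expressed (as the top families are in
  ## real multi-tissue data); profile types are drawn for the rest
  counts <- allocate_counts(n, profile_mix)
  ptype <- sample(rep(c("specific", "predominant", "ubiquitous"), counts))
  ptype[famA | famB] <- "ubiquitous"
  home <- sample.int(nl, n, replace = TRUE)
  shape <- matrix(1, n, nl)
  for (i in seq_len(n)) {
    if (ptype[i] == "specific") {
      shape[i, ] <- 0; shape[i, home[i]] <- nl
    } else if (ptype[i] == "predominant") {
      shape[i, ] <- 0.3 * nl / (nl - 1); shape[i, home[i]] <- 0.7 * nl
    }
  }
  sig <- lib_specs$n_reads * (1 - lib_specs$noise_fraction -
                                lib_specs$pirna_fraction -
                                lib_specs$decoy_fraction)
  for (j in seq_len(nl)) lam[, j] <- w * shape[, j] * sig[j]
  attr(lam, "profile_type") <- setNames(ptype, truth$locus_id)
  lam
}

## categorical end-shift distribution: P(0)=.6, P(|1|)=.3, P(|2|)=.1,
## applied independently at the 5' and 3' ends
sample_shifts <- function(n) {
  sample(c(-2L, -1L, 0L, 1L, 2L), n, replace = TRUE,
         prob = c(0.05, 0.15, 0.6, 0.15, 0.05))
}

#' Simulate one small-RNA FASTQ library
#'
#' Per-locus read counts are Poisson with the configured expectation. Each
#' signal read is an isomiR of the planted mature (or, at `star_fraction`,
#' of the star arm) with independent 5' and 3' end shifts in {0, +/-1, +/-2};
#' the raw read is `insert + adapter` truncated to `read_len`. Gonadal
#' libraries add a 26-28 nt piRNA-like population drawn from random genome
#' positions; noise reads (homopolymers, N-containing reads, 36-nt
#' adapter-free junk) are all rejected by the cleaning filters; decoy reads
#' are fragments of the planted ncRNA/repeat elements. Base quality is
#' constant (the pipeline never uses it).
#'
#' @param sim a [sim_genome()]
#' @param lam named numeric vector of expected counts for this library
#'   (a column of [assign_expression()])
#' @param spec one row of [default_library_specs()] (list or data.frame row)
#' @param adapter 3' adapter sequence
#' @param read_len raw read length
#' @param star_fraction fraction of locus reads drawn from the star arm
#' @return a list of class `sim_library`: `reads`, `ids`, `truth` (per-read
#'   sidecar: source, insert length, truncated-insert flag), `spec`
#' @export
sim_library <- function(sim, lam, spec, adapter = "ATCTCGTATGCCGTCTTCTGCTTG",
                        read_len = 36, star_fraction = 0.1) {
  spec <- as.list(spec)
  set.seed(spec$seed)
  truth <- sim$truth
  inserts <- character(0); src <- character(0)

  ## signal reads
  if (nrow(truth)) {
    nloc <- rpois(nrow(truth), lam[truth$locus_id])
    for (i in seq_len(nrow(truth))) {
      if (nloc[i] == 0) next
      star <- runif(nloc[i]) < star_fraction
      a <- ifelse(star, truth$star_start[i], truth$mature_start[i]) +
        sample_shifts(nloc[i])
      b <- ifelse(star, truth$star_end[i], truth$mature_end[i]) +
        sample_shifts(nloc[i])
      a <- pmax(1, a); b <- pmin(nchar(truth$precursor_seq[i]), b)
      ins <- substr(rep(truth$precursor_seq[i], nloc[i]), a, b)
      inserts <- c(inserts, ins)
      src <- c(src, rep(truth$locus_id[i], nloc[i]))
    }
  }

  ## piRNA-like population (gonadal only)
  n_pi <- if (isTRUE(spec$is_gonadal)) rpois(1, spec$pirna_fraction *
                                               spec$n_reads) else 0
  if (n_pi > 0) {
    lens <- sample(26:28, n_pi, replace = TRUE, prob = c(0.25, 0.5, 0.25))
    ci <- sample.int(length(sim$genome), n_pi, replace = TRUE)
    pos <- floor(runif(n_pi) * (Biostrings::width(sim$genome)[ci] - 30)) + 1
    frag <- substr(as.character(sim$genome)[ci], pos, pos + lens - 1)
    flip <- runif(n_pi) < 0.5
    frag[flip] <- revcomp(frag[flip])
    inserts <- c(inserts, frag)
    src <- c(src, rep("pirna", n_pi))
  }

  ## decoy ncRNA / repeat fragments: few distinct fragments, reused heavily
  dbs <- list(rrna = sim$rrna_db, trna = sim$trna_db,
              other_ncrna = sim$other_db, repeat_db = sim$repeat_db)
  pool <- character(0)
  for (db in dbs) {
    for (s in as.character(db)) {
      L <- nchar(s); mid <- floor(L / 2)
      for (k in 1:3) {
        fl <- sample(19:24, 1)
        st <- max(1, mid - fl + sample(0:fl, 1))
        pool <- c(pool, substr(s, st, min(L, st + fl - 1)))
      }
    }
  }
  n_dec <- if (length(pool)) rpois(1, spec$decoy_fraction * spec$n_reads)
           else 0
  if (n_dec > 0) {
    inserts <- c(inserts, sample(pool, n_dec, replace = TRUE))
    src <- c(src, rep("decoy", n_dec))
  }

  ## noise rejected by the cleaning filters
  n_noise <- rpois(1, spec$noise_fraction * spec$n_reads)
  noise_reads <- character(0); noise_src <- character(0)
  if (n_noise > 0) {
    kind <- sample(c("homopolymer", "with_n", "junk36"), n_noise,
                   replace = TRUE, prob = c(0.4, 0.3, 0.3))
    for (k in which(kind == "homopolymer")) {
      nt <- sample(c("A", "C", "G", "T"), 2)
      L <- sample(16:28, 1)
      noise_reads <- c(noise_reads, paste(
        sample(nt, L, replace = TRUE, prob = c(0.8, 0.2)), collapse = ""))
    }
    for (k in which(kind == "with_n")) {
      s <- random_dna(1, sample(18:26, 1))
      p <- sample.int(nchar(s), sample(1:3, 1))
      for (q in p) substr(s, q, q) <- "N"
      noise_reads <- c(noise_reads, s)
    }
    noise_reads <- c(noise_reads, random_dna(sum(kind == "junk36"), 36))
    noise_src <- c(rep("noise_homopolymer", sum(kind == "homopolymer")),
                   rep("noise_n", sum(kind == "with_n")),
                   rep("noise_junk", sum(kind == "junk36")))
  }

  truncated <- nchar(inserts) > read_len
  raw <- substr(paste0(inserts, adapter,
                       strrep("A", read_len)), 1, read_len)
  junk_is_raw <- noise_src == "noise_junk"
  noise_raw <- ifelse(junk_is_raw, noise_reads,
                      substr(paste0(noise_reads, adapter,
                                    strrep("A", read_len)), 1, read_len))
  all_raw <- c(raw, noise_raw)
  all_src <- c(src, noise_src)
  all_ins <- c(nchar(inserts), nchar(noise_reads))
  all_trunc <- c(truncated, rep(FALSE, length(noise_raw)))

  ord <- sample.int(length(all_raw))
  out <- list(
    reads = all_raw[ord],
    ids = sprintf("%s_%06d", spec$name, seq_along(all_raw)),
    truth = data.frame(id = sprintf("%s_%06d", spec$name,
                                    seq_along(all_raw)),
                       source = all_src[ord], insert_len = all_ins[ord],
                       truncated_insert = all_trunc[ord],
                       stringsAsFactors = FALSE),
    spec = spec)
  class(out) <- "sim_library"
  out
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper: genome + databases, expression assignment, and one
#' simulated library per specification row.
#'
#' @param genome_cfg a [sim_genome_config()]
#' @param lib_specs data.frame from [default_library_specs()]
#' @param seed master seed (genome and expression; library seeds come from
#'   `lib_specs$seed`)
#' @param ... passed to [sim_library()]
#' @return list of class `sim_dataset`: `genome_sim`, `expression`
#'   (expected-count matrix), `libraries` (list of `sim_library`)
#' @export
sim_dataset <- function(genome_cfg = sim_genome_config(),
                        lib_specs = default_library_specs(), seed = 1, ...) {
  gs <- sim_genome(genome_cfg, seed = seed)
  lam <- assign_expression(gs, lib_specs, seed = seed + 1)
  libs <- lapply(seq_len(nrow(lib_specs)), function(j) {
    sim_library(gs, lam[, j], lib_specs[j, ], ...)
  })
  names(libs) <- lib_specs$name
  structure(list(genome_sim = gs, expression = lam, libraries = libs,
                 lib_specs = lib_specs),
            class = "sim_dataset")
}
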