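## Independent oracles used to cross-check the implementation. These are
## deliberately naive: brute-force scans, quadratic merges and memoized
## recursive enumeration, kept free of the code paths they verify.

## complement a single sequence without Biostrings
rc_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

## --- exact mapping: scan every genome position on both strands ----------
oracle_map <- function(seqs, genome_chr) {
  out <- NULL
  for (si in seq_along(seqs)) {
    sq <- seqs[si]
    w <- nchar(sq)
    rcq <- rc_chr(sq)
    for (cn in names(genome_chr)) {
      g <- genome_chr[[cn]]
      L <- nchar(g)
      if (L < w) next
      starts <- 1:(L - w + 1)
      subs <- substring(g, starts, starts + w - 1)
      for (p in starts[subs == sq])
        out <- rbind(out, data.frame(seq = sq, chrom = cn, start = p - 1,
                                     end = p - 1 + w, strand = "+"))
      for (p in starts[subs == rcq])
        out <- rbind(out, data.frame(seq = sq, chrom = cn, start = p - 1,
                                     end = p - 1 + w, strand = "-"))
    }
  }
  out
}

## --- locus building: quadratic union-find over all alignment pairs ------
oracle_merge <- function(aln, gap) {
  n <- nrow(aln)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    if (aln$chrom[i] != aln$chrom[j] || aln$strand[i] != aln$strand[j])
      next
    if (aln$start[j] > aln$end[i] + gap || aln$start[i] > aln$end[j] + gap)
      next
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <- rj
  }
  vapply(seq_len(n), find, integer(1))
}

## two partitions of the same items are identical up to label names
same_partition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

## --- folding: memoized recursive enumeration over all stem anchors ------
oracle_fold_score <- function(seq, loop_min = 3, loop_max = 20,
                              max_gap = 4, open = 4, ext = 1) {
  s <- strsplit(toupper(gsub("U", "T", seq)), "")[[1]]
  n <- length(s)
  pw <- function(a, b) {
    k <- paste0(a, b)
    if (k %in% c("GC", "CG")) 3
    else if (k %in% c("AT", "TA")) 2
    else if (k %in% c("GT", "TG")) 1
    else -1
  }
  memo <- matrix(NA_real_, n, n)
  best_from <- function(i, j) {
    if (!is.na(memo[i, j])) return(memo[i, j])
    p <- pw(s[i], s[j])
    if (p < 0) { memo[i, j] <<- -Inf; return(-Inf) }
    best <- -Inf
    if ((j - i - 1) >= loop_min && (j - i - 1) <= loop_max) best <- 0
    for (a in 0:max_gap) for (b in 0:max_gap) {
      ii <- i + 1 + a; jj <- j - 1 - b
      if (ii >= jj) next
      v <- best_from(ii, jj)
      if (is.finite(v)) {
        pen <- if (a == 0 && b == 0) 0 else open + ext * (a + b)
        best <- max(best, v - pen)
      }
    }
    memo[i, j] <<- if (is.finite(best)) p + best else -Inf
    memo[i, j]
  }
  sc <- -Inf
  for (i in 1:(n - 1)) for (j in (i + 1):n) sc <- max(sc, best_from(i, j))
  if (is.finite(sc)) sc else NA_real_
}

## --- conservation: position-by-position Hamming scan --------------------
oracle_hamming_scan <- function(pattern, genome_chr, max_mm) {
  out <- NULL
  for (cn in names(genome_chr)) {
    g <- strsplit(genome_chr[[cn]], "")[[1]]
    L <- length(g)
    for (pat_strand in list(c(pattern, "+"), c(rc_chr(pattern), "-"))) {
      p <- strsplit(pat_strand[1], "")[[1]]
      w <- length(p)
      if (L < w) next
      mm <- integer(L - w + 1)
      for (k in seq_len(w))
        mm <- mm + (g[k:(L - w + k)] != p[k])
      for (pos in which(mm <= max_mm))
        out <- rbind(out, data.frame(chrom = cn, start = pos - 1,
                                     end = pos - 1 + w,
                                     strand = pat_strand[2],
                                     mismatches = mm[pos]))
    }
  }
  out
}

## --- adapter trimming: exhaustive candidate enumeration ------------------
oracle_trim_pos <- function(read, adapter, rate = 0.1, min_overlap = 3) {
  L <- nchar(read)
  al <- nchar(adapter)
  rch <- strsplit(read, "")[[1]]
  ach <- strsplit(adapter, "")[[1]]
  best <- -1; bestp <- -1
  for (p in 0:(L - min_overlap)) {
    m <- min(al, L - p)
    mis <- sum(rch[(p + 1):(p + m)] != ach[1:m])
    if (mis > floor(rate * m + 1e-9)) next
    sc <- m - 2 * mis
    if (sc > best) { best <- sc; bestp <- p }
  }
  bestp
}
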