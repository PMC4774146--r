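## Exact full-length placement of unique sequences on the genome and
## merging of placements into candidate loci.

#' Map unique sequences to the genome by exact full-length matching
#'
#' Every exact occurrence on both strands is found (Biostrings pattern
#' matching per width group). A sequence with more than `max_hits` total
#' occurrences is considered repetitive: it contributes no alignments and is
#' listed separately. Sequences containing non-ACGT characters are skipped
#' with a warning.
#'
#' @param uniques data.frame with `seq_id`, `seq` and `pooled_count` columns
#'   (as produced by [collapse_and_threshold()]), or a character vector of
#'   sequences
#' @param genome named DNAStringSet (or named character vector)
#' @param max_hits repetitiveness cap (default 15)
#' @return list with `alignments` (data.frame: `seq_id`, `seq`, `chrom`,
#'   `start`, `end` 0-based half-open, `strand`, `n_total_hits`,
#'   `pooled_count`), `repetitive` (seq_id, n_hits) and `skipped`
#' @export
map_exact <- function(uniques, genome, max_hits = 15) {
  if (is.character(uniques))
    uniques <- data.frame(seq_id = paste0("u", seq_along(uniques)),
                          seq = uniques,
                          pooled_count = 1L, stringsAsFactors = FALSE)
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  check_that(!is.null(names(genome)), "genome sequences must be named")
  bad <- !grepl("^[ACGT]+$", uniques$seq)
  if (any(bad))
    warning(sum(bad), " sequence(s) with non-ACGT characters skipped")
  u <- uniques[!bad, , drop = FALSE]
  empty_aln <- data.frame(seq_id = character(), seq = character(),
                          chrom = character(), start = integer(),
                          end = integer(), strand = character(),
                          n_total_hits = integer(),
                          pooled_count = integer())
  if (nrow(u) == 0)
    return(list(alignments = empty_aln,
                repetitive = data.frame(seq_id = character(),
                                        n_hits = integer()),
                skipped = uniques$seq_id[bad]))

  chrom_names <- names(genome)
  rc_genome <- Biostrings::reverseComplement(genome)
  hits <- vector("list", nrow(u))
  for (w in unique(nchar(u$seq))) {
    idx <- which(nchar(u$seq) == w)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(u$seq[idx]))
    for (ci in seq_along(genome)) {
      L <- Biostrings::width(genome)[ci]
      fwd <- Biostrings::matchPDict(pd, genome[[ci]])
      rev <- Biostrings::matchPDict(pd, rc_genome[[ci]])
      for (k in seq_along(idx)) {
        f <- fwd[[k]]; r <- rev[[k]]
        rows <- NULL
        if (length(f))
          rows <- data.frame(chrom = chrom_names[ci],
                             start = BiocGenerics::start(f) - 1L,
                             end = BiocGenerics::end(f), strand = "+")
        if (length(r))
          rows <- rbind(rows, data.frame(
            chrom = chrom_names[ci],
            start = L - BiocGenerics::end(r),
            end = L - BiocGenerics::start(r) + 1L, strand = "-"))
        if (!is.null(rows))
          hits[[idx[k]]] <- rbind(hits[[idx[k]]], rows)
      }
    }
  }
  n_hits <- vapply(hits, function(h) if (is.null(h)) 0L else nrow(h),
                   integer(1))
  repet <- n_hits > max_hits
  aln <- lapply(which(n_hits > 0 & !repet), function(k) {
    cbind(data.frame(seq_id = u$seq_id[k], seq = u$seq[k]), hits[[k]],
          n_total_hits = n_hits[k], pooled_count = u$pooled_count[k])
  })
  aln <- if (length(aln)) do.call(rbind, aln) else empty_aln
  rownames(aln) <- NULL
  list(alignments = aln,
       repetitive = data.frame(seq_id = u$seq_id[repet],
                               n_hits = n_hits[repet]),
       skipped = uniques$seq_id[bad])
}

#' Merge alignments into candidate loci
#'
#' Loci are the connected components of the relation "same chromosome and
#' strand, separated by at most `merge_gap` nt", where the gap between two
#' placements is `next start - previous end` (bases between them; the merge
#' is inclusive at the gap, so 70 merges and 71 splits at the default).
#'
#' @param alignments data.frame as returned by [map_exact()]
#' @param merge_gap maximum separating gap, inclusive (default 70)
#' @return list with `loci` (data.frame: `locus_id`, `chrom`, `start`,
#'   `end`, `strand`, `n_members`, `n_sequences`, `total_count`,
#'   `dominant_seq`, `dominant_start`, `dominant_end`) sorted by
#'   (chrom, start, strand), and `alignments` with a `locus_id` column
#' @export
build_loci <- function(alignments, merge_gap = 70) {
  check_that(merge_gap >= 0, "merge_gap must be >= 0")
  empty <- data.frame(locus_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), n_members = integer(),
                      n_sequences = integer(), total_count = integer(),
                      dominant_seq = character(),
                      dominant_start = integer(), dominant_end = integer())
  if (is.null(alignments) || nrow(alignments) == 0)
    return(list(loci = empty, alignments = alignments))
  a <- alignments[order(alignments$chrom, alignments$strand,
                        alignments$start, alignments$end), ]
  grp <- integer(nrow(a))
  gid <- 0L
  cur_end <- -Inf; cur_chrom <- ""; cur_strand <- ""
  for (i in seq_len(nrow(a))) {
    if (a$chrom[i] != cur_chrom || a$strand[i] != cur_strand ||
        a$start[i] - cur_end > merge_gap) {
      gid <- gid + 1L
      cur_end <- a$end[i]
    } else {
      cur_end <- max(cur_end, a$end[i])
    }
    cur_chrom <- a$chrom[i]; cur_strand <- a$strand[i]
    grp[i] <- gid
  }
  a$locus_id <- grp
  loci <- do.call(rbind, lapply(split(a, grp), function(m) {
    dom <- m[order(-m$pooled_count, m$start, m$seq), ][1, ]
    data.frame(chrom = m$chrom[1], start = min(m$start), end = max(m$end),
               strand = m$strand[1], n_members = nrow(m),
               n_sequences = length(unique(m$seq_id)),
               total_count = sum(m$pooled_count),
               dominant_seq = dom$seq, dominant_start = dom$start,
               dominant_end = dom$end)
  }))
  ord <- order(loci$chrom, loci$start, loci$strand)
  loci <- loci[ord, ]
  loci$locus_id <- sprintf("locus_%05d", seq_len(nrow(loci)))
  remap <- setNames(loci$locus_id, rownames(loci))
  a$locus_id <- remap[as.character(a$locus_id)]
  rownames(loci) <- rownames(a) <- NULL
  loci <- loci[, c("locus_id", setdiff(names(loci), "locus_id"))]
  list(loci = loci, alignments = a)
}

#' Per-position read depth of a locus
#'
#' Sums the pooled counts of member alignments over the positions they
#' cover.
#'
#' @param locus one row of the `loci` table from [build_loci()]
#' @param alignments the locus-annotated alignment table
#' @return integer vector of depth, one entry per locus position
#' @export
locus_stack_profile <- function(locus, alignments) {
  m <- alignments[alignments$locus_id == locus$locus_id, , drop = FALSE]
  depth <- integer(locus$end - locus$start)
  for (i in seq_len(nrow(m))) {
    rel <- (m$start[i] - locus$start + 1):(m$end[i] - locus$start)
    depth[rel] <- depth[rel] + m$pooled_count[i]
  }
  depth
}
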