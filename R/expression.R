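## Expression profiling: locus/isomiR count matrices with CPM, family
## abundance, read-length profiles, tissue clustering and qPCR correlation.

#' Build a locus- or isomiR-level expression matrix
#'
#' At isomiR level every assigned unique sequence is a row; at locus level
#' member counts are summed per locus. Counts-per-million are computed per
#' library over the matrix's own column totals; all-zero libraries get a
#' zero CPM column and are flagged.
#'
#' @param uniques unique-sequence table from [collapse_and_threshold()]
#'   (per-library count columns)
#' @param assignment data.frame mapping `seq_id` to `locus_id`; unique
#'   sequences without an assignment are excluded. Typically derived from
#'   [build_loci()] alignments via [assign_uniques()].
#' @param level "isomir" or "locus"
#' @return list of class `expr_matrix`: `counts`, `cpm` (matrices, rows x
#'   libraries), `level`, `row_locus` (row id to locus id),
#'   `empty_libraries`
#' @export
build_matrix <- function(uniques, assignment, level = c("isomir", "locus")) {
  level <- match.arg(level)
  libs <- setdiff(names(uniques), c("seq_id", "seq", "pooled_count"))
  m <- merge(uniques, assignment[, c("seq_id", "locus_id")], by = "seq_id")
  if (level == "isomir") {
    ids <- m$seq_id
    check_that(!anyDuplicated(ids), "duplicate row ids")
    counts <- as.matrix(m[, libs, drop = FALSE])
    rownames(counts) <- ids
    row_locus <- setNames(m$locus_id, ids)
  } else {
    counts <- rowsum(as.matrix(m[, libs, drop = FALSE]), m$locus_id)
    row_locus <- setNames(rownames(counts), rownames(counts))
  }
  tot <- colSums(counts)
  empty <- tot == 0
  cpm <- sweep(counts, 2, ifelse(empty, 1, tot), "/") * 1e6
  cpm[, empty] <- 0
  structure(list(counts = counts, cpm = cpm, level = level,
                 row_locus = row_locus,
                 empty_libraries = names(tot)[empty]),
            class = "expr_matrix")
}

#' Assign unique sequences to loci
#'
#' A unique sequence is assigned to the locus of its alignment; a sequence
#' aligning within several loci is assigned to the locus with the highest
#' total count (ties: first by coordinate order).
#'
#' @param alignments locus-annotated alignment table from [build_loci()]
#' @param loci the loci table (for the tie-break by total count)
#' @return data.frame with `seq_id`, `locus_id`
#' @export
assign_uniques <- function(alignments, loci) {
  pri <- setNames(loci$total_count, loci$locus_id)
  a <- alignments[order(alignments$seq_id,
                        -pri[alignments$locus_id]), , drop = FALSE]
  a <- a[!duplicated(a$seq_id), c("seq_id", "locus_id")]
  rownames(a) <- NULL
  a
}

#' Family abundance table
#'
#' Per-family fraction of total counts, pooled and per library. Families
#' reaching `min_fraction` of the pooled total are listed individually; the
#' remainder (and rows without a family label) aggregate into "other".
#'
#' @param mat an `expr_matrix` from [build_matrix()]
#' @param family_map named character vector: row id -> family label
#' @param min_fraction listing threshold on the pooled fraction
#' @return data.frame with `family`, `pooled_fraction` and one fraction
#'   column per library; fractions sum to 1 per column
#' @export
family_abundance <- function(mat, family_map, min_fraction = 0.01) {
  fam <- family_map[rownames(mat$counts)]
  fam[is.na(fam)] <- "other"
  by_fam <- rowsum(mat$counts, fam)
  pooled <- rowSums(by_fam) / sum(by_fam)
  keep <- pooled >= min_fraction & rownames(by_fam) != "other"
  main <- by_fam[keep, , drop = FALSE]
  other <- colSums(by_fam[!keep, , drop = FALSE])
  tab <- rbind(main, other = other)
  out <- data.frame(family = rownames(tab),
                    pooled_fraction = rowSums(tab) / sum(tab),
                    stringsAsFactors = FALSE)
  per <- sweep(tab, 2, pmax(1, colSums(tab)), "/")
  colnames(per) <- paste0("frac_", colnames(per))
  out <- cbind(out, as.data.frame(per))
  out <- out[order(-out$pooled_fraction), ]
  rownames(out) <- NULL
  out
}

#' Read-length profile of a cleaned library
#'
#' Histogram of insert lengths plus detected modes: a length bin strictly
#' greater than both neighbours (absent neighbours count 0) holding at
#' least `min_mode_fraction` of the reads.
#'
#' @param reads character vector of cleaned reads (or integer lengths)
#' @param range lengths tabulated (bins outside are still counted at the
#'   range edges' neighbours for mode detection)
#' @param min_mode_fraction minimum share of reads for a mode
#' @return list of class `length_profile`: `histogram` (named counts),
#'   `modes` (integer vector), `total`
#' @export
length_profile <- function(reads, range = 16:28, min_mode_fraction = 0.05) {
  len <- if (is.character(reads)) nchar(reads) else as.integer(reads)
  lv <- sort(unique(c(range, len)))
  h <- table(factor(len, levels = lv))
  counts <- as.integer(h)
  total <- sum(counts)
  padded <- c(0L, counts, 0L)
  is_mode <- counts > padded[seq_along(counts)] &
    counts > padded[seq_along(counts) + 2] &
    counts >= min_mode_fraction * total
  structure(list(histogram = setNames(counts, lv),
                 modes = lv[is_mode], total = total),
            class = "length_profile")
}

#' Unsupervised tissue clustering
#'
#' Rows are log2(CPM + 1), median-centered; the distance is 1 - Pearson
#' correlation; linkage is average. Rows and columns are sorted by id
#' before clustering so the leaf ordering is deterministic and invariant to
#' input order; zero-variance rows are dropped with a warning.
#'
#' @param mat an `expr_matrix`
#' @param libraries libraries to cluster (e.g. one per tissue); default all
#' @return list of class `tissue_clustering`: `row_hclust`, `col_hclust`,
#'   `row_order`, `col_order`, `centered` (the clustered matrix),
#'   `dropped_rows`
#' @export
cluster_tissues <- function(mat, libraries = colnames(mat$cpm)) {
  x <- log2(mat$cpm[, libraries, drop = FALSE] + 1)
  x <- x[order(rownames(x)), order(colnames(x)), drop = FALSE]
  check_that(nrow(x) >= 2 && ncol(x) >= 2,
             "need at least 2 rows and 2 columns")
  v <- apply(x, 1, function(r) stats::var(r))
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance row(s) dropped")
    x <- x[v > 0, , drop = FALSE]
  }
  check_that(nrow(x) >= 2, "fewer than 2 rows with variance")
  x <- sweep(x, 1, apply(x, 1, median), "-")
  dr <- as.dist(1 - cor(t(x)))
  dc <- as.dist(1 - cor(x))
  hr <- hclust(dr, method = "average")
  hc <- hclust(dc, method = "average")
  structure(list(row_hclust = hr, col_hclust = hc,
                 row_order = rownames(x)[hr$order],
                 col_order = colnames(x)[hc$order],
                 centered = x,
                 dropped_rows = names(v)[v == 0]),
            class = "tissue_clustering")
}

#' Export a clustering tree as Newick
#'
#' @param hc an `hclust` (e.g. `col_hclust` of [cluster_tissues()])
#' @param path output file
#' @return the path, invisibly
#' @export
write_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Correlate sequencing expression with qPCR abundance
#'
#' Per miRNA, Pearson correlation of log-transformed paired values over the
#' shared tissues; miRNAs with fewer than 3 shared tissues are skipped with
#' a warning.
#'
#' @param seq_mat numeric matrix, miRNAs x tissues (e.g. CPM rows)
#' @param qpcr_tab numeric matrix or data.frame, miRNAs x tissues of
#'   relative abundances (already normalised upstream)
#' @param pseudocount added before the log to keep zeros finite
#' @return data.frame with `mirna`, `n` (shared tissues), `r`
#' @export
correlate_qpcr <- function(seq_mat, qpcr_tab, pseudocount = 1e-8) {
  qpcr_tab <- as.matrix(qpcr_tab)
  shared_t <- intersect(colnames(seq_mat), colnames(qpcr_tab))
  shared_m <- intersect(rownames(seq_mat), rownames(qpcr_tab))
  out <- NULL
  for (m in shared_m) {
    t_ok <- shared_t[!is.na(qpcr_tab[m, shared_t])]
    if (length(t_ok) < 3) {
      warning("miRNA ", m, " skipped: fewer than 3 shared tissues")
      next
    }
    x <- log2(as.numeric(seq_mat[m, t_ok]) + pseudocount)
    y <- log2(as.numeric(qpcr_tab[m, t_ok]) + pseudocount)
    out <- rbind(out, data.frame(mirna = m, n = length(t_ok),
                                 r = cor(x, y)))
  }
  if (is.null(out))
    out <- data.frame(mirna = character(), n = integer(), r = numeric())
  rownames(out) <- NULL
  out
}
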