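## Annotation of predicted precursors against reference databases, the
## functional partition (repeat / other ncRNA / miRNA / novel), and
## structural classification against gene models.

#' Merge two miRNA databases into one with provenance
#'
#' Records with identical sequences in both databases are collapsed into a
#' single record carrying both provenances; the provenance later drives the
#' both / database-1-only / database-2-only breakdown of miRNA-annotated
#' predictions.
#'
#' @param db1,db2 named DNAStringSets (ids unique within each database)
#' @return DNAStringSet with metadata columns `source` ("db1", "db2" or
#'   "both") and `alt_id` (the collapsed partner id, if any)
#' @export
merge_mirna_dbs <- function(db1, db2) {
  check_that(!anyDuplicated(names(db1)), "duplicate id in db1")
  check_that(!anyDuplicated(names(db2)), "duplicate id in db2")
  s1 <- as.character(db1); s2 <- as.character(db2)
  shared2 <- s2 %in% s1
  src <- c(ifelse(s1 %in% s2, "both", "db1"), rep("db2", sum(!shared2)))
  alt <- c(unname(vapply(s1, function(s) {
    hit <- names(db2)[s2 == s]
    if (length(hit)) hit[1] else NA_character_
  }, character(1))), rep(NA_character_, sum(!shared2)))
  merged <- Biostrings::DNAStringSet(c(s1, s2[!shared2]))
  names(merged) <- c(names(db1), names(db2)[!shared2])
  S4Vectors::mcols(merged) <- S4Vectors::DataFrame(source = src,
                                                   alt_id = alt)
  merged
}

## best local alignment of query vs subject on both strands; returns
## identity over the aligned region and aligned fraction of the shorter seq
best_local_hit <- function(query, subject) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  best <- NULL
  for (q in c(query, revcomp(query))) {
    al <- Biostrings::pairwiseAlignment(q, subject, type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = 5, gapExtension = 2)
    alen <- Biostrings::nchar(Biostrings::alignedPattern(al))
    if (alen == 0) next
    nmatch <- Biostrings::nmatch(al)
    cand <- list(identity = nmatch / alen,
                 aligned_fraction = alen / min(nchar(query),
                                               nchar(subject)),
                 mismatches = alen - nmatch)
    if (is.null(best) || cand$identity * cand$aligned_fraction >
        best$identity * best$aligned_fraction) best <- cand
  }
  best
}

#' Annotate precursor sequences against reference databases
#'
#' Non-repeat databases are searched by local alignment (both strands); a
#' hit is reported when identity is at least `min_identity` over at least
#' `min_cov` of the shorter of query and subject. The repeat database is
#' matched separately and requires a perfect full-length occurrence (the
#' precursor inside the repeat element, or the element inside the
#' precursor, on either strand).
#'
#' @param precursors named character vector or DNAStringSet of predicted
#'   precursor sequences
#' @param dbs named list of DNAStringSets; recognised names are
#'   `mirna_merged`, `rrna`, `trna`, `other_ncrna`, `repeat`
#' @param min_identity,min_cov hit thresholds for non-repeat databases
#' @return data.frame of hits: `query_id`, `db_name`, `subject_id`,
#'   `identity`, `aligned_fraction`, `mismatches`
#' @export
annotate_against_dbs <- function(precursors, dbs, min_identity = 0.9,
                                 min_cov = 0.8) {
  if (methods::is(precursors, "DNAStringSet"))
    precursors <- setNames(as.character(precursors), names(precursors))
  hits <- list()
  add <- function(qid, db, sid, id, af, mm) {
    hits[[length(hits) + 1]] <<- data.frame(
      query_id = qid, db_name = db, subject_id = sid, identity = id,
      aligned_fraction = af, mismatches = mm, stringsAsFactors = FALSE)
  }
  for (qi in seq_along(precursors)) {
    q <- precursors[[qi]]
    qid <- names(precursors)[qi]
    for (db in names(dbs)) {
      ref <- dbs[[db]]
      if (length(ref) == 0) next
      refs <- as.character(ref)
      if (db == "repeat") {
        qrc <- revcomp(q)
        for (si in seq_along(refs)) {
          s <- refs[si]
          perfect <- grepl(q, s, fixed = TRUE) ||
            grepl(qrc, s, fixed = TRUE) ||
            grepl(s, q, fixed = TRUE) || grepl(revcomp(s), q, fixed = TRUE)
          if (perfect)
            add(qid, db, names(ref)[si], 1, 1, 0L)
        }
      } else {
        for (si in seq_along(refs)) {
          h <- best_local_hit(q, refs[si])
          if (!is.null(h) && h$identity >= min_identity &&
              h$aligned_fraction >= min_cov)
            add(qid, db, names(ref)[si], h$identity, h$aligned_fraction,
                h$mismatches)
        }
      }
    }
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(query_id = character(), db_name = character(),
               subject_id = character(), identity = numeric(),
               aligned_fraction = numeric(), mismatches = integer())
}

#' Partition predictions into functional categories
#'
#' Mutually exclusive, exhaustive categories with precedence
#' repeat > other_ncrna > mirna_multi > mirna_only > novel: a perfect repeat
#' match discards the prediction; any non-miRNA ncRNA hit without a miRNA
#' hit discards it as other ncRNA; a miRNA hit plus any other ncRNA hit is
#' multi-annotated; a miRNA hit alone is miRNA-only (broken down by merged
#' database provenance); no hits is novel. Predictions with both repeat and
#' other-ncRNA evidence are counted once in the discard pool; the overlap is
#' reported.
#'
#' @param prediction_ids character vector of prediction ids
#' @param hits hit table from [annotate_against_dbs()]
#' @param mirna_db merged miRNA database from [merge_mirna_dbs()] (used for
#'   the provenance breakdown; optional)
#' @return list with `categories` (data.frame: `query_id`, `category`,
#'   `mirna_source`) and `accounting` (named list of every count)
#' @export
partition_predictions <- function(prediction_ids, hits, mirna_db = NULL) {
  cat_of <- character(length(prediction_ids))
  src_of <- rep(NA_character_, length(prediction_ids))
  prov <- NULL
  if (!is.null(mirna_db))
    prov <- setNames(S4Vectors::mcols(mirna_db)$source, names(mirna_db))
  for (i in seq_along(prediction_ids)) {
    h <- hits[hits$query_id == prediction_ids[i], , drop = FALSE]
    has_rep <- any(h$db_name == "repeat")
    has_mir <- any(h$db_name == "mirna_merged")
    has_other <- any(!h$db_name %in% c("repeat", "mirna_merged"))
    cat_of[i] <- if (has_rep) "repeat"
      else if (has_other && !has_mir) "other_ncrna"
      else if (has_mir && has_other) "mirna_multi"
      else if (has_mir) "mirna_only"
      else "novel"
    if (cat_of[i] == "mirna_only" && !is.null(prov)) {
      ps <- unique(unname(prov[h$subject_id[h$db_name == "mirna_merged"]]))
      src_of[i] <- if ("both" %in% ps || all(c("db1", "db2") %in% ps))
        "both_dbs" else if (identical(ps, "db1")) "db1_only" else "db2_only"
    }
  }
  overlap <- sum(vapply(prediction_ids, function(id) {
    h <- hits[hits$query_id == id, , drop = FALSE]
    any(h$db_name == "repeat") &&
      any(!h$db_name %in% c("repeat", "mirna_merged"))
  }, logical(1)))
  acct <- list(
    n_predictions = length(prediction_ids),
    n_repeat = sum(cat_of == "repeat"),
    n_other_ncrna = sum(cat_of == "other_ncrna"),
    n_discarded = sum(cat_of %in% c("repeat", "other_ncrna")),
    n_repeat_and_other = overlap,
    n_remaining = sum(!cat_of %in% c("repeat", "other_ncrna")),
    n_mirna_annotated = sum(cat_of %in% c("mirna_multi", "mirna_only")),
    n_mirna_multi = sum(cat_of == "mirna_multi"),
    n_mirna_only = sum(cat_of == "mirna_only"),
    n_mirna_both_dbs = sum(src_of == "both_dbs", na.rm = TRUE),
    n_mirna_db1_only = sum(src_of == "db1_only", na.rm = TRUE),
    n_mirna_db2_only = sum(src_of == "db2_only", na.rm = TRUE),
    n_novel = sum(cat_of == "novel"))
  list(categories = data.frame(query_id = prediction_ids,
                               category = cat_of, mirna_source = src_of,
                               stringsAsFactors = FALSE),
       accounting = acct)
}

#' Structural classification of loci against gene models
#'
#' Classifies each interval by any-overlap (at least 1 bp) precedence:
#' 5'UTR/3'UTR > exon > intron (inside a gene but outside its exons) >
#' intergenic. Gene-model strand is ignored: overlap on either strand
#' counts as genic.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) or a GRanges
#' @param gene_models GRanges with a `type` metadata column using
#'   gene/exon/five_prime_UTR/three_prime_UTR (e.g. from
#'   `rtracklayer::import` of a GFF3), or a path to a GFF3 file
#' @return character vector of categories: `utr5`, `utr3`, `exon`,
#'   `intron`, `intergenic`
#' @export
annotate_structural <- function(intervals, gene_models) {
  if (is.character(gene_models))
    gene_models <- rtracklayer::import(gene_models)
  if (!methods::is(intervals, "GRanges"))
    intervals <- GenomicRanges::GRanges(
      intervals$chrom, IRanges::IRanges(intervals$start + 1, intervals$end))
  type <- as.character(gene_models$type)
  known <- type %in% c("gene", "exon", "five_prime_UTR", "three_prime_UTR")
  if (any(!known)) {
    bad <- setdiff(unique(type), c("gene", "exon", "five_prime_UTR",
                                   "three_prime_UTR"))
    gene_models <- gene_models[known]
    type <- type[known]
    if (length(bad))
      warning("skipping gene-model features of type: ",
              paste(bad, collapse = ", "))
  }
  ov <- function(what) {
    IRanges::overlapsAny(intervals, gene_models[type == what],
                         ignore.strand = TRUE)
  }
  in_u5 <- ov("five_prime_UTR"); in_u3 <- ov("three_prime_UTR")
  in_ex <- ov("exon"); in_gene <- ov("gene")
  out <- rep("intergenic", length(intervals))
  out[in_gene] <- "intron"
  out[in_ex] <- "exon"
  out[in_u3] <- "utr3"
  out[in_u5] <- "utr5"
  out
}

#' Percentage breakdown of structural categories
#'
#' Percentages are `100 * count / total` rounded half-up to one decimal.
#'
#' @param counts named integer vector (or table) of category counts
#' @return data.frame with `category`, `count`, `percentage`
#' @export
summarize_structural <- function(counts) {
  counts <- unlist(as.list(counts))
  check_that(all(counts >= 0), "counts must be >= 0")
  total <- sum(counts)
  check_that(total > 0, "total count must be > 0")
  data.frame(category = names(counts), count = as.integer(counts),
             percentage = round_half_up(100 * counts / total, 1),
             row.names = NULL, stringsAsFactors = FALSE)
}
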