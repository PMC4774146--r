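## End-to-end orchestration and the flow-accounting report.

#' Pipeline configuration
#'
#' Collects all stage parameters. Sequence inputs may be given as loaded
#' objects (DNAStringSet, read vectors) or as file paths; [run_all()]
#' loads paths on demand.
#'
#' @param genome named DNAStringSet or FASTA path
#' @param gene_models GRanges with a `type` column or GFF3 path (optional)
#' @param libraries named list of raw-read character vectors or named
#'   vector of FASTQ paths
#' @param mirna_db1,mirna_db2 known-miRNA DNAStringSets or FASTA paths
#' @param rrna_db,trna_db,other_db,repeat_db reference databases
#' @param adapter,min_len,max_len,max_error_rate,min_pooled_count cleaning
#'   parameters (see [clean_libraries()])
#' @param max_hits,merge_gap mapping and locus parameters
#' @param scoring a [scoring_config()]
#' @param min_identity,min_cov annotation thresholds
#' @param panel optional conservation panel (named list of genomes or FASTA
#'   paths)
#' @param max_mismatch conservation substitution allowance
#' @param seed integer seed recorded with the run
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(genome, libraries, gene_models = NULL,
                            mirna_db1 = Biostrings::DNAStringSet(),
                            mirna_db2 = Biostrings::DNAStringSet(),
                            rrna_db = Biostrings::DNAStringSet(),
                            trna_db = Biostrings::DNAStringSet(),
                            other_db = Biostrings::DNAStringSet(),
                            repeat_db = Biostrings::DNAStringSet(),
                            adapter = "ATCTCGTATGCCGTCTTCTGCTTG",
                            min_len = 16, max_len = 28,
                            max_error_rate = 0.1, min_pooled_count = 1000,
                            max_hits = 15, merge_gap = 70,
                            scoring = scoring_config(),
                            min_identity = 0.9, min_cov = 0.8,
                            panel = NULL, max_mismatch = 2, seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Pipeline configuration for an in-memory synthetic dataset
#'
#' @param ds a [sim_dataset()]
#' @param min_pooled_count pooled threshold scaled for synthetic depth
#' @param ... further arguments to [pipeline_config()]
#' @return a `pipeline_config`
#' @export
pipeline_config_from_sim <- function(ds, min_pooled_count = 10, ...) {
  gs <- ds$genome_sim
  pipeline_config(
    genome = gs$genome,
    libraries = lapply(ds$libraries, `[[`, "reads"),
    gene_models = gs$genes,
    mirna_db1 = gs$known_db1, mirna_db2 = gs$known_db2,
    rrna_db = gs$rrna_db, trna_db = gs$trna_db, other_db = gs$other_db,
    repeat_db = gs$repeat_db, min_pooled_count = min_pooled_count, ...)
}

#' Load a pipeline configuration from a YAML file
#'
#' The file holds the same keys as [pipeline_config()] (sequence inputs as
#' file paths; `libraries` as a name-to-FASTQ map; `scoring` as a map of
#' [scoring_config()] overrides). Keys given in `...` override file keys.
#'
#' @param path YAML file
#' @param ... overrides passed through to [pipeline_config()]
#' @return a `pipeline_config`
#' @export
pipeline_config_from_yaml <- function(path, ...) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$scoring)) y$scoring <- do.call(scoring_config, y$scoring)
  if (!is.null(y$libraries)) y$libraries <- unlist(y$libraries)
  over <- list(...)
  y[names(over)] <- over
  do.call(pipeline_config, y)
}

load_seqs <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x))
    Biostrings::readDNAStringSet(x)
  else if (is.character(x)) Biostrings::DNAStringSet(x)
  else x
}

#' Run the complete discovery pipeline
#'
#' Cleaning, collapsing and thresholding; exact mapping with the
#' repetitiveness cap; locus building; hairpin prediction and scoring;
#' database annotation and functional partition; structural classification;
#' expression matrices, family abundance and length profiles; optional
#' conservation. Deterministic for a fixed configuration.
#'
#' @param config a [pipeline_config()]
#' @param out_dir optional directory for stage artifacts (TSV/BED/FASTA)
#' @return list of class `mirloci_run` with each stage's output and a
#'   `flow` report (see [flow_report()])
#' @export
run_all <- function(config, out_dir = NULL) {
  set.seed(config$seed)
  genome <- load_seqs(config$genome)
  libs <- config$libraries
  if (is.character(libs)) libs <- lapply(libs, read_fastq)

  cl <- clean_libraries(libs, adapter = config$adapter,
                        min_len = config$min_len, max_len = config$max_len,
                        max_error_rate = config$max_error_rate,
                        min_pooled_count = config$min_pooled_count)
  mp <- map_exact(cl$uniques, genome, max_hits = config$max_hits)
  bl <- build_loci(mp$alignments, merge_gap = config$merge_gap)
  preds <- predict_loci(bl$loci, bl$alignments, genome, config$scoring)

  mirna_db <- merge_mirna_dbs(load_seqs(config$mirna_db1),
                              load_seqs(config$mirna_db2))
  dbs <- list(mirna_merged = mirna_db, rrna = load_seqs(config$rrna_db),
              trna = load_seqs(config$trna_db),
              other_ncrna = load_seqs(config$other_db),
              "repeat" = load_seqs(config$repeat_db))
  prec <- setNames(preds$precursor_seq, preds$locus_id)
  hits <- annotate_against_dbs(prec, dbs, config$min_identity,
                               config$min_cov)
  part <- partition_predictions(preds$locus_id, hits, mirna_db)
  preds$category <- part$categories$category[
    match(preds$locus_id, part$categories$query_id)]

  if (!is.null(config$gene_models)) {
    gm <- config$gene_models
    if (is.character(gm)) gm <- rtracklayer::import(gm)
    preds$structural <- annotate_structural(
      preds[, c("chrom", "start", "end")], gm)
  }

  assignment <- assign_uniques(bl$alignments, bl$loci)
  mat <- build_matrix(cl$uniques, assignment, level = "isomir")
  prof <- lapply(libs, function(r) {
    k <- clean_library(r, adapter = config$adapter,
                       min_len = config$min_len, max_len = config$max_len,
                       max_error_rate = config$max_error_rate)$kept
    length_profile(k)
  })

  cons <- NULL
  if (!is.null(config$panel)) {
    mo <- preds[preds$category %in% c("mirna_only", "novel"), ,
                drop = FALSE]
    matures <- setNames(mo$dominant_seq, mo$locus_id)
    cons <- conservation_profiles(matures, config$panel,
                                  config$max_mismatch)
  }

  flow <- flow_report(cl, mp, bl, preds, part)
  run <- structure(list(cleaning = cl, mapping = mp, loci = bl$loci,
                        alignments = bl$alignments, predictions = preds,
                        hits = hits, partition = part, matrix = mat,
                        length_profiles = prof, conservation = cons,
                        flow = flow, config = config),
                   class = "mirloci_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

## artifact writer for a completed run
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(run$cleaning$per_library,
            file.path(out_dir, "cleaning_report.tsv"))
  write_collapsed_fasta(run$cleaning$uniques,
                        file.path(out_dir, "uniques.fa"))
  write_tsv(run$cleaning$uniques, file.path(out_dir, "counts.tsv"))
  write_tsv(run$alignments, file.path(out_dir, "alignments.tsv"))
  write_tsv(run$mapping$repetitive, file.path(out_dir, "repetitive.tsv"))
  write_bed(run$loci, file.path(out_dir, "loci.bed"))
  write_tsv(run$predictions, file.path(out_dir, "predictions.tsv"))
  if (nrow(run$predictions)) {
    s <- Biostrings::DNAStringSet(setNames(run$predictions$precursor_seq,
                                           run$predictions$locus_id))
    Biostrings::writeXStringSet(s, file.path(out_dir, "precursors.fa"))
    vienna <- as.vector(rbind(paste0(">", run$predictions$locus_id),
                              run$predictions$precursor_seq,
                              run$predictions$dotbracket))
    writeLines(vienna, file.path(out_dir, "precursors.vienna"))
  }
  write_tsv(run$hits, file.path(out_dir, "annotation_hits.tsv"))
  write_tsv(run$partition$categories,
            file.path(out_dir, "categories.tsv"))
  jsonlite::write_json(unclass(run$flow),
                       file.path(out_dir, "flow_report.json"),
                       auto_unbox = TRUE, digits = NA)
  ft <- data.frame(counter = names(unlist(run$flow)),
                   value = unlist(run$flow))
  write_tsv(ft, file.path(out_dir, "flow_report.tsv"))
  invisible(out_dir)
}

#' Assemble the stage-by-stage flow report
#'
#' Ordered counters mirroring the pipeline: raw reads, cleaned reads,
#' unique sequences before/after the pooled threshold, mapped fraction,
#' alignments, loci, predictions and the functional partition with the
#' high/low-confidence split of novel predictions, plus structural
#' breakdowns of the miRNA-only and novel sets when available. Every arrow
#' conserves items: outputs plus discards equal inputs.
#'
#' @param cl,mp,bl,preds,part stage outputs as produced inside [run_all()]
#' @return list of class `flow_report`
#' @export
flow_report <- function(cl, mp, bl, preds, part) {
  n_uniq <- nrow(cl$uniques)
  mapped_ids <- unique(mp$alignments$seq_id)
  novel_ids <- part$categories$query_id[part$categories$category == "novel"]
  novel_high <- sum(preds$confidence == "high" &
                      preds$locus_id %in% novel_ids)
  fl <- list(
    raw_reads = sum(cl$per_library$raw_reads),
    cleaned_reads = sum(cl$per_library$cleaned),
    unique_before_threshold = cl$report$unique_before_threshold,
    unique_after_threshold = cl$report$unique_after_threshold,
    n_mapped_uniques = length(mapped_ids),
    n_repetitive = nrow(mp$repetitive),
    mapped_fraction = if (n_uniq > 0)
      round(length(mapped_ids) / n_uniq, 4) else NA_real_,
    n_alignments = nrow(mp$alignments),
    n_loci = nrow(bl$loci),
    n_predictions = nrow(preds))
  fl <- c(fl, part$accounting[c("n_repeat", "n_other_ncrna", "n_discarded",
                                "n_remaining", "n_mirna_annotated",
                                "n_mirna_multi", "n_mirna_only",
                                "n_mirna_both_dbs", "n_mirna_db1_only",
                                "n_mirna_db2_only", "n_novel")])
  fl$n_novel_high <- novel_high
  fl$n_novel_low <- fl$n_novel - novel_high
  if (!is.null(preds$structural)) {
    mo <- preds$locus_id %in% part$categories$query_id[
      part$categories$category == "mirna_only"]
    nv <- preds$locus_id %in% novel_ids
    fl$structural_mirna_only <- as.list(table(preds$structural[mo]))
    fl$structural_novel <- as.list(table(preds$structural[nv]))
  }
  class(fl) <- "flow_report"
  fl
}

#' @export
print.flow_report <- function(x, ...) {
  flat <- unlist(unclass(x))
  cat("flow report:\n")
  for (nm in names(flat)) cat(sprintf("  %-28s %s\n", nm, flat[[nm]]))
  invisible(x)
}

#' Derived totals from the prediction/annotation accounting
#'
#' From the five primary counters - predictions, discarded (repeat or other
#' ncRNA), annotated as miRNA, multi-annotated among those, and
#' high-confidence novel - derives and cross-checks the repertoire
#' arithmetic: remaining = predictions - discarded; miRNA-only = annotated -
#' multi; novel = remaining - annotated; repertoire = miRNA-only + novel;
#' low-confidence novel = novel - high. Inconsistent counters raise an
#' error naming the violated identity.
#'
#' @param counters named list or `flow_report`; recognised names are
#'   `n_predictions`, `n_discarded`, `n_mirna_annotated`, `n_mirna_multi`,
#'   `n_novel_high`
#' @return data.frame of derived totals with one row per quantity
#' @export
report_totals <- function(counters) {
  g <- function(nm) {
    v <- counters[[nm]]
    check_that(!is.null(v) && !is.na(v), paste("missing counter", nm))
    as.numeric(v)
  }
  p <- g("n_predictions"); d <- g("n_discarded")
  ann <- g("n_mirna_annotated"); multi <- g("n_mirna_multi")
  high <- g("n_novel_high")
  check_that(d <= p, "violated identity: discarded <= predictions")
  remaining <- p - d
  check_that(ann <= remaining,
             "violated identity: annotated-as-miRNA <= remaining")
  check_that(multi <= ann,
             "violated identity: multi-annotated <= annotated-as-miRNA")
  mirna_only <- ann - multi
  novel <- remaining - ann
  check_that(high <= novel,
             "violated identity: high-confidence novel <= novel")
  repertoire <- mirna_only + novel
  low <- novel - high
  if (!is.null(counters[["n_novel"]]))
    check_that(novel == as.numeric(counters[["n_novel"]]),
               "violated identity: novel = remaining - annotated-as-miRNA")
  data.frame(
    quantity = c("remaining_after_discard", "novel", "mirna_only",
                 "repertoire_total", "novel_low_confidence"),
    value = c(remaining, novel, mirna_only, repertoire, low))
}
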