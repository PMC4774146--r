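## Readers and writers for the pipeline's external formats.

#' Read a FASTQ file as a character vector of reads
#'
#' Base qualities are ignored throughout the pipeline.
#' @param path FASTQ path (gzip transparent)
#' @return character vector of read sequences
#' @export
read_fastq <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' Write reads as FASTQ (Phred+33, constant quality)
#'
#' @param reads character vector
#' @param path output path
#' @param ids read ids (default sequential)
#' @param qual quality character used for every base
#' @return the path, invisibly
#' @export
write_fastq <- function(reads, path, ids = NULL, qual = "I") {
  if (is.null(ids)) ids <- sprintf("read_%06d", seq_along(reads))
  lines <- character(4 * length(reads))
  lines[seq(1, length(lines), 4)] <- paste0("@", ids)
  lines[seq(2, length(lines), 4)] <- reads
  lines[seq(3, length(lines), 4)] <- "+"
  lines[seq(4, length(lines), 4)] <- strrep(qual, nchar(reads))
  writeLines(lines, path)
  invisible(path)
}

#' Write collapsed unique sequences as FASTA
#'
#' Headers follow `>seq_id|pooled_count`.
#' @param uniques table from [collapse_and_threshold()]
#' @param path output path
#' @return the path, invisibly
#' @export
write_collapsed_fasta <- function(uniques, path) {
  s <- Biostrings::DNAStringSet(uniques$seq)
  names(s) <- paste0(uniques$seq_id, "|", uniques$pooled_count)
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

#' Write intervals as BED6
#'
#' @param df data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, plus `name` and `score` columns (or the columns named by
#'   `name_col` / `score_col`)
#' @param path output path
#' @param name_col,score_col columns used for the BED name and score
#' @return the path, invisibly
#' @export
write_bed <- function(df, path, name_col = "locus_id",
                      score_col = "total_count") {
  bed <- data.frame(df$chrom, df$start, df$end, df[[name_col]],
                    df[[score_col]], df$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a table as TSV
#' @param df data.frame
#' @param path output path
#' @return the path, invisibly
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic dataset to disk
#'
#' Emits genome FASTA, gene models as GFF3, truth BED6 and TSV, expected
#' expression TSV, all reference databases as FASTA and one FASTQ per
#' library.
#'
#' @param ds a [sim_dataset()]
#' @param dir output directory (created if needed)
#' @return named list of written paths, invisibly
#' @export
write_sim_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gs <- ds$genome_sim
  p <- list()
  fa <- function(x, f) {
    Biostrings::writeXStringSet(x, file.path(dir, f))
    file.path(dir, f)
  }
  p$genome <- fa(gs$genome, "genome.fa")
  p$gff <- file.path(dir, "genes.gff3")
  rtracklayer::export(gs$genes, p$gff, format = "gff3")
  tb <- gs$truth
  p$truth_bed <- file.path(dir, "truth.bed")
  tb$total_count <- 0L
  write_bed(tb, p$truth_bed, name_col = "locus_id")
  p$truth_tsv <- write_tsv(gs$truth, file.path(dir, "truth.tsv"))
  expr <- as.data.frame(ds$expression)
  expr <- cbind(locus_id = rownames(ds$expression), expr)
  p$expression <- write_tsv(expr, file.path(dir, "expression.tsv"))
  p$known_db1 <- fa(gs$known_db1, "known_mirna_db1.fa")
  p$known_db2 <- fa(gs$known_db2, "known_mirna_db2.fa")
  p$rrna <- fa(gs$rrna_db, "rrna.fa")
  p$trna <- fa(gs$trna_db, "trna.fa")
  p$other <- fa(gs$other_db, "other_ncrna.fa")
  p$repeats <- fa(gs$repeat_db, "repeats.fa")
  p$libraries <- vapply(names(ds$libraries), function(nm) {
    lib <- ds$libraries[[nm]]
    write_fastq(lib$reads, file.path(dir, paste0(nm, ".fastq")),
                ids = lib$truth$id)
  }, character(1))
  invisible(p)
}
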