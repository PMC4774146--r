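## Read cleaning: 3' adapter trimming, length/complexity filtering,
## collapsing to unique sequences with per-library counts, and the
## pooled-count threshold.

#' Trim the 3' adapter from reads
#'
#' Semi-global 3'-anchored search: the adapter prefix is matched at every
#' start position (full occurrence or 3'-terminal partial occurrence),
#' allowing mismatches up to `max_error_rate` of the matched length. The best
#' occurrence maximises matches minus twice the mismatches; ties are broken
#' towards the leftmost (longest-adapter) occurrence. Reads with no
#' acceptable occurrence are returned unchanged and flagged.
#'
#' @param reads character vector of raw reads
#' @param adapter 3' adapter sequence
#' @param max_error_rate allowed mismatch fraction of the matched length
#' @param min_overlap minimum matched adapter length considered
#' @return data.frame with `read`, `trimmed` (insert sequence) and
#'   `adapter_found` (logical)
#' @export
trim_adapter <- function(reads, adapter = "ATCTCGTATGCCGTCTTCTGCTTG",
                         max_error_rate = 0.1, min_overlap = 3) {
  check_that(length(reads) > 0 && all(nzchar(reads)), "reads must be non-empty")
  check_that(nzchar(adapter), "adapter must be non-empty")
  pos <- trim_positions_cpp(reads, adapter, max_error_rate, min_overlap)
  found <- pos >= 0
  trimmed <- reads
  trimmed[found] <- substr(reads[found], 1, pos[found])
  data.frame(read = reads, trimmed = trimmed, adapter_found = found,
             stringsAsFactors = FALSE)
}

#' Length, N and complexity filters for trimmed inserts
#'
#' A sequence passes when its length is within `[min_len, max_len]`
#' (inclusive), it contains no N, and it uses at least 3 distinct
#' nucleotides. Rejection reasons are checked in the order short, long,
#' has_n, low_complexity.
#'
#' @param seqs character vector over A/C/G/T/N
#' @param min_len,max_len inclusive length window
#' @return data.frame with `seq`, `pass`, `reason` (one of ok, short, long,
#'   has_n, low_complexity)
#' @export
passes_filters <- function(seqs, min_len = 16, max_len = 28) {
  L <- nchar(seqs)
  reason <- rep("ok", length(seqs))
  reason[L < min_len] <- "short"
  reason[reason == "ok" & L > max_len] <- "long"
  reason[reason == "ok" & grepl("N", seqs, fixed = TRUE)] <- "has_n"
  idx <- which(reason == "ok")
  if (length(idx))
    reason[idx[n_distinct_nt(seqs[idx]) < 3]] <- "low_complexity"
  data.frame(seq = seqs, pass = reason == "ok", reason = reason,
             stringsAsFactors = FALSE)
}

#' Clean one library: trim, filter, tally
#'
#' Untrimmed (no-adapter) reads are kept if they pass the filters, and
#' reported separately.
#'
#' @param reads character vector of raw reads
#' @param adapter 3' adapter
#' @param min_len,max_len length window
#' @param max_error_rate adapter-match error rate
#' @return list with `kept` (surviving insert sequences) and `stats`
#'   (one-row data.frame of the cleaning counters)
#' @export
clean_library <- function(reads, adapter = "ATCTCGTATGCCGTCTTCTGCTTG",
                          min_len = 16, max_len = 28, max_error_rate = 0.1) {
  ## collapse raw reads first: trimming is per-sequence, so unique raws
  ## suffice and the work scales with library complexity, not depth
  tab <- table(reads)
  uraw <- names(tab)
  cnt <- as.integer(tab)
  tr <- trim_adapter(uraw, adapter, max_error_rate)
  fl <- passes_filters(tr$trimmed, min_len, max_len)
  n_of <- function(keep) sum(cnt[keep])
  stats <- data.frame(
    raw_reads = sum(cnt),
    adapter_trimmed = n_of(tr$adapter_found),
    no_adapter = n_of(!tr$adapter_found),
    removed_short = n_of(fl$reason == "short"),
    removed_long = n_of(fl$reason == "long"),
    removed_N = n_of(fl$reason == "has_n"),
    removed_low_complexity = n_of(fl$reason == "low_complexity"),
    cleaned = n_of(fl$pass),
    no_adapter_kept = n_of(fl$pass & !tr$adapter_found))
  list(kept = rep(tr$trimmed[fl$pass], cnt[fl$pass]), stats = stats)
}

#' Collapse cleaned reads to unique sequences and apply the pooled threshold
#'
#' One record per distinct sequence with per-library counts; the pooled count
#' is summed over all libraries, and records below `min_pooled_count` are
#' dropped (the study-scale default is 1000; synthetic runs scale it down).
#'
#' @param cleaned named list of character vectors, one per library (the
#'   library order is fixed by the list order)
#' @param min_pooled_count pooled-count threshold; sequences with pooled
#'   count strictly below it are removed
#' @return list with `uniques` (data.frame: `seq_id`, `seq`, one count
#'   column per library, `pooled_count`), `dropped` (same shape, below
#'   threshold) and `report` (unique-sequence tallies)
#' @export
collapse_and_threshold <- function(cleaned, min_pooled_count = 1000) {
  libs <- names(cleaned)
  check_that(!is.null(libs) && all(nzchar(libs)),
             "cleaned must be a named list of per-library read vectors")
  all_seq <- unlist(cleaned, use.names = FALSE)
  if (length(all_seq) == 0) {
    empty <- data.frame(seq_id = character(), seq = character())
    for (l in libs) empty[[l]] <- integer()
    empty$pooled_count <- integer()
    return(list(uniques = empty, dropped = empty,
                report = data.frame(unique_before_threshold = 0L,
                                    unique_after_threshold = 0L)))
  }
  useq <- sort(unique(all_seq))
  counts <- vapply(cleaned, function(v) {
    t <- table(factor(v, levels = useq))
    as.integer(t)
  }, integer(length(useq)))
  counts <- matrix(counts, nrow = length(useq),
                   dimnames = list(NULL, libs))
  pooled <- as.integer(rowSums(counts))
  df <- data.frame(seq_id = sprintf("u%06d", seq_along(useq)), seq = useq,
                   stringsAsFactors = FALSE)
  for (l in libs) df[[l]] <- counts[, l]
  df$pooled_count <- pooled
  keep <- pooled >= min_pooled_count
  list(uniques = df[keep, , drop = FALSE],
       dropped = df[!keep, , drop = FALSE],
       report = data.frame(unique_before_threshold = nrow(df),
                           unique_after_threshold = sum(keep)))
}

#' Clean a set of libraries end to end
#'
#' @param read_sets named list of raw-read character vectors (one per
#'   library) or paths to FASTQ files (gzip transparent)
#' @param adapter,min_len,max_len,max_error_rate see [clean_library()]
#' @param min_pooled_count see [collapse_and_threshold()]
#' @return list with `uniques`, `dropped`, `per_library` (cleaning counters,
#'   one row per library) and `report`
#' @export
clean_libraries <- function(read_sets, adapter = "ATCTCGTATGCCGTCTTCTGCTTG",
                            min_len = 16, max_len = 28,
                            max_error_rate = 0.1, min_pooled_count = 1000) {
  if (is.character(read_sets))
    read_sets <- lapply(setNames(read_sets, names(read_sets)), read_fastq)
  per <- lapply(read_sets, clean_library, adapter = adapter,
                min_len = min_len, max_len = max_len,
                max_error_rate = max_error_rate)
  stats <- do.call(rbind, lapply(per, `[[`, "stats"))
  stats <- cbind(data.frame(library = names(read_sets)), stats)
  rownames(stats) <- NULL
  coll <- collapse_and_threshold(lapply(per, `[[`, "kept"),
                                 min_pooled_count)
  list(uniques = coll$uniques, dropped = coll$dropped,
       per_library = stats, report = coll$report)
}
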