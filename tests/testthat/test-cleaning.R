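adapter <- "ATCTCGTATGCCGTCTTCTGCTTG"

test_that("adapter trimming recovers inserts from 36-nt raw reads", {
  set.seed(1)
  ins22 <- paste(sample(c("A", "C", "G", "T"), 22, replace = TRUE),
                 collapse = "")
  raw <- substr(paste0(ins22, adapter), 1, 36)   # insert + 14 adapter bases
  tr <- trim_adapter(raw, adapter)
  expect_true(tr$adapter_found)
  expect_equal(tr$trimmed, ins22)

  ## 30-nt insert leaves only 6 adapter bases
  ins30 <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                 collapse = "")
  raw30 <- paste0(ins30, substr(adapter, 1, 6))
  tr30 <- trim_adapter(raw30, adapter)
  expect_true(tr30$adapter_found)
  expect_equal(tr30$trimmed, ins30)

  ## no adapter at all: returned unchanged and flagged
  clean36 <- strrep("ACGG", 9)
  tr0 <- trim_adapter(clean36, adapter)
  expect_false(tr0$adapter_found)
  expect_equal(tr0$trimmed, clean36)
})

test_that("trimming agrees with exhaustive candidate enumeration", {
  set.seed(2)
  reads <- character(120)
  for (i in seq_along(reads)) {
    ins <- paste(sample(c("A", "C", "G", "T"), sample(10:34, 1),
                        replace = TRUE), collapse = "")
    r <- substr(paste0(ins, adapter, strrep("A", 36)), 1, 36)
    ## sometimes inject a mismatch into the adapter portion
    if (runif(1) < 0.4 && nchar(ins) < 34) {
      p <- nchar(ins) + sample.int(min(8, 36 - nchar(ins)), 1)
      substr(r, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    reads[i] <- r
  }
  got <- trim_adapter(reads, adapter)
  got_len <- ifelse(got$adapter_found, nchar(got$trimmed), -1)
  exp_pos <- vapply(reads, oracle_trim_pos, numeric(1), adapter = adapter)
  expect_equal(got_len, unname(exp_pos))
})

test_that("length, N and complexity filters use inclusive boundaries", {
  seqs <- c(strrep("ACG", 5),            # 15 nt: short
            paste0(strrep("ACG", 5), "T"),  # 16 nt: pass
            strrep("ACGT", 7),           # 28 nt: pass
            paste0(strrep("ACGT", 7), "A"), # 29 nt: long
            "ACGTACGTNACGTACGT",         # N
            strrep("AC", 9),             # 2 distinct nucleotides
            "ACGTACGTACGTACGTACGTAC")    # clean 22-mer
  fl <- passes_filters(seqs)
  expect_equal(fl$reason, c("short", "ok", "ok", "long", "has_n",
                            "low_complexity", "ok"))
  expect_equal(fl$pass, fl$reason == "ok")
})

test_that("collapsing preserves per-library counts and pools them", {
  s <- "ACGTACGTACGTACGTACGTAC"
  libs <- list(a = rep(s, 5), b = rep(s, 5), c = rep(s, 5))
  cc <- collapse_and_threshold(libs, min_pooled_count = 1)
  expect_equal(nrow(cc$uniques), 1)
  expect_equal(unlist(cc$uniques[1, c("a", "b", "c")], use.names = FALSE),
               c(5L, 5L, 5L))
  expect_equal(cc$uniques$pooled_count, 15L)
})

test_that("the pooled threshold drops a count one below it", {
  s1 <- strrep("ACGT", 6)
  s2 <- paste0(strrep("GTCA", 5), "GT")
  libs <- list(x = c(rep(s1, 999), rep(s2, 600)),
               y = rep(s2, 400))
  cc <- collapse_and_threshold(libs, min_pooled_count = 1000)
  expect_equal(cc$uniques$seq, s2)           # 600 + 400 = 1000 kept
  expect_equal(cc$dropped$seq, s1)           # 999 dropped
  ## conservation: kept + dropped pooled counts = input reads
  expect_equal(sum(cc$uniques$pooled_count) + sum(cc$dropped$pooled_count),
               length(libs$x) + length(libs$y))
})

test_that("collapsing is order independent and the empty case is clean", {
  set.seed(3)
  reads <- sample(c(strrep("ACGT", 5), strrep("TGCA", 5),
                    "ACGTACGTACGTACGTACGTT"), 60, replace = TRUE)
  a <- collapse_and_threshold(list(l1 = reads), 1)
  b <- collapse_and_threshold(list(l1 = sample(reads)), 1)
  expect_equal(a$uniques, b$uniques)
  e <- collapse_and_threshold(list(l1 = character(0)), 5)
  expect_equal(nrow(e$uniques), 0)
  expect_equal(e$report$unique_before_threshold, 0)
})

test_that("noise injected by the generator is rejected at the stated rate", {
  ds <- small_sim(seed = 9, n_reads = 6000)
  lib <- ds$libraries$lib_muscle
  st <- clean_library(lib$reads)$stats
  rejected <- (st$removed_short + st$removed_long + st$removed_N +
                 st$removed_low_complexity) / st$raw_reads
  f <- ds$lib_specs$noise_fraction[ds$lib_specs$name == "lib_muscle"]
  expect_lt(abs(rejected - f), 0.03)
  expect_gte(st$raw_reads,
             st$cleaned + st$removed_short + st$removed_long +
               st$removed_N + st$removed_low_complexity)
})
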