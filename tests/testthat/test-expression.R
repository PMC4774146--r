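mk_uniques <- function() {
  data.frame(seq_id = c("u1", "u2", "u3"),
             seq = c(strrep("ACGT", 5), strrep("CAGT", 5),
                     strrep("GTCA", 5)),
             libA = c(10L, 30L, 2L), libB = c(0L, 6L, 4L),
             pooled_count = c(10L, 36L, 6L), stringsAsFactors = FALSE)
}
mk_assign <- function() data.frame(seq_id = c("u1", "u2", "u3"),
                                   locus_id = c("L1", "L1", "L2"))

test_that("isomiR and locus matrices sum counts correctly", {
  mi <- build_matrix(mk_uniques(), mk_assign(), level = "isomir")
  expect_equal(nrow(mi$counts), 3)
  ml <- build_matrix(mk_uniques(), mk_assign(), level = "locus")
  expect_equal(ml$counts["L1", "libA"], 40)
  expect_equal(ml$counts["L2", "libB"], 4)
  ## CPM columns sum to one million when the column has reads
  expect_equal(unname(colSums(mi$cpm)), c(1e6, 1e6))
  ## unassigned uniques are excluded
  a2 <- mk_assign()[1:2, ]
  expect_equal(nrow(build_matrix(mk_uniques(), a2, "isomir")$counts), 2)
})

test_that("an empty library column is flagged and zeroed", {
  u <- mk_uniques()
  u$libB <- 0L
  m <- build_matrix(u, mk_assign(), "isomir")
  expect_equal(m$empty_libraries, "libB")
  expect_true(all(m$cpm[, "libB"] == 0))
})

test_that("family abundance lists dominant families and pools the rest", {
  m <- build_matrix(mk_uniques(), mk_assign(), "locus")
  fmap <- c(L1 = "mir-X", L2 = "mir-Y")
  ab <- family_abundance(m, fmap, min_fraction = 0.5)
  expect_equal(ab$family, c("mir-X", "other"))
  expect_equal(sum(ab$pooled_fraction), 1)
  ## everything below the cut collapses into one row
  ab2 <- family_abundance(m, fmap, min_fraction = 1.0)
  expect_equal(ab2$family, "other")
  expect_equal(ab2$pooled_fraction, 1)
})

test_that("length profile finds strict local-maximum modes", {
  reads <- c(rep(strrep("A", 20), 4), rep(strrep("A", 22), 40),
             rep(strrep("A", 23), 10), rep(strrep("A", 27), 30),
             rep(strrep("A", 26), 8))
  lp <- length_profile(reads)
  expect_equal(lp$modes, c(22L, 27L))
  expect_equal(lp$total, length(reads))
  ## a flat histogram has no modes
  flat <- unlist(lapply(16:28, function(L) rep(strrep("A", L), 5)))
  expect_length(length_profile(flat)$modes, 0)
})

test_that("tissue clustering median-centres and is order invariant", {
  set.seed(31)
  counts <- matrix(rpois(80, 50), nrow = 10,
                   dimnames = list(paste0("r", sprintf("%02d", 1:10)),
                                   paste0("t", 1:8)))
  counts[1, ] <- counts[2, ] <- c(500, 400, 5, 5, 300, 2, 2, 450)
  mat <- list(counts = counts,
              cpm = sweep(counts, 2, colSums(counts), "/") * 1e6,
              level = "isomir")
  class(mat) <- "expr_matrix"
  cl <- cluster_tissues(mat)
  expect_true(all(abs(apply(cl$centered, 1, median)) < 1e-9))
  ## identical rows are merged first (distance zero)
  merged_first <- cl$row_hclust$merge[1, ]
  ids <- rownames(cl$centered)
  expect_setequal(ids[-merged_first], c("r01", "r02"))
  ## permuting input rows/columns leaves the result unchanged
  mat2 <- mat
  perm <- sample(nrow(counts)); permc <- sample(ncol(counts))
  mat2$counts <- counts[perm, permc]
  mat2$cpm <- mat$cpm[perm, permc]
  cl2 <- cluster_tissues(mat2)
  expect_equal(cl2$row_order, cl$row_order)
  expect_equal(cl2$col_order, cl$col_order)
  ## Newick export produces a readable tree over the libraries
  f <- tempfile()
  write_newick(cl$col_hclust, f)
  tree <- ape::read.tree(f)
  expect_setequal(tree$tip.label, colnames(counts))
  file.remove(f)
})

test_that("qPCR correlation is exact on identity and sign-reversal", {
  set.seed(32)
  m <- matrix(2^rnorm(27, 8, 2), nrow = 3,
              dimnames = list(c("mirA", "mirB", "mirC"), paste0("t", 1:9)))
  r1 <- correlate_qpcr(m, m)
  expect_equal(r1$r, rep(1, 3))
  ## anti-correlated pair on the log scale
  anti <- matrix(2^(-log2(m["mirA", , drop = FALSE])), nrow = 1,
                 dimnames = list("mirA", colnames(m)))
  r2 <- correlate_qpcr(m["mirA", , drop = FALSE], anti)
  expect_equal(r2$r, -1, tolerance = 1e-4)
  ## fewer than three shared tissues: skipped with a warning
  expect_warning(
    r3 <- correlate_qpcr(m[1, 1:2, drop = FALSE], m[1, 1:2, drop = FALSE]),
    "skipped")
  expect_equal(nrow(r3), 0)
})

test_that("noise attenuates the qPCR correlation as theory predicts", {
  set.seed(33)
  sd_x <- 2; sd_e <- 1
  n_t <- 12
  rs <- replicate(400, {
    z <- rnorm(n_t, 8, sd_x)
    correlate_qpcr(matrix(2^z, 1, dimnames = list("m", paste0("t", 1:n_t))),
                   matrix(2^(z + rnorm(n_t, 0, sd_e)), 1,
                          dimnames = list("m", paste0("t", 1:n_t))))$r
  })
  expected <- sd_x / sqrt(sd_x^2 + sd_e^2)
  expect_lt(abs(mean(rs) - expected), 0.03)
})
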