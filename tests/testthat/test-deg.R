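toy_matrix <- function(counts, reps = 2) {
  count_matrix(counts, rep(c("reference", "treatment"), each = ncol(counts) / 2))
}

test_that("count matrices are validated", {
  m <- matrix(1:12, nrow = 3)
  expect_s3_class(toy_matrix(m), "count_matrix")
  expect_error(count_matrix(m, rep("reference", 4)), "reference' or 'treatment|replicates")
  expect_error(count_matrix(m - 5, rep(c("reference", "treatment"), each = 2)), "non-negative")
  expect_error(count_matrix(m, c("reference", "treatment", "treatment", "treatment")), "two replicates")
})

test_that("median-of-ratios size factors behave on hand-checkable inputs", {
  base <- c(10, 50, 100, 500, 1000)
  m <- toy_matrix(cbind(base, base, base, base))
  expect_equal(size_factors(m), rep(1, 4), ignore_attr = TRUE)

  doubled <- toy_matrix(cbind(base, base, base, 2 * base))
  f <- size_factors(doubled)
  expect_equal(unname(f[4] / f[1]), 2) # the doubled sample's factor is twice the others
  expect_equal(prod(f)^(1 / 4), 1) # geometric mean one after rescaling

  single <- toy_matrix(matrix(c(10, 20, 40, 80), nrow = 1))
  f1 <- size_factors(single)
  expect_equal(f1 / f1[1], c(1, 2, 4, 8), ignore_attr = TRUE)

  zero_sample <- matrix(c(5, 0, 7, 3), nrow = 1)
  expect_error(size_factors(toy_matrix(zero_sample)), "all-zero")
})

test_that("the NB Wald test is null-centred and finds planted means", {
  set.seed(20)
  null <- toy_matrix(matrix(rep(c(100L, 200L, 400L), each = 6), nrow = 3, byrow = TRUE), 3)
  res <- nb_wald_test(null)
  expect_equal(res$log2fc, rep(0, 3))
  expect_true(all(res$pvalue > 0.99))

  # normalised means 400 vs 100 with pseudocount 0.5 -> log2FC just under 2
  m <- toy_matrix(cbind(100, 100, 100, 400, 400, 400))
  res <- nb_wald_test(m, factors = rep(1, 6))
  expect_equal(res$log2fc, log2(400.5 / 100.5), tolerance = 1e-12)
  expect_equal(res$log2fc, 2.0, tolerance = 0.01)

  # all-zero genes are flagged, not NaN
  z <- toy_matrix(rbind(c(5L, 6L, 4L, 9L, 8L, 7L), rep(0L, 6)))
  res <- nb_wald_test(z)
  expect_false(res$degenerate[1])
  expect_true(res$degenerate[2])
  expect_equal(res$pvalue[2], 1)
  expect_equal(res$log2fc[2], 0)
})

test_that("null NB counts give calibrated raw p-values (3 vs 3)", {
  sim <- generate_counts(synth_config(7, n_genes = 2000, deg_fraction = 0))
  res <- nb_wald_test(sim$matrix)
  frac <- mean(res$pvalue < 0.05)
  ci_half <- 2.58 * sqrt(0.05 * 0.95 / 2000) # binomial 99% CI around 0.05
  expect_gt(frac, 0.05 - ci_half)
  expect_lt(frac, 0.05 + ci_half)
})

test_that("Wald p-values agree in rank with an exhaustive permutation oracle", {
  sim <- generate_counts(synth_config(
    11, n_genes = 50, deg_fraction = 0.5, lfc_min = 1, lfc_max = 4
  ))
  m <- sim$matrix
  wald <- nb_wald_test(m)
  norm <- log2(sweep(m$counts, 2, size_factors(m), "/") + 0.5)
  combs <- utils::combn(6, 3)
  stat_for <- function(idx) {
    abs(rowMeans(norm[, idx, drop = FALSE]) - rowMeans(norm[, -idx, drop = FALSE]))
  }
  observed <- stat_for(which(m$condition == "treatment"))
  perm <- vapply(
    seq_len(ncol(combs)), function(k) stat_for(combs[, k]), numeric(nrow(norm))
  )
  p_perm <- rowMeans(perm >= observed - 1e-12)
  expect_gte(stats::cor(wald$pvalue, p_perm, method = "spearman"), 0.9)
})

test_that("the NB Wald stage agrees with an independent DE engine", {
  suppressMessages(library(DESeq2))
  sim <- generate_counts(synth_config(3, n_genes = 400, deg_fraction = 0.25))
  m <- sim$matrix
  mine <- nb_wald_test(m)
  dds <- DESeqDataSetFromMatrix(m$counts, data.frame(condition = m$condition), ~condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- DESeq2::results(dds, contrast = c("condition", "treatment", "reference"))
  ok <- !is.na(ref$pvalue)
  expect_gte(stats::cor(mine$log2fc[ok], ref$log2FoldChange[ok]), 0.99)
  expect_gte(stats::cor(mine$pvalue[ok], ref$pvalue[ok], method = "spearman"), 0.95)
})

test_that("BH adjustment matches hand-worked examples and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.5)), c(0.01, 0.5))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5)) # all equal: unchanged

  # oracle: the classic step-up procedure, decided from raw p-values
  step_up_rejects <- function(p, alpha) {
    m <- length(p)
    ord <- order(p)
    k <- which(p[ord] <= alpha * seq_len(m) / m)
    rejected <- logical(m)
    if (length(k)) rejected[ord[seq_len(max(k))]] <- TRUE
    rejected
  }
  set.seed(33)
  for (i in 1:10) {
    p <- stats::runif(sample(5:200, 1))^2
    adj <- bh_adjust(p)
    expect_equal(adj, stats::p.adjust(p, "BH")) # library cross-check
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    # monotone non-decreasing in rank of raw p
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
    # thresholding adjusted values = running the step-up procedure
    for (alpha in c(0.01, 0.05, 0.2)) {
      expect_equal(adj < alpha, step_up_rejects(p, alpha), ignore_attr = TRUE)
    }
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(-0.1)), "\\[0, 1\\]")
})

test_that("DEG classification reproduces the threshold rule and percentages", {
  # fraction arithmetic on the 2594-gene universe
  fake <- data.frame(
    gene_id = sprintf("g%d", 1:600),
    base_mean_ref = 100, base_mean_trt = 100,
    log2fc = c(rep(3, 489), rep(0, 111)),
    pvalue = c(rep(1e-6, 489), rep(0.9, 111))
  )
  res <- classify_and_summarize(fake, n_total_genes = 2594)
  expect_equal(res$summary$n_deg, 489)
  expect_equal(res$summary$fraction_deg, 18.85)
  res517 <- classify_and_summarize(
    data.frame(
      gene_id = sprintf("g%d", 1:517), base_mean_ref = 1, base_mean_trt = 1,
      log2fc = 4, pvalue = 1e-8
    ),
    n_total_genes = 2594
  )
  expect_equal(res517$summary$n_deg, 517)
  expect_equal(res517$summary$fraction_deg, 19.93)

  # both conditions of the rule must hold
  edge <- data.frame(
    gene_id = c("a", "b", "c"),
    base_mean_ref = 10, base_mean_trt = 10,
    log2fc = c(1.9, 2.0, 5.0),
    pvalue = c(0.001, 0.001, 0.5)
  )
  out <- classify_and_summarize(edge)
  expect_equal(out$table$is_deg, c(FALSE, TRUE, FALSE))

  # per-category counting: a gene may land in several categories
  ann <- data.frame(
    gene_id = c("b", "b", "c"),
    category = c("carbon metabolism", "WLP", "WLP")
  )
  out <- classify_and_summarize(edge, annotation = ann)
  per <- out$summary$per_category
  expect_equal(per$n_deg[per$category == "carbon metabolism"], 1L)
  expect_equal(per$n_deg[per$category == "WLP"], 1L)
})

test_that("all-zero genes keep the universe size but leave BH multiplicity", {
  counts <- rbind(
    matrix(rpois(40, 100), nrow = 10),
    matrix(0L, nrow = 2, ncol = 4)
  )
  m <- toy_matrix(counts)
  res <- deg_analyze(m)
  tab <- res$table
  expect_equal(tab$padj[11:12], c(1, 1))
  expect_equal(tab$log2fc[11:12], c(0, 0))
  # BH over the 10 tested genes only
  expect_equal(tab$padj[1:10], bh_adjust(tab$pvalue[1:10]))
})

test_that("planted strong effects at high expression are recovered", {
  sim <- generate_counts(synth_config(42, lfc_min = 3, lfc_max = 3))
  res <- deg_analyze(sim$matrix)
  truth <- sim$truth
  high <- truth$planted & truth$base_mean >= 100
  expect_gt(sum(high), 100)
  expect_gte(mean(res$table$is_deg[high]), 0.9)
  # and the false-positive fraction among unplanted genes stays below alpha
  expect_lte(mean(res$table$is_deg[!truth$planted]), 0.05)
})
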