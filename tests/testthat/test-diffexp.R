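# Normalization, dispersion estimation and the NB Wald test.

test_that("size factors match a brute-force median-of-ratios oracle", {
  # independent re-implementation, kept deliberately naive
  oracle <- function(cm) {
    geo <- apply(cm, 1, function(x) exp(mean(log(x))))
    keep <- is.finite(geo) & geo > 0
    sf <- apply(cm, 2, function(col) median(col[keep] / geo[keep]))
    sf / exp(mean(log(sf)))
  }
  for (seed in 1:5) {
    cm <- withr::with_seed(seed, {
      matrix(rpois(120, 50) + 1L, 20, 6,
             dimnames = list(paste0("g", 1:20), paste0("s", 1:6)))
    })
    expect_equal(unname(size_factors(cm)), unname(oracle(cm)),
                 tolerance = 1e-12)
  }
})

test_that("size factors: identity, scaling equivariance, geometric mean 1", {
  cm <- matrix(rep(c(5L, 9L, 40L, 100L), 4), 4, 4,
               dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  expect_equal(unname(size_factors(cm)), rep(1, 4))
  cm2 <- cm
  cm2[, 2] <- cm[, 2] * 2L
  sf <- size_factors(cm2)
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-12)
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-6)
})

test_that("size factors error without an all-positive gene unless pseudo-reference", {
  cm <- matrix(c(0L, 5L, 3L, 0L), 2, 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(size_factors(cm), "pseudo_reference")
  sf <- size_factors(cm, pseudo_reference = TRUE)
  expect_true(all(sf > 0))
})

test_that("dispersion estimator hits the Poisson and NB regimes", {
  cond50 <- factor(rep(c("a", "b"), each = 50))
  pois <- withr::with_seed(1, {
    matrix(rpois(500 * 100, rep(rlnorm(500, log(200), 0.5), 100)), 500, 100)
  })
  rownames(pois) <- paste0("g", 1:500); colnames(pois) <- paste0("s", 1:100)
  dp <- estimate_dispersion(pois, rep(1, 100), cond50)
  expect_lt(median(attr(dp, "raw")), 1e-2)

  nb <- withr::with_seed(2, {
    mu <- rlnorm(500, log(200), 0.5)
    matrix(rnbinom(500 * 100, mu = rep(mu, 100), size = 10), 500, 100)
  })
  rownames(nb) <- paste0("g", 1:500); colnames(nb) <- paste0("s", 1:100)
  dn <- estimate_dispersion(nb, rep(1, 100), cond50)
  expect_gt(median(attr(dn, "raw")), 0.07)
  expect_lt(median(attr(dn, "raw")), 0.13)

  const <- matrix(7L, 20, 6, dimnames = list(paste0("g", 1:20),
                                             paste0("s", 1:6)))
  dc <- estimate_dispersion(const, rep(1, 6), two_group_condition())
  expect_true(all(attr(dc, "raw") == 0))
  expect_true(all(dc >= 1e-8))

  expect_error(estimate_dispersion(const[, 1:2], rep(1, 2),
                                   factor(c("a", "b"))), "replicates")
})

test_that("NB Wald test recovers a planted two-fold change", {
  cnt <- make_two_group_counts(n_genes = 1500, n_resp = 150, fc = 2,
                               alpha = 0.01, seed = 21)
  cond <- two_group_condition()
  sf <- size_factors(cnt)
  disp <- estimate_dispersion(cnt, sf, cond)
  de <- nb_wald_test(cnt, sf, disp, cond)
  expect_gt(mean(de$log2FoldChange[1:150]), 0.8)
  expect_lt(mean(de$log2FoldChange[1:150]), 1.2)
  # Wald identity and BH dominance
  ok <- !is.na(de$lfcSE) & de$lfcSE > 0
  expect_equal(de$stat[ok], de$log2FoldChange[ok] / de$lfcSE[ok],
               tolerance = 1e-12)
  expect_true(all(de$padj[ok] >= de$pvalue[ok]))
})

test_that("null contrasts are calibrated and direction swaps negate", {
  # literally identical groups: the fold change vanishes
  half <- make_two_group_counts(n_genes = 100, n_per_group = 3, seed = 30)[, 1:3]
  dup <- cbind(half, half)
  colnames(dup) <- sprintf("s%d", 1:6)
  cond <- two_group_condition()
  de_dup <- nb_wald_test(dup, size_factors(dup), rep(0.05, 100), cond)
  expect_lt(median(abs(de_dup$log2FoldChange), na.rm = TRUE), 1e-8)

  # sampled null: flat p-value distribution
  cnt <- make_two_group_counts(n_genes = 800, alpha = 0.05, seed = 31)
  sf <- size_factors(cnt)
  disp <- estimate_dispersion(cnt, sf, cond)
  de <- nb_wald_test(cnt, sf, disp, cond)
  expect_gt(mean(de$pvalue, na.rm = TRUE), 0.4)
  rev <- nb_wald_test(cnt, sf, disp, cond, ref = "treated")
  expect_equal(rev$log2FoldChange, -de$log2FoldChange, tolerance = 1e-8)
  expect_equal(rev$stat, -de$stat, tolerance = 1e-8)
  expect_equal(rev$pvalue, de$pvalue, tolerance = 1e-8)
})

test_that("scaling one sample is absorbed by its size factor", {
  base <- matrix(c(10L, 20L, 40L, 80L, 160L, 320L), 6, 1)
  cnt <- cbind(base, base, base * 2L, base, base, base)  # noise-free
  rownames(cnt) <- paste0("g", 1:6); colnames(cnt) <- paste0("s", 1:6)
  cond <- two_group_condition()
  sf <- size_factors(cnt)
  expect_equal(unname(sf[3] / sf[1]), 2, tolerance = 1e-12)
  disp <- rep(1e-8, 6)
  de <- nb_wald_test(cnt, sf, disp, cond)
  expect_true(all(abs(de$log2FoldChange) < 1e-6))
})

test_that("batch-aware design absorbs a gene-wise batch effect", {
  n <- 1200
  withr::local_seed(41)
  mu <- rlnorm(n, log(200), 0.8)
  fc <- rep(1, n); fc[1:120] <- 2
  batch <- factor(rep(c("b1", "b2"), 3))
  bf <- rep(1, n); bf[sample(n, n / 2)] <- 1.4
  mu_mat <- outer(mu, rep(1, 6))
  for (j in which(batch == "b2")) mu_mat[, j] <- mu_mat[, j] * bf
  for (j in 4:6) mu_mat[, j] <- mu_mat[, j] * fc
  cnt <- matrix(rnbinom(n * 6, mu = mu_mat, size = 100), n, 6,
                dimnames = list(paste0("g", 1:n), paste0("s", 1:6)))
  cond <- two_group_condition()
  sf <- size_factors(cnt)
  disp <- estimate_dispersion(cnt, sf, interaction(cond, batch))
  de <- nb_wald_test(cnt, sf, disp, cond,
                     covariates = data.frame(batch = batch))
  expect_lt(abs(mean(de$log2FoldChange[1:120]) - 1), 0.1)
})

test_that("confounded designs are rejected with the collinear column named", {
  cnt <- make_two_group_counts(n_genes = 10, seed = 51)
  cond <- two_group_condition()
  batch <- factor(c("b1", "b1", "b1", "b2", "b2", "b2"))  # batch == condition
  sf <- size_factors(cnt)
  expect_error(
    nb_wald_test(cnt, sf, rep(0.05, 10), cond,
                 covariates = data.frame(batch = batch)),
    "confounded")
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  p <- c(0.01, NA, 0.5)
  expect_true(is.na(bh_adjust(p)[2]))
})

test_that("significance filter applies strict Table-style thresholds", {
  res <- data.frame(
    gene_id = c("a", "b", "c"),
    baseMean = c(12, 12, 9),
    padj = c(0.04, 0.04, 0.001),
    log2FoldChange = c(0.60, 0.585, 3)
  )
  kept <- significance_filter(res)
  expect_equal(kept$gene_id, "a")  # b fails strict lfc, c fails baseMean
})

test_that("NB Wald log2FC agrees with DESeq2 on a shared dataset", {
  skip_if_not_installed("DESeq2")
  cnt <- make_two_group_counts(n_genes = 400, n_resp = 60, fc = 2.5,
                               alpha = 0.02, seed = 61)
  cond <- two_group_condition()
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      cnt, data.frame(condition = cond), ~condition)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    ref <- as.data.frame(DESeq2::results(dds))
  })
  # same estimator family; conventions differ only in the even-n median
  # (ratio-scale midpoint here vs log-scale midpoint there)
  sf <- size_factors(cnt)
  sf_ref <- DESeq2::sizeFactors(dds)
  expect_equal(unname(sf / sf[1]), unname(sf_ref / sf_ref[1]),
               tolerance = 2e-3)
  disp <- estimate_dispersion(cnt, sf, cond)
  de <- nb_wald_test(cnt, sf, disp, cond)
  hi <- which(de$baseMean > 50)
  expect_gt(cor(de$log2FoldChange[hi], ref$log2FoldChange[hi]), 0.98)
})
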