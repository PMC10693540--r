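# Williams trend test, Exp5 fitting, benchmark doses, accumulation curves,
# OCR normalization and Dunnett LOELs.

test_that("Williams trend test separates monotone signal from flat noise", {
  dose <- rep(c(0, 1, 2, 4, 8), each = 3)
  flat <- rep(5, 15)
  t0 <- williams_trend_test(flat, dose, n_perm = 99)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p, 1)

  y <- withr::with_seed(1, rep(c(10, 20, 30, 40, 60), each = 3) +
                          rnorm(15, 0, 0.01))
  tt <- williams_trend_test(y, dose, n_perm = 5000, seed = 2)
  expect_lte(tt$p, 1e-3)
  expect_equal(tt$direction, "increasing")
  expect_equal(tt$max_fc, 6, tolerance = 1e-3)
  expect_true(tt$passes_prefilter)

  down <- williams_trend_test(-y, dose, n_perm = 200, seed = 2)
  expect_equal(down$direction, "decreasing")

  expect_error(williams_trend_test(1:3, rep(0, 3)), "dose groups")
  expect_identical(williams_trend_test(y, dose, n_perm = 99, seed = 5)$p,
                   williams_trend_test(y, dose, n_perm = 99, seed = 5)$p)
})

test_that("Williams statistic uses amalgamated means", {
  # non-monotone middle group is pooled by PAVA, not ignored
  dose <- rep(c(0, 1, 2), each = 2)
  y <- c(0, 0, 3, 3, 2, 2)  # groups: 0, 3, 2 -> isotonic treated means 2.5, 2.5
  tt <- williams_trend_test(y, dose, n_perm = 19, seed = 1)
  s2 <- 0  # all groups constant
  expect_true(is.infinite(tt$statistic) && tt$statistic > 0)
  # with noise, the statistic is finite and positive
  y2 <- y + withr::with_seed(3, rnorm(6, 0, 0.1))
  tt2 <- williams_trend_test(y2, dose, n_perm = 19, seed = 1)
  expect_true(is.finite(tt2$statistic) && tt2$statistic > 0)
})

test_that("Exp5 recovers its own noise-free parameters and nests the flat model", {
  d <- c(0, 0.05, 0.1, 0.2, 0.5, 1, 2)
  y <- exp5_mean(d, 100, 0.5, 2, 1)
  fit <- fit_exp5(d, y)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$params - c(100, 0.5, 2, 1)) / c(100, 0.5, 2, 1)),
            1e-3)

  # c = 1 collapses to a constant curve
  expect_equal(exp5_mean(d, 100, 0.5, 1, 1), rep(100, length(d)))

  # fitted RSS never exceeds the flat model's RSS
  for (seed in 1:4) {
    yn <- withr::with_seed(seed, rnorm(length(d), 50, 5))
    f <- fit_exp5(d, yn)
    expect_lte(f$rss, sum((yn - mean(yn))^2) + 1e-9)
  }
  expect_error(fit_exp5(c(0, 1, 2), c(1, 2, 3)), "4 distinct dose")
})

test_that("benchmark-dose inversion is exact and scales with the rate", {
  fit <- fit_exp5(c(0, 0.05, 0.1, 0.2, 0.5, 1, 2),
                  exp5_mean(c(0, 0.05, 0.1, 0.2, 0.5, 1, 2), 100, 0.5, 2, 1))
  bm <- compute_bmd(fit)
  expect_equal(bm$bmd, -2 * log(0.9), tolerance = 1e-6)
  expect_equal(bm$target, 110, tolerance = 1e-3)
  # the inverted dose reproduces the target response
  expect_equal(exp5_mean(bm$bmd, fit$params["a"], fit$params["b"],
                         fit$params["c"], fit$params["g"]),
               c(a = bm$target), tolerance = 1e-6)

  # doubling b halves the BMD at g = 1
  d <- c(0, 0.05, 0.1, 0.2, 0.5, 1, 2)
  fit2 <- fit_exp5(d, exp5_mean(d, 100, 1, 2, 1))
  expect_equal(compute_bmd(fit2)$bmd, bm$bmd / 2, tolerance = 1e-4)

  # target beyond the asymptote: undefined, flagged
  bm_out <- compute_bmd(fit, bmr = list(type = "relative", magnitude = 1.5))
  expect_false(bm_out$defined)
  expect_true(is.na(bm_out$bmd))

  # sd-type benchmark response
  bm_sd <- compute_bmd(fit, bmr = list(type = "sd", magnitude = 1),
                       sd_control = 10)
  expect_equal(bm_sd$target, 110, tolerance = 1e-3)
  expect_error(compute_bmd(fit, bmr = list(type = "sd", magnitude = 1)),
               "sd_control")
})

test_that("round-trip fit-then-invert reproduces the generating BMD", {
  d <- c(0, 0.02, 0.08, 0.3, 1, 4)
  for (pars in list(c(50, 2, 3, 1), c(200, 0.8, 0.4, 1.5))) {
    y <- exp5_mean(d, pars[1], pars[2], pars[3], pars[4])
    fit <- fit_exp5(d, y, g_starts = c(1, 1.5))
    truth <- compute_bmd(
      structure(list(params = c(a = pars[1], b = pars[2], c = pars[3],
                                g = pars[4])), class = "exp5_fit"))
    est <- compute_bmd(fit)
    expect_equal(est$bmd, truth$bmd, tolerance = 1e-3)
  }
})

test_that("accumulation curve counts BMDs at or below each dose", {
  f <- accumulation_curve(c(1, 1, 10))
  expect_equal(f(1), 2)
  expect_equal(f(5), 2)
  expect_equal(f(10), 3)
  expect_equal(f(0.5), 0)

  f0 <- accumulation_curve(c(NA, Inf))
  expect_equal(f0(c(1, 100)), c(0, 0))

  bmds <- withr::with_seed(12, runif(100, 0.01, 10))
  fr <- accumulation_curve(bmds)
  srt <- sort(bmds)
  for (x in srt[c(1, 25, 50, 99)]) {
    expect_equal(fr(x), sum(srt <= x))  # sorted-rank oracle
  }
  # order invariance
  fp <- accumulation_curve(rev(bmds))
  expect_equal(attr(fp, "table"), attr(fr, "table"))
})

test_that("OCR normalization anchors vehicle at 100 and positive control at 0", {
  ocr <- data.frame(
    compound = c("DMSO", "DMSO", "positive_control", "cmpA", "cmpA", "cmpA"),
    concentration = c(0, 0, 0, 1, 1, 1),
    phase = "basal",
    well = 1:6,
    ocr = c(148, 152, 30, 150, 30, 90))
  pct <- ocr_percent_of_control(ocr)
  expect_equal(pct$percent_of_control[4], 100)   # raw at vehicle mean
  expect_equal(pct$percent_of_control[5], 0)     # raw at positive-control mean
  expect_equal(pct$percent_of_control[6], 50)    # midway -> 50%
  expect_error(ocr_percent_of_control(ocr[4:6, ]), "vehicle")

  # rescaling to non-effective concentrations
  ocr2 <- rbind(ocr, data.frame(compound = "cmpA", concentration = c(2, 4),
                                phase = "basal", well = 7:8, ocr = c(120, 120)))
  pct2 <- ocr_percent_of_control(ocr2, rescale_concs = c(2, 4))
  ref <- mean(pct2$percent_of_control[pct2$concentration %in% c(2, 4)])
  expect_equal(ref, 100)
})

test_that("Dunnett LOEL finds the lowest significant concentration", {
  v <- withr::with_seed(3, c(rnorm(3, 100, 3), rnorm(3, 100, 3),
                             rnorm(3, 100, 3), rnorm(3, 70, 3),
                             rnorm(3, 40, 3)))
  conc <- rep(c(0, 0.1, 1, 10, 100), each = 3)
  res <- anova_dunnett_loel(v, conc)
  expect_equal(res$loel, 10)

  # single treated group reduces to a two-sample t-test
  v2 <- withr::with_seed(4, c(rnorm(4, 10, 1), rnorm(4, 13, 1)))
  conc2 <- rep(c(0, 5), each = 4)
  res2 <- anova_dunnett_loel(v2, conc2)
  tt <- t.test(v2[5:8], v2[1:4], var.equal = TRUE)
  expect_equal(res2$p$p_adj, tt$p.value, tolerance = 1e-3)

  expect_error(anova_dunnett_loel(1:4, c(0, 0, 1, 2)), "replicates")
})

test_that("familywise error of the Dunnett LOEL is controlled", {
  hits <- withr::with_seed(31, {
    vapply(1:200, function(i) {
      v <- rnorm(18, 100, 5)
      conc <- rep(c(0, 0.1, 0.5, 1, 5, 10), each = 3)
      !is.na(anova_dunnett_loel(v, conc)$loel)
    }, logical(1))
  })
  expect_gte(mean(!hits), 0.93)
})

test_that("bmd_pipeline fits only genes passing the trend prefilter", {
  d <- rep(c(0, 0.05, 0.2, 0.8, 3), each = 3)
  withr::local_seed(7)
  responsive <- exp5_mean(d, 100, 2, 3, 1) * rlnorm(15, 0, 0.05)
  flat <- rlnorm(15, log(100), 0.05)
  norm <- rbind(gene_resp = responsive, gene_flat = flat)
  res <- bmd_pipeline(norm, d, n_perm = 500, seed = 1)
  expect_true(res$passes_prefilter[res$gene_id == "gene_resp"])
  expect_false(res$passes_prefilter[res$gene_id == "gene_flat"])
  expect_true(is.finite(res$bmd[res$gene_id == "gene_resp"]))
  expect_true(is.na(res$bmd[res$gene_id == "gene_flat"]))
})
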