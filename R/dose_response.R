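# Dose-response analytics: Williams trend prefilter, Exp5 benchmark-dose
# modelling, accumulation curves, OCR normalization and Dunnett LOELs.

# Weighted pool-adjacent-violators: isotonic (non-decreasing) fit of y with
# weights w. Returns the amalgamated values, one per input position.
#' @noRd
pava <- function(y, w) {
  n <- length(y)
  level <- numeric(n); weight <- numeric(n); size <- integer(n)
  j <- 0L
  for (i in seq_len(n)) {
    j <- j + 1L
    level[j] <- y[i]; weight[j] <- w[i]; size[j] <- 1L
    while (j > 1L && level[j - 1L] > level[j]) {
      wsum <- weight[j - 1L] + weight[j]
      level[j - 1L] <- (weight[j - 1L] * level[j - 1L] +
                          weight[j] * level[j]) / wsum
      weight[j - 1L] <- wsum
      size[j - 1L] <- size[j - 1L] + size[j]
      j <- j - 1L
    }
  }
  rep(level[seq_len(j)], size[seq_len(j)])
}

# Williams statistic for ordered dose groups: amalgamated (isotonic) treated
# means against the control mean, scaled by the pooled within-group SE.
# `split_idx` is a list of row indices per group, control first.
#' @noRd
williams_stat <- function(y, split_idx, n_per, decreasing = FALSE) {
  if (decreasing) y <- -y
  means <- vapply(split_idx, function(ix) mean(y[ix]), numeric(1))
  ss <- sum(vapply(seq_along(split_idx), function(g) {
    sum((y[split_idx[[g]]] - means[g])^2)
  }, numeric(1)))
  df <- length(y) - length(split_idx)
  s2 <- if (df > 0) ss / df else 0
  iso <- pava(means[-1], n_per[-1])
  k <- length(iso)
  num <- iso[k] - means[1]
  den <- sqrt(s2 * (1 / n_per[k + 1] + 1 / n_per[1]))
  if (den == 0) {
    return(if (num == 0) 0 else sign(num) * Inf)
  }
  num / den
}

#' Williams trend test with permutation p-value
#'
#' Tests for a monotone concentration-response: dose-group means are
#' amalgamated under an isotonic constraint (pool-adjacent-violators,
#' weighted by group size) and the highest amalgamated mean is compared to
#' the control mean, scaled by the pooled within-group standard error. The
#' direction (increasing or decreasing) with the larger statistic is
#' selected. Significance comes from permuting the replicate-to-group
#' assignment. The prefilter flag combines `p < p_max` with an absolute
#' fold-change criterion (largest group-mean ratio to control, either
#' direction, above `fc_min`).
#'
#' @param values Numeric response vector.
#' @param dose Dose per value; the lowest dose (typically 0) is the control
#'   group.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param p_max,fc_min Prefilter cut-offs (defaults 0.05 and 1.5-fold).
#' @return List of class `trend_test` with `statistic`, `p`, `direction`,
#'   `max_fc` (signed: negative values mean a decrease, magnitude is the
#'   fold ratio), and `passes_prefilter`.
#' @export
williams_trend_test <- function(values, dose, n_perm = 10000L, seed = 1L,
                                p_max = 0.05, fc_min = 1.5) {
  if (length(values) != length(dose)) {
    config_error("values and dose must have equal length")
  }
  lv <- sort(unique(dose))
  if (length(lv) < 2L) config_error("need >= 2 dose groups including control")
  split_idx <- lapply(lv, function(d) which(dose == d))
  n_per <- vapply(split_idx, length, integer(1))
  if (any(n_per < 1L)) config_error("every dose group needs >= 1 replicate")
  if (sum(n_per) - length(lv) < 1L) {
    config_error("no residual degrees of freedom for the pooled variance")
  }

  t_inc <- williams_stat(values, split_idx, n_per, decreasing = FALSE)
  t_dec <- williams_stat(values, split_idx, n_per, decreasing = TRUE)
  if (abs(t_dec) > abs(t_inc)) {
    t_obs <- t_dec; direction <- "decreasing"
  } else {
    t_obs <- t_inc; direction <- "increasing"
  }

  n <- length(values)
  t_perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      yp <- values[sample.int(n)]
      max(williams_stat(yp, split_idx, n_per, FALSE),
          williams_stat(yp, split_idx, n_per, TRUE))
    }, numeric(1))
  })
  p <- (1 + sum(t_perm >= t_obs)) / (1 + n_perm)

  means <- vapply(split_idx, function(ix) mean(values[ix]), numeric(1))
  m0 <- means[1]
  max_fc <- NA_real_
  if (m0 > 0 && all(means > 0)) {
    ratio <- means[-1] / m0
    f <- ratio[which.max(abs(log(ratio)))]
    max_fc <- if (f >= 1) f else -1 / f
  }
  structure(
    list(statistic = t_obs, p = p, direction = direction, max_fc = max_fc,
         passes_prefilter = isTRUE(p < p_max && is.finite(max_fc) &&
                                     abs(max_fc) > fc_min)),
    class = "trend_test"
  )
}

#' Fit the Exp5 concentration-response model
#'
#' Nonlinear least squares for
#' `m(d) = a * (c - (c - 1) * exp(-(b d)^g))` with `b, g > 0`, using
#' Levenberg-Marquardt with a multi-start grid over `b` (log-spaced across
#' the tested dose range) and a small set of `g` starts; a flat candidate
#' (`c = 1`) is always in the pool so the returned residual sum of squares
#' never exceeds that of the constant model. The best converged start wins.
#'
#' @param dose,response Numeric vectors (replicates allowed); at least four
#'   distinct dose levels are required for the four free parameters.
#' @param n_b_starts Number of log-spaced `b` starting values.
#' @param g_starts Starting values for the shape exponent.
#' @param g_min Lower bound on the shape exponent. The default of 1 is the
#'   usual restricted-power convention for continuous benchmark-dose
#'   models: it rules out infinite slope at dose zero, which otherwise
#'   makes low-dose benchmark estimates unstable. Set below 1 to allow
#'   supralinear curves.
#' @param fit_log If `TRUE`, minimize squared residuals of the logarithm of
#'   the response (requires strictly positive responses). This is the
#'   efficient choice for expression-like data whose noise is
#'   multiplicative; the default linear scale suits endpoints with
#'   additive error. `rss` is reported on the fitted scale.
#' @return Object of class `exp5_fit`: `params` (a, b, c, g), `rss`,
#'   `converged`, plus the data.
#' @export
fit_exp5 <- function(dose, response, n_b_starts = 5L, g_starts = c(1, 2, 4),
                     g_min = 1, fit_log = FALSE) {
  if (length(dose) != length(response)) {
    config_error("dose and response must have equal length")
  }
  if (any(dose < 0)) config_error("doses must be >= 0")
  if (length(unique(dose)) < 4L) {
    config_error("Exp5 has 4 free parameters; need >= 4 distinct dose levels")
  }
  if (fit_log && any(response <= 0)) {
    config_error("fit_log = TRUE requires strictly positive responses")
  }
  dpos <- unique(dose[dose > 0])
  b_grid <- 10^seq(log10(1 / max(dpos)) - 1, log10(1 / min(dpos)) + 1,
                   length.out = n_b_starts)
  a0 <- mean(response[dose == min(dose)])
  if (!is.finite(a0) || a0 <= 0) a0 <- max(mean(response), 1e-6)
  top <- mean(response[dose == max(dose)])
  c0 <- max(top / a0, 1e-3)

  dat <- data.frame(d = dose, y = response)
  form <- if (fit_log) {
    log(y) ~ log(a * (cc - (cc - 1) * exp(-(b * d)^g)))
  } else {
    y ~ a * (cc - (cc - 1) * exp(-(b * d)^g))
  }
  best <- NULL
  g_starts <- pmax(g_starts, g_min)
  for (b0 in b_grid) {
    for (g0 in g_starts) {
      for (cc0 in unique(c(c0, 2, 0.5))) {
        fit <- tryCatch(
          minpack.lm::nlsLM(
            form,
            data = dat,
            start = list(a = a0, b = b0, cc = cc0, g = g0),
            lower = c(a = 1e-9, b = 1e-9, cc = 1e-9, g = g_min),
            upper = c(a = Inf, b = Inf, cc = Inf, g = 18),
            control = minpack.lm::nls.lm.control(maxiter = 200)),
          error = function(e) NULL)
        if (is.null(fit)) next
        rss <- sum(residuals(fit)^2)
        if (is.null(best) || rss < best$rss) {
          cf <- coef(fit)
          best <- list(params = c(a = unname(cf["a"]), b = unname(cf["b"]),
                                  c = unname(cf["cc"]), g = unname(cf["g"])),
                       rss = rss, converged = TRUE)
        }
      }
    }
  }
  # constant-model fallback; also guarantees the flat-nesting RSS bound
  if (fit_log) {
    a_flat <- exp(mean(log(response)))
    rss_flat <- sum((log(response) - log(a_flat))^2)
  } else {
    a_flat <- mean(response)
    rss_flat <- sum((response - a_flat)^2)
  }
  if (is.null(best) || best$rss > rss_flat) {
    best <- list(params = c(a = a_flat, b = 1 / max(dpos), c = 1, g = 1),
                 rss = rss_flat, converged = !is.null(best))
  }
  structure(c(best, list(dose = dose, response = response)),
            class = "exp5_fit")
}

#' @export
print.exp5_fit <- function(x, ...) {
  cat("Exp5 fit: a =", signif(x$params["a"], 4),
      "b =", signif(x$params["b"], 4),
      "c =", signif(x$params["c"], 4),
      "g =", signif(x$params["g"], 4),
      "| rss =", signif(x$rss, 4),
      "| converged:", x$converged, "\n")
  invisible(x)
}

#' Benchmark dose from a fitted Exp5 curve
#'
#' Inverts the fitted curve at the benchmark-response target. For the
#' default relative benchmark response the target is a `magnitude`
#' fractional change of the modeled control response `a`, in the direction
#' of the curve (`c > 1` up, `c < 1` down); with `type = "sd"` the target is
#' `a` plus/minus `magnitude` control standard deviations. The closed-form
#' inversion is exact; a target outside the curve's range `(a, a*c)` yields
#' an undefined (NA) benchmark dose, flagged in the result.
#'
#' @param fit An [fit_exp5()] result.
#' @param bmr List with `type` (`"relative"` or `"sd"`) and `magnitude`
#'   (default 10% relative).
#' @param sd_control Control standard deviation, required for `type = "sd"`.
#' @return List with `bmd` (uM or NA), `target`, and `defined`.
#' @export
compute_bmd <- function(fit, bmr = list(type = "relative", magnitude = 0.1),
                        sd_control = NULL) {
  stopifnot(inherits(fit, "exp5_fit"))
  p <- fit$params
  dir <- sign(p["c"] - 1)
  if (dir == 0) {
    return(list(bmd = NA_real_, target = NA_real_, defined = FALSE))
  }
  target <- switch(
    bmr$type,
    relative = p["a"] * (1 + dir * bmr$magnitude),
    sd = {
      if (is.null(sd_control)) {
        config_error("sd-type benchmark response needs sd_control")
      }
      p["a"] + dir * bmr$magnitude * sd_control
    },
    config_error("unknown bmr type '%s'", bmr$type)
  )
  bmd <- exp5_invert(unname(target), p["a"], p["b"], p["c"], p["g"])
  list(bmd = unname(bmd), target = unname(target), defined = is.finite(bmd))
}

#' Benchmark-dose accumulation curve
#'
#' Step function counting, at each concentration, how many genes have a
#' benchmark dose at or below it: the transcriptomic point-of-departure
#' accumulation plot. Input order is irrelevant; evaluation at the maximal
#' dose returns the number of genes with a defined BMD.
#'
#' @param bmds Numeric vector of benchmark doses (NA/non-finite dropped).
#' @return A right-continuous step function (see [stats::stepfun()]) with
#'   the breakpoint table in `attr(, "table")`.
#' @export
accumulation_curve <- function(bmds) {
  x <- sort(bmds[is.finite(bmds)])
  if (length(x) == 0L) {
    f <- function(v) rep(0, length(v))
    attr(f, "table") <- data.frame(bmd = numeric(0), cumulative = integer(0))
    return(f)
  }
  ux <- unique(x)
  cum <- vapply(ux, function(v) sum(x <= v), numeric(1))
  f <- stepfun(ux, c(0, cum), right = FALSE)
  attr(f, "table") <- data.frame(bmd = ux, cumulative = cum)
  f
}

#' Express raw OCR as percent of control
#'
#' Subtracts the mean positive-control rate (full ETC shutdown:
#' non-mitochondrial respiration) and scales so the mean vehicle basal rate
#' maps to 100 percent. Optionally rescales each compound/phase series to
#' the mean of designated non-effective concentrations to absorb plate-level
#' drift.
#'
#' @param ocr Data frame with `compound`, `concentration`, `phase`, `ocr`
#'   (raw rates, pmol O2/min/well).
#' @param positive_control Raw rates of the positive-control wells; by
#'   default taken from rows with `compound == "positive_control"`.
#' @param vehicle_basal Raw basal rates of vehicle wells; by default rows
#'   with `compound == "DMSO"` and `phase == "basal"`.
#' @param rescale_concs Optional numeric vector (length >= 2) of
#'   concentrations treated as non-effective; each compound/phase series is
#'   rescaled so their mean percent is 100.
#' @return The input with a `percent_of_control` column appended.
#' @export
ocr_percent_of_control <- function(ocr, positive_control = NULL,
                                   vehicle_basal = NULL,
                                   rescale_concs = NULL) {
  if (is.null(positive_control)) {
    positive_control <- ocr$ocr[ocr$compound == "positive_control"]
  }
  if (is.null(vehicle_basal)) {
    vehicle_basal <- ocr$ocr[ocr$compound == "DMSO" & ocr$phase == "basal"]
  }
  if (length(positive_control) < 1L || length(vehicle_basal) < 1L) {
    config_error("need >= 1 positive-control and >= 1 vehicle basal well")
  }
  mp <- mean(positive_control)
  mv <- mean(vehicle_basal)
  if (mv == mp) config_error("vehicle and positive-control means coincide")
  out <- ocr
  out$percent_of_control <- 100 * (ocr$ocr - mp) / (mv - mp)
  if (!is.null(rescale_concs)) {
    if (length(rescale_concs) < 2L) {
      config_error("rescaling needs >= 2 non-effective concentrations")
    }
    for (cmp in setdiff(unique(out$compound), c("DMSO", "positive_control"))) {
      for (ph in unique(out$phase)) {
        sel <- out$compound == cmp & out$phase == ph
        refm <- mean(out$percent_of_control[
          sel & out$concentration %in% rescale_concs])
        if (is.finite(refm) && refm > 0) {
          out$percent_of_control[sel] <-
            out$percent_of_control[sel] / refm * 100
        }
      }
    }
  }
  out
}

#' One-way ANOVA with Dunnett post-test: lowest observed effect level
#'
#' Fits a one-way ANOVA over concentration groups and performs Dunnett
#' many-to-one comparisons against the control (lowest concentration,
#' typically the vehicle at 0), with single-step adjusted p-values from the
#' equicorrelated multivariate-t distribution. The LOEL is the lowest
#' concentration whose adjusted p falls below `alpha`, or `NA` when no
#' group is significant.
#'
#' @param values Numeric responses.
#' @param conc Concentration per response; the lowest level is the control.
#' @param alpha Significance level.
#' @return List with `loel` (uM or NA) and the per-concentration adjusted
#'   p-value table.
#' @export
anova_dunnett_loel <- function(values, conc, alpha = 0.05) {
  lv <- sort(unique(conc))
  if (length(lv) < 2L) config_error("need a control and >= 1 treated group")
  tab <- table(conc)
  if (any(tab < 2L)) {
    config_error("every concentration group needs >= 2 replicates")
  }
  d <- data.frame(y = values,
                  g = factor(conc, levels = lv))
  fit <- aov(y ~ g, data = d)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  sm <- summary(gl)
  p_adj <- as.numeric(sm$test$pvalues)
  treated <- lv[-1]
  sig <- treated[p_adj < alpha]
  list(
    loel = if (length(sig) > 0) min(sig) else NA_real_,
    p = data.frame(concentration = treated, p_adj = p_adj)
  )
}

#' Williams-prefiltered Exp5 benchmark-dose table for one compound
#'
#' Convenience stage: for each gene, applies the Williams trend prefilter to
#' its normalized counts over the concentration series, fits Exp5 for the
#' passing genes, and computes the benchmark dose. Genes failing the
#' fold-change criterion are skipped before any permutation is spent on
#' them.
#'
#' @param norm_counts Normalized count matrix (genes x samples) for one
#'   compound's series including its vehicle samples.
#' @param conc Concentration per sample (0 for vehicle).
#' @param n_perm Permutations for the trend p-value.
#' @param seed Integer seed.
#' @param p_max,fc_min Prefilter cut-offs.
#' @param bmr Benchmark-response specification (see [compute_bmd()]).
#' @return Data frame per tested gene: trend statistic and p, prefilter
#'   flag, Exp5 parameters, rss, convergence and BMD (NA when not fitted).
#' @export
bmd_pipeline <- function(norm_counts, conc, n_perm = 1000L, seed = 1L,
                         p_max = 0.05, fc_min = 1.5,
                         bmr = list(type = "relative", magnitude = 0.1)) {
  lv <- sort(unique(conc))
  genes <- rownames(norm_counts)
  rows <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    y <- norm_counts[i, ]
    means <- vapply(lv, function(d) mean(y[conc == d]), numeric(1))
    fc_ok <- FALSE
    if (means[1] > 0 && all(means > 0)) {
      ratio <- means[-1] / means[1]
      fmax <- max(ratio, 1 / ratio)
      fc_ok <- fmax > fc_min
    }
    if (!fc_ok) {
      rows[[i]] <- data.frame(gene_id = genes[i], statistic = NA_real_,
                              p = NA_real_, passes_prefilter = FALSE,
                              a = NA_real_, b = NA_real_, c = NA_real_,
                              g = NA_real_, rss = NA_real_, converged = NA,
                              bmd = NA_real_, stringsAsFactors = FALSE)
      next
    }
    tt <- williams_trend_test(y, conc, n_perm = n_perm, seed = seed + i,
                              p_max = p_max, fc_min = fc_min)
    if (!tt$passes_prefilter) {
      rows[[i]] <- data.frame(gene_id = genes[i], statistic = tt$statistic,
                              p = tt$p, passes_prefilter = FALSE,
                              a = NA_real_, b = NA_real_, c = NA_real_,
                              g = NA_real_, rss = NA_real_, converged = NA,
                              bmd = NA_real_, stringsAsFactors = FALSE)
      next
    }
    fit <- fit_exp5(conc, y, n_b_starts = 4L, g_starts = 1,
                    fit_log = all(y > 0))
    bm <- compute_bmd(fit, bmr = bmr)
    rows[[i]] <- data.frame(gene_id = genes[i], statistic = tt$statistic,
                            p = tt$p, passes_prefilter = TRUE,
                            a = fit$params["a"], b = fit$params["b"],
                            c = fit$params["c"], g = fit$params["g"],
                            rss = fit$rss, converged = fit$converged,
                            bmd = bm$bmd, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
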