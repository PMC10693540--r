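# Negative-binomial Wald-test differential expression.
#
# Median-of-ratios normalization, method-of-moments dispersion with
# mean-trend shrinkage, and per-gene NB log-link GLM fits by iteratively
# reweighted least squares. This is a deliberately simplified relative of the
# standard shrinkage-based NB framework: no empirical-Bayes dispersion
# posterior, no fold-change moderation, no outlier replacement. The
# consequences for replicating published gene counts are documented in the
# methods vignette.

#' Median-of-ratios size factors
#'
#' Computes per-sample scaling factors as the median across genes of the
#' ratio between a sample's count and the gene's geometric mean over all
#' samples, using only genes with a positive geometric mean (by default,
#' genes positive in every sample). Factors are rescaled so their geometric
#' mean is 1.
#'
#' @param counts Count matrix, genes/probes x samples.
#' @param pseudo_reference If `TRUE`, fall back to computing each gene's
#'   geometric mean over its positive counts only, so genes with zeros still
#'   contribute (useful when no gene is positive in all samples).
#' @return Named positive numeric vector of size factors.
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  if (ncol(counts) < 1L) config_error("count matrix has no samples")
  logc <- log(counts)
  if (pseudo_reference) {
    logc[!is.finite(logc)] <- NA
    log_geo <- rowMeans(logc, na.rm = TRUE)
    use <- is.finite(log_geo)
  } else {
    log_geo <- rowMeans(logc)
    use <- is.finite(log_geo)
  }
  if (!any(use)) {
    config_error(paste0(
      "no gene has all-positive counts; rerun with pseudo_reference = TRUE ",
      "to use a positive-count pseudo-reference"))
  }
  geo <- exp(log_geo[use])
  sf <- apply(counts[use, , drop = FALSE], 2, function(col) {
    median(col / geo, na.rm = TRUE)
  })
  if (any(!is.finite(sf) | sf <= 0)) {
    config_error("size factor estimation produced non-positive factors")
  }
  sf <- sf / exp(mean(log(sf)))
  sf
}

#' Normalize counts by size factors
#'
#' @param counts Count matrix.
#' @param sf Size factors from [size_factors()].
#' @return Matrix of normalized counts.
#' @export
normalize_counts <- function(counts, sf) {
  sweep(counts, 2, sf, "/")
}

#' Per-gene dispersion with mean-trend shrinkage
#'
#' Method-of-moments gene dispersion on normalized counts: within each
#' replicate group the estimate is `(s^2 - m) / m^2`; group estimates are
#' combined weighted by degrees of freedom and truncated at zero. A
#' mean-dispersion trend `a0 + a1 / mu` is then fit across genes and each
#' gene is shrunk toward the trend with weight `shrink_weight`, stabilizing
#' the noisy per-gene estimates at small replicate numbers. Values are
#' floored at `1e-8`.
#'
#' @param counts Count matrix (genes x samples).
#' @param sf Size factors.
#' @param groups Factor of replicate groups (same length as samples).
#' @param shrink_weight Weight of the trend in the final estimate, in
#'   `[0, 1]`.
#' @return Numeric dispersion vector (one per gene) with the raw estimates in
#'   `attr(, "raw")` and trend values in `attr(, "trend")`.
#' @export
estimate_dispersion <- function(counts, sf, groups, shrink_weight = 0.8) {
  groups <- droplevels(as.factor(groups))
  tab <- table(groups)
  if (all(tab < 2)) {
    config_error("dispersion estimation needs >= 2 replicates in some group")
  }
  norm <- normalize_counts(counts, sf)
  raw <- numeric(nrow(norm))
  mu_bar <- rowMeans(norm)
  num <- numeric(nrow(norm))
  den <- numeric(nrow(norm))
  for (g in levels(groups)) {
    idx <- groups == g
    n_g <- sum(idx)
    if (n_g < 2) next
    sub <- norm[, idx, drop = FALSE]
    m <- rowMeans(sub)
    v <- apply(sub, 1, var)
    a_g <- ifelse(m > 0, (v - m) / m^2, 0)
    num <- num + (n_g - 1) * a_g
    den <- den + (n_g - 1)
  }
  raw <- pmax(num / den, 0)
  trend <- fit_dispersion_trend(raw, mu_bar)
  out <- pmax((1 - shrink_weight) * raw + shrink_weight * trend, 1e-8)
  names(out) <- rownames(counts)
  attr(out, "raw") <- raw
  attr(out, "trend") <- trend
  out
}

# Mean-dispersion trend a0 + a1/mu fit by least squares on genes with
# informative estimates; coefficients clamped to be non-negative.
#' @noRd
fit_dispersion_trend <- function(raw, mu) {
  use <- mu > 1 & raw > 0
  if (sum(use) < 10) {
    fallback <- if (any(raw > 0)) mean(raw[raw > 0]) else 1e-8
    return(rep(max(fallback, 1e-8), length(raw)))
  }
  fit <- lm(raw[use] ~ I(1 / mu[use]))
  a0 <- max(coef(fit)[1], 1e-8)
  a1 <- max(coef(fit)[2], 0)
  pmax(a0 + a1 / pmax(mu, 1e-8), 1e-8)
}

# NB deviance for IRLS convergence monitoring.
#' @noRd
nb_deviance <- function(y, mu, alpha) {
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  if (alpha < 1e-10) {
    2 * sum(t1 - (y - mu))
  } else {
    k <- 1 / alpha
    2 * sum(t1 - (y + k) * log((y + k) / (mu + k)))
  }
}

# One-gene NB log-link GLM by IRLS with fixed dispersion and offset.
#' @noRd
nb_irls <- function(y, X, offset, alpha, tol = 1e-8, max_iter = 100L) {
  p <- ncol(X)
  eta0 <- log(pmax(y, 0.5)) - offset
  beta <- tryCatch(qr.solve(X, eta0), error = function(e) rep(0, p))
  dev_old <- Inf
  converged <- FALSE
  XtWX <- NULL
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    Xw <- X * w
    XtWX <- crossprod(X, Xw)
    beta_new <- tryCatch(solve(XtWX, crossprod(Xw, z)),
                         error = function(e) NULL)
    if (is.null(beta_new)) break
    beta <- drop(beta_new)
    eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
    mu <- exp(eta)
    dev <- nb_deviance(y, mu, alpha)
    if (is.finite(dev) && abs(dev - dev_old) < tol * (abs(dev) + 0.1)) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  se <- rep(NA_real_, p)
  if (!is.null(XtWX)) {
    cv <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (!is.null(cv)) se <- sqrt(pmax(diag(cv), 0))
  }
  list(beta = beta, se = se, converged = converged)
}

#' Negative-binomial Wald test for a two-group contrast
#'
#' Fits, per gene, an NB log-link GLM with intercept, optional batch
#' covariates and a condition term, using the log size factors as offset and
#' the supplied dispersions as fixed. The reported `log2FoldChange` is the
#' condition coefficient divided by `ln 2` (treatment over control), `stat`
#' its Wald statistic, and p-values come from the standard-normal reference.
#' Genes with zero counts across all compared samples are excluded before
#' testing. Adjusted p-values are Benjamini-Hochberg across the tested genes.
#'
#' @param counts Count matrix restricted to the compared samples.
#' @param sf Size factors for those samples.
#' @param dispersions Per-gene dispersion vector.
#' @param condition Factor/character of length `ncol(counts)` with exactly
#'   two levels.
#' @param ref Reference (control) level of `condition`; defaults to the
#'   first level.
#' @param covariates Optional data frame of additional design covariates
#'   (e.g. the experiment/batch identifier for the batch-aware class design).
#' @param tol,max_iter IRLS convergence tolerance on deviance and iteration
#'   cap; non-converged genes are flagged, not dropped.
#' @return Data frame with one row per tested gene:
#'   `gene_id`, `ctr_read_counts`, `treat_read_counts`, `baseMean`,
#'   `log2FoldChange`, `lfcSE`, `stat`, `pvalue`, `padj`, `dispersion`,
#'   `converged`.
#' @export
nb_wald_test <- function(counts, sf, dispersions, condition, ref = NULL,
                         covariates = NULL, tol = 1e-8, max_iter = 100L) {
  condition <- as.factor(condition)
  if (nlevels(droplevels(condition)) != 2L) {
    config_error("condition must have exactly two levels")
  }
  condition <- droplevels(condition)
  if (!is.null(ref)) condition <- stats::relevel(condition, ref = ref)
  if (length(condition) != ncol(counts)) {
    config_error("condition length does not match sample count")
  }

  if (is.null(covariates)) {
    X <- model.matrix(~condition)
  } else {
    dd <- cbind(as.data.frame(covariates), .cond = condition)
    X <- model.matrix(~., data = dd)
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    config_error("design is confounded; collinear column(s): %s",
                 paste(bad, collapse = ", "))
  }
  cond_col <- ncol(X)  # condition term is last by construction

  offset <- log(sf)
  norm <- normalize_counts(counts, sf)
  is_treat <- condition == levels(condition)[2]

  keep <- rowSums(counts) > 0
  genes <- rownames(counts)
  ln2 <- log(2)

  res <- data.frame(
    gene_id = genes,
    ctr_read_counts = rowMeans(norm[, !is_treat, drop = FALSE]),
    treat_read_counts = rowMeans(norm[, is_treat, drop = FALSE]),
    baseMean = rowMeans(norm),
    log2FoldChange = NA_real_, lfcSE = NA_real_, stat = NA_real_,
    pvalue = NA_real_, padj = NA_real_,
    dispersion = as.numeric(dispersions),
    converged = NA,
    stringsAsFactors = FALSE
  )
  for (i in which(keep)) {
    fit <- nb_irls(counts[i, ], X, offset, dispersions[i],
                   tol = tol, max_iter = max_iter)
    res$log2FoldChange[i] <- fit$beta[cond_col] / ln2
    res$lfcSE[i] <- fit$se[cond_col] / ln2
    res$stat[i] <- fit$beta[cond_col] / fit$se[cond_col]
    res$pvalue[i] <- 2 * pnorm(-abs(res$stat[i]))
    res$converged[i] <- fit$converged
  }
  res$padj <- bh_adjust(res$pvalue)
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' missing values propagate.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    config_error("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Significance filter for differential-expression results
#'
#' Keeps genes with `baseMean > basemean_min`, `padj < padj_max` and
#' `|log2FoldChange| > lfc_min` (all inequalities strict). The defaults are
#' the study cut-offs: baseMean above 10, adjusted p below 0.05, absolute
#' log2 fold change above 0.585 (i.e. 1.5-fold).
#'
#' @param results A [nb_wald_test()] result (or any data frame with the
#'   `baseMean`, `padj`, `log2FoldChange` columns).
#' @param padj_max,lfc_min,basemean_min Thresholds.
#' @return The filtered data frame.
#' @export
significance_filter <- function(results, padj_max = 0.05, lfc_min = 0.585,
                                basemean_min = 10) {
  keep <- !is.na(results$padj) &
    results$baseMean > basemean_min &
    results$padj < padj_max &
    abs(results$log2FoldChange) > lfc_min
  results[keep, , drop = FALSE]
}

#' Write a differential-expression table
#'
#' Emits the standard per-gene output column set (control and treatment mean
#' normalized counts, baseMean, log2FoldChange, lfcSE, stat, pvalue, padj).
#'
#' @param res A [nb_wald_test()] result.
#' @param path Output TSV.
#' @return Invisibly, `path`.
#' @export
write_de_table <- function(res, path) {
  cols <- c("gene_id", "ctr_read_counts", "treat_read_counts", "baseMean",
            "log2FoldChange", "lfcSE", "stat", "pvalue", "padj")
  write.table(res[, cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
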