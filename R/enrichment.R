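# Over-representation analysis (hypergeometric Z-score + permutation p) and
# upstream-regulator activation z-scores on explicit signed networks.

#' Read a GMT gene-set file
#'
#' Tab-delimited GMT: set name, description, then member gene symbols.
#' Members are de-duplicated; sets without members are dropped with a
#' warning.
#'
#' @param path GMT file.
#' @return Named list of character vectors of class `geneset_db`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  db <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L) {
      config_error("malformed GMT line %d: fewer than 2 tab-separated fields", i)
    }
    members <- unique(trimws(parts[-(1:2)]))
    members <- members[nzchar(members)]
    if (length(members) == 0L) {
      warning(sprintf("GMT set '%s' (line %d) has no members; dropped",
                      parts[1], i), call. = FALSE)
      next
    }
    db[[parts[1]]] <- members
  }
  structure(db, class = c("geneset_db", "list"), source = path)
}

#' Hypergeometric over-representation Z-score
#'
#' For a universe of `N` measured genes of which `R` meet the selection
#' criteria, and a set containing `n` measured genes of which `r` are
#' selected, the Z-score standardizes `r` by the hypergeometric mean `nR/N`
#' and finite-population variance:
#' `Z = (r - nR/N) / sqrt(n (R/N) (1 - R/N) (1 - (n-1)/(N-1)))`.
#' Z = 0 when the set's selected fraction matches the universe.
#'
#' @param N Total measured genes.
#' @param R Selected genes in the universe.
#' @param n Measured genes in the set (must satisfy `1 <= n < N`).
#' @param r Selected genes in the set (vectorized).
#' @return Z-score(s).
#' @export
ora_zscore <- function(N, R, n, r) {
  if (n < 1 || n >= N) {
    config_error("ora_zscore requires 1 <= n < N (got n = %d, N = %d)", n, N)
  }
  if (R < 0 || R > N || any(r < 0) || any(r > pmin(n, R))) {
    config_error("invalid counts: need 0 <= r <= min(n, R) and 0 <= R <= N")
  }
  p <- R / N
  denom <- sqrt(n * p * (1 - p) * (1 - (n - 1) / (N - 1)))
  num <- r - n * p
  if (denom == 0) {
    return(ifelse(num == 0, 0, sign(num) * Inf))
  }
  num / denom
}

#' Permutation p-value for a gene set's Z-score
#'
#' Permutes the selection labels uniformly over the measured universe
#' `n_perm` times, recomputing the Z-score each time. The reported p is the
#' add-one-corrected one-sided exceedance probability
#' `(1 + #(Z_perm >= Z_obs)) / (1 + n_perm)`.
#'
#' @param universe Character vector of measured genes.
#' @param selected Character vector of selected genes (subset of universe).
#' @param geneset Character vector of set members.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @return List with `z`, `perm_p` and the `(N, R, n, r)` counts.
#' @export
permutation_pvalue <- function(universe, selected, geneset, n_perm = 1000L,
                               seed = 1L) {
  if (n_perm < 1) config_error("n_perm must be >= 1")
  sel <- universe %in% selected
  in_set <- universe %in% geneset
  N <- length(universe); R <- sum(sel); n <- sum(in_set); r <- sum(sel & in_set)
  z_obs <- ora_zscore(N, R, n, r)
  r_perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) sum(sel[sample.int(N)] & in_set),
           numeric(1))
  })
  z_perm <- ora_zscore(N, R, n, r_perm)
  perm_p <- (1 + sum(z_perm >= z_obs)) / (1 + n_perm)
  list(z = z_obs, perm_p = perm_p, N = N, R = R, n = n, r = r)
}

#' Run over-representation analysis across a gene-set database
#'
#' The universe is the baseMean-filtered measured gene list of a
#' differential-expression result and the selection is its significant
#' subset (the usual cut-offs applied upstream by
#' [significance_filter()]). Sets are restricted to measured genes; sets
#' with no measured member are skipped with a warning. One joint set of
#' label permutations drives every set's permutation p. A set is flagged
#' significant when `|Z| > z_min` and `perm_p < p_max`.
#'
#' @param de A [nb_wald_test()] result, or `NULL` when `universe` and
#'   `selected` are given directly.
#' @param db A `geneset_db` (named list of member vectors).
#' @param universe,selected Optional explicit universe/selection character
#'   vectors overriding the extraction from `de`.
#' @param basemean_min,padj_max,lfc_min Selection thresholds applied to `de`.
#' @param z_min,p_max Significance cut-offs on the Z-score and permutation p.
#' @param n_perm Number of label permutations.
#' @param seed Integer seed.
#' @param gene_map Optional named vector mapping probe/row ids of `de` to
#'   gene symbols before matching against the sets.
#' @return Data frame: `set`, `N`, `R`, `n`, `r`, `Z`, `perm_p`,
#'   `significant`, sorted by decreasing Z.
#' @export
run_ora <- function(de = NULL, db, universe = NULL, selected = NULL,
                    basemean_min = 10, padj_max = 0.05, lfc_min = 0.585,
                    z_min = 2, p_max = 0.05, n_perm = 1000L, seed = 1L,
                    gene_map = NULL) {
  if (is.null(universe)) {
    keep <- !is.na(de$baseMean) & de$baseMean > basemean_min
    universe <- de$gene_id[keep]
    sig <- significance_filter(de, padj_max = padj_max, lfc_min = lfc_min,
                               basemean_min = basemean_min)
    selected <- sig$gene_id
  }
  if (!is.null(gene_map)) {
    universe <- unique(unname(gene_map[universe]))
    selected <- unique(unname(gene_map[selected]))
  }
  universe <- unique(universe)
  selected <- unique(intersect(selected, universe))
  N <- length(universe); R <- length(selected)
  sel <- universe %in% selected

  set_idx <- lapply(db, function(members) which(universe %in% members))
  empty <- vapply(set_idx, length, integer(1)) == 0
  if (any(empty)) {
    warning(sprintf("skipping %d set(s) with no measured member: %s",
                    sum(empty), paste(names(db)[empty], collapse = ", ")),
            call. = FALSE)
    set_idx <- set_idx[!empty]
  }
  if (length(set_idx) == 0L) {
    return(data.frame(set = character(0), N = integer(0), R = integer(0),
                      n = integer(0), r = integer(0), Z = numeric(0),
                      perm_p = numeric(0), significant = logical(0)))
  }

  perm_sel <- withr::with_seed(seed, {
    matrix(sel[vapply(seq_len(n_perm), function(i) sample.int(N),
                      integer(N))], nrow = N)
  })

  rows <- lapply(names(set_idx), function(nm) {
    idx <- set_idx[[nm]]
    n <- length(idx)
    r <- sum(sel[idx])
    z <- ora_zscore(N, R, n, r)
    r_perm <- colSums(perm_sel[idx, , drop = FALSE])
    z_perm <- ora_zscore(N, R, n, r_perm)
    perm_p <- (1 + sum(z_perm >= z)) / (1 + n_perm)
    data.frame(set = nm, N = N, R = R, n = n, r = r, Z = z, perm_p = perm_p,
               significant = abs(z) > z_min & perm_p < p_max,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$Z), , drop = FALSE]
}

#' Activation z-score of one regulator
#'
#' Weight-normalized agreement between a regulator's expected regulation
#' directions and the observed directions of its differentially expressed
#' targets: `z = sum(w * s_R * s_D) / sqrt(sum(w^2))` over the overlapping
#' targets. `|z| >= 2` predicts activation (positive) or inhibition
#' (negative); fewer extreme values give no state call. With zero
#' overlapping targets the z-score is undefined and flagged.
#'
#' @param edges Data frame of the regulator's edges with columns `target`,
#'   `sign` (+1/-1 expected regulation direction) and `weight` (>= 0).
#' @param observed Named numeric vector of observed directions (+1/-1) for
#'   the differentially expressed genes; targets absent from it are excluded
#'   from the sums.
#' @return List with `activation_z`, `n_overlap` and `predicted_state`
#'   (`"activated"`, `"inhibited"` or `"none"`).
#' @export
activation_zscore <- function(edges, observed) {
  if (anyDuplicated(edges$target)) {
    config_error("duplicate (regulator, target) edges")
  }
  idx <- match(edges$target, names(observed))
  ok <- !is.na(idx)
  if (!any(ok)) {
    return(list(activation_z = NA_real_, n_overlap = 0L,
                predicted_state = "none"))
  }
  w <- edges$weight[ok]
  s_r <- edges$sign[ok]
  s_d <- unname(observed[idx[ok]])
  z <- sum(w * s_r * s_d) / sqrt(sum(w^2))
  state <- if (z >= 2) "activated" else if (z <= -2) "inhibited" else "none"
  list(activation_z = z, n_overlap = sum(ok), predicted_state = state)
}

#' Right-tailed Fisher overlap p-value
#'
#' Tests whether the overlap between a regulator's targets and the selected
#' gene list exceeds chance, via the right tail of Fisher's exact test on
#' the 2x2 membership table over the measured universe.
#'
#' @param regulator_targets Character vector of targets (within universe).
#' @param selected_genes Character vector of selected genes.
#' @param universe Character vector of measured genes.
#' @return The one-sided p-value.
#' @export
overlap_pvalue <- function(regulator_targets, selected_genes, universe) {
  targets <- intersect(unique(regulator_targets), universe)
  selected <- intersect(unique(selected_genes), universe)
  if (length(targets) == 0L) return(1)
  a <- length(intersect(targets, selected))
  b <- length(targets) - a
  c3 <- length(selected) - a
  d <- length(universe) - a - b - c3
  fisher.test(matrix(c(a, b, c3, d), 2, byrow = TRUE),
              alternative = "greater")$p.value
}

#' Upstream-regulator analysis over a signed network
#'
#' For every regulator in the network, computes the activation z-score from
#' the observed directions of the significant genes and the Fisher overlap
#' p-value against the measured universe, then adjusts the overlap p-values
#' by Benjamini-Hochberg across regulators. A regulator is flagged
#' significant when its state is called (`|z| >= 2`) and its adjusted
#' overlap p is below `padj_max`.
#'
#' @param network Data frame of edges: `regulator`, `target`, `sign`,
#'   `weight`.
#' @param de A [nb_wald_test()] result.
#' @param basemean_min,padj_max_de,lfc_min Selection thresholds on `de`.
#' @param padj_max Significance threshold on the adjusted overlap p.
#' @return Data frame: `regulator`, `activation_z`, `n_overlap`,
#'   `overlap_p`, `overlap_padj`, `predicted_state`, `significant`.
#' @export
run_upstream <- function(network, de, basemean_min = 10, padj_max_de = 0.05,
                         lfc_min = 0.585, padj_max = 0.05) {
  universe <- de$gene_id[!is.na(de$baseMean) & de$baseMean > basemean_min]
  sig <- significance_filter(de, padj_max = padj_max_de, lfc_min = lfc_min,
                             basemean_min = basemean_min)
  observed <- setNames(sign(sig$log2FoldChange), sig$gene_id)
  regs <- unique(network$regulator)
  rows <- lapply(regs, function(rg) {
    edges <- network[network$regulator == rg, , drop = FALSE]
    az <- activation_zscore(edges, observed)
    p <- overlap_pvalue(edges$target, sig$gene_id, universe)
    data.frame(regulator = rg, activation_z = az$activation_z,
               n_overlap = az$n_overlap, overlap_p = p,
               predicted_state = az$predicted_state,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$overlap_padj <- bh_adjust(out$overlap_p)
  out$significant <- out$predicted_state != "none" &
    !is.na(out$overlap_padj) & out$overlap_padj < padj_max
  out[order(-abs(ifelse(is.na(out$activation_z), 0, out$activation_z))), ,
      drop = FALSE]
}

#' Read a 4-column signed regulator network TSV
#'
#' @param path TSV with columns `regulator`, `target`, `sign`, `weight`.
#' @return Data frame of edges.
#' @export
read_network <- function(path) {
  net <- read.delim(path, sep = detect_delimiter(path),
                    stringsAsFactors = FALSE)
  need <- c("regulator", "target", "sign", "weight")
  miss <- setdiff(need, names(net))
  if (length(miss) > 0) {
    config_error("network lacks column(s): %s", paste(miss, collapse = ", "))
  }
  if (!all(net$sign %in% c(-1, 1))) {
    config_error("network sign column must be +1 or -1")
  }
  if (any(net$weight < 0)) config_error("network weights must be >= 0")
  if (anyDuplicated(net[, c("regulator", "target")])) {
    config_error("duplicate (regulator, target) pairs in network")
  }
  net
}
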