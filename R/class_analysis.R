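# Class-level dataset assembly, intersection analysis, fold-change
# concordance and the mitotoxic subset rule.

#' Select the reference concentration of a compound
#'
#' The reference concentration is the one inducing the highest number of
#' differentially expressed genes among concentrations strictly below the
#' cytotoxicity LOEL (when one exists). Ties are broken toward the lower
#' concentration.
#'
#' @param deg_counts Named numeric vector: names are concentrations (uM),
#'   values are DEG counts.
#' @param cytotox_loel Cytotoxicity LOEL in uM, or `NULL`/`NA` when the
#'   compound shows no cytotoxicity in the tested range.
#' @return The selected concentration (numeric scalar).
#' @export
select_reference_concentration <- function(deg_counts, cytotox_loel = NULL) {
  conc <- as.numeric(names(deg_counts))
  if (any(is.na(conc))) {
    config_error("deg_counts must be named by numeric concentrations")
  }
  ord <- order(conc)
  conc <- conc[ord]
  cnt <- as.numeric(deg_counts)[ord]
  if (!is.null(cytotox_loel) && !is.na(cytotox_loel)) {
    keep <- conc < cytotox_loel
    if (!any(keep)) {
      config_error("all tested concentrations are at or above the cytotoxicity LOEL")
    }
    conc <- conc[keep]
    cnt <- cnt[keep]
  }
  conc[which.max(cnt)]  # which.max takes the first (lowest) on ties
}

#' Assemble a merged class-level dataset
#'
#' Concatenates, across experiments, the samples at each class member's
#' reference concentration together with the vehicle samples of every
#' experiment involved, preserving `experiment_id` so the batch-aware
#' `~ experiment + class` design can be fit downstream. Probes can be
#' restricted to a harmonized list.
#'
#' @param counts Full count matrix (probes x samples).
#' @param meta Sample annotation (as from [generate_experiment()] /
#'   [read_sample_meta()]).
#' @param selections Data frame with `compound` and `concentration` columns:
#'   one reference concentration per compound.
#' @param class_map Named character vector mapping compound to class.
#' @param probes_keep Optional character vector of probe ids to retain.
#' @return List with the subset `counts` and `meta`; `meta$class` holds the
#'   class label (`"vehicle"` for controls).
#' @export
build_class_dataset <- function(counts, meta, selections, class_map,
                                probes_keep = NULL) {
  miss <- setdiff(selections$compound, names(class_map))
  if (length(miss) > 0) {
    config_error("no class mapping for compound(s): %s",
                 paste(miss, collapse = ", "))
  }
  key <- paste(meta$compound, meta$concentration)
  want <- paste(selections$compound, selections$concentration)
  treated <- meta[key %in% want & !meta$is_vehicle, , drop = FALSE]
  if (nrow(treated) == 0L) {
    config_error("no samples match the requested reference concentrations")
  }
  exps <- unique(treated$experiment_id)
  vehicles <- meta[meta$is_vehicle & meta$experiment_id %in% exps, ,
                   drop = FALSE]
  no_veh <- setdiff(exps, unique(vehicles$experiment_id))
  if (length(no_veh) > 0) {
    config_error("experiment(s) without vehicle samples: %s",
                 paste(no_veh, collapse = ", "))
  }
  sub <- rbind(vehicles, treated)
  sub$class <- ifelse(sub$is_vehicle, "vehicle",
                      unname(class_map[sub$compound]))
  cm <- counts[, sub$sample_id, drop = FALSE]
  if (!is.null(probes_keep)) {
    cm <- cm[rownames(cm) %in% probes_keep, , drop = FALSE]
  }
  list(counts = cm, meta = sub)
}

#' Three-set intersection summary
#'
#' Computes all seven regions of the three-class Venn diagram of significant
#' gene sets: the triple intersection, the three pairwise-only regions and
#' the three class-unique regions.
#'
#' @param set_ci,set_cii,set_ciii Character vectors of significant genes per
#'   class (over a common universe).
#' @return List of class `class_set_summary` with `regions` (named list of
#'   gene vectors), `counts` (named integer vector) and `union_size`.
#' @export
intersect_sets <- function(set_ci, set_cii, set_ciii) {
  a <- unique(set_ci); b <- unique(set_cii); c3 <- unique(set_ciii)
  all3 <- intersect(intersect(a, b), c3)
  regions <- list(
    CI_CII_CIII = all3,
    CI_CII = setdiff(intersect(a, b), all3),
    CI_CIII = setdiff(intersect(a, c3), all3),
    CII_CIII = setdiff(intersect(b, c3), all3),
    CI_only = setdiff(a, union(b, c3)),
    CII_only = setdiff(b, union(a, c3)),
    CIII_only = setdiff(c3, union(a, b))
  )
  structure(
    list(regions = regions,
         counts = vapply(regions, length, integer(1)),
         union_size = length(union(union(a, b), c3)),
         sets = list(CI = a, CII = b, CIII = c3)),
    class = "class_set_summary"
  )
}

#' Fold-change concordance across classes
#'
#' Measures how similarly the three classes change the genes of the triple
#' intersection: the squared correlation of the pooled pairwise log2
#' fold-change pairs. In `"pooled"` mode (default) all ordered class pairs
#' are stacked into one regression, which makes the result invariant to
#' class order; `"per_pair"` returns one R-squared per unordered pair.
#'
#' @param lfc Matrix or data frame of log2 fold changes, genes x classes
#'   (>= 3 genes, >= 2 classes).
#' @param genes Optional character vector restricting rows (e.g. the
#'   intersect gene list).
#' @param mode `"pooled"` or `"per_pair"`.
#' @return Numeric R-squared (pooled) or named vector (per pair).
#' @export
concordance <- function(lfc, genes = NULL, mode = c("pooled", "per_pair")) {
  mode <- match.arg(mode)
  lfc <- as.matrix(lfc)
  if (!is.null(genes)) lfc <- lfc[rownames(lfc) %in% genes, , drop = FALSE]
  lfc <- lfc[stats::complete.cases(lfc), , drop = FALSE]
  if (nrow(lfc) < 3L) config_error("concordance needs >= 3 genes")
  k <- ncol(lfc)
  pairs <- utils::combn(k, 2)
  if (mode == "per_pair") {
    out <- apply(pairs, 2, function(pr) cor(lfc[, pr[1]], lfc[, pr[2]])^2)
    names(out) <- apply(pairs, 2, function(pr) {
      paste(colnames(lfc)[pr], collapse = "_vs_")
    })
    return(out)
  }
  # both orientations of every pair -> symmetric in class order
  x <- c(); y <- c()
  for (j in seq_len(ncol(pairs))) {
    x <- c(x, lfc[, pairs[1, j]], lfc[, pairs[2, j]])
    y <- c(y, lfc[, pairs[2, j]], lfc[, pairs[1, j]])
  }
  cor(x, y)^2
}

#' Mitotoxic compound-concentration subset
#'
#' Selects compound-concentration pairs that depress basal respiration by at
#' least `ocr_drop` percent while viability stays within the sub-cytotoxic
#' range (above `100 - max_viability_ic` percent of control): the
#' mitochondria-specific exposure set.
#'
#' @param ocr_pct Data frame with `compound`, `concentration`, `phase` and
#'   `percent_of_control` (as from [ocr_percent_of_control()]); only the
#'   basal phase is used.
#' @param viability Data frame with `compound`, `concentration`,
#'   `viability` (percent of control).
#' @param ocr_drop Minimum OCR decrease in percent (default 40: keep OCR
#'   at or below 60% of control).
#' @param max_viability_ic Maximal tolerated inhibition of viability in
#'   percent (default 25: require viability at or above 75% of control).
#' @return Data frame of selected pairs with their mean basal OCR percent
#'   and viability.
#' @export
mitotoxic_subset <- function(ocr_pct, viability, ocr_drop = 40,
                             max_viability_ic = 25) {
  basal <- ocr_pct[ocr_pct$phase == "basal" &
                     !(ocr_pct$compound %in% c("DMSO", "positive_control")), ]
  ocr_mean <- stats::aggregate(
    percent_of_control ~ compound + concentration, basal, mean)
  via_mean <- stats::aggregate(
    viability ~ compound + concentration, viability, mean)
  m <- merge(ocr_mean, via_mean, by = c("compound", "concentration"))
  sel <- m$percent_of_control <= (100 - ocr_drop) &
    m$viability >= (100 - max_viability_ic)
  out <- m[sel, , drop = FALSE]
  out[order(out$compound, out$concentration), , drop = FALSE]
}

#' Write class set lists with per-class statistics
#'
#' Mirrors the supplementary-style gene lists: per Venn region one block of
#' genes with each class's log2 fold change, baseMean and adjusted p.
#'
#' @param summary A [intersect_sets()] result.
#' @param de_by_class Named list of per-class [nb_wald_test()] results.
#' @param path Output TSV.
#' @return Invisibly, `path`.
#' @export
write_class_sets <- function(summary, de_by_class, path) {
  rows <- list()
  for (region in names(summary$regions)) {
    genes <- summary$regions[[region]]
    if (length(genes) == 0) next
    block <- data.frame(region = region, gene_id = genes,
                        stringsAsFactors = FALSE)
    for (cl in names(de_by_class)) {
      de <- de_by_class[[cl]]
      idx <- match(genes, de$gene_id)
      block[[paste0(cl, "_log2FC")]] <- de$log2FoldChange[idx]
      block[[paste0(cl, "_baseMean")]] <- de$baseMean[idx]
      block[[paste0(cl, "_padj")]] <- de$padj[idx]
    }
    rows[[region]] <- block
  }
  out <- do.call(rbind, rows)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
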