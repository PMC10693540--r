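# Count table and probe-panel I/O, library-size QC, probe harmonization.

#' Read a probe-by-sample count table
#'
#' Reads a delimited text count table whose first column holds probe
#' identifiers. The delimiter (tab or comma) is detected from the header
#' line. Counts must be non-negative integers; malformed cells are rejected
#' with the offending probe and sample named.
#'
#' @param path Count table file.
#' @param annotation_path Optional probe annotation file with columns
#'   `probe_id`, `gene_symbol` and (optionally) `panel_version`.
#' @return List with `counts` (integer matrix, probes x samples) and
#'   `probes` (annotation data frame or `NULL`).
#' @export
read_counts <- function(path, annotation_path = NULL) {
  if (!file.exists(path)) config_error("count file not found: %s", path)
  sep <- detect_delimiter(path)
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    warning("count table has a header but no data rows; returning empty matrix",
            call. = FALSE)
    m <- matrix(integer(0), nrow = 0, ncol = max(ncol(df) - 1L, 0L),
                dimnames = list(NULL, if (ncol(df) > 1) names(df)[-1]))
    return(list(counts = m, probes = read_probe_annotation(annotation_path)))
  }
  probe_ids <- as.character(df[[1]])
  dup <- probe_ids[duplicated(probe_ids)]
  if (length(dup) > 0) {
    config_error("duplicated probe id(s): %s",
                 paste(unique(dup), collapse = ", "))
  }
  vals <- df[, -1, drop = FALSE]
  m <- as.matrix(vals)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(
      matrix(as.numeric(m), nrow(m)))) & !is.na(m), arr.ind = TRUE)
    loc <- if (nrow(bad) > 0) {
      sprintf(" (first at probe %s, sample %s)",
              probe_ids[bad[1, 1]], colnames(m)[bad[1, 2]])
    } else ""
    config_error("non-numeric count cells%s", loc)
  }
  bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    config_error("non-integer or negative count at probe %s, sample %s",
                 probe_ids[bad[1, 1]], colnames(m)[bad[1, 2]])
  }
  storage.mode(m) <- "integer"
  rownames(m) <- probe_ids
  list(counts = m, probes = read_probe_annotation(annotation_path))
}

#' @noRd
detect_delimiter <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' @noRd
read_probe_annotation <- function(path) {
  if (is.null(path)) return(NULL)
  ann <- read.delim(path, sep = detect_delimiter(path),
                    stringsAsFactors = FALSE)
  need <- c("probe_id", "gene_symbol")
  miss <- setdiff(need, names(ann))
  if (length(miss) > 0) {
    config_error("probe annotation lacks column(s): %s",
                 paste(miss, collapse = ", "))
  }
  ann$gene_symbol <- trimws(ann$gene_symbol)
  ann
}

#' Read a sample annotation table
#'
#' @param path Delimited text file with at least `sample_id`, `compound`,
#'   `concentration`, `experiment_id` and `is_vehicle` columns.
#' @return Data frame with typed columns.
#' @export
read_sample_meta <- function(path) {
  meta <- read.delim(path, sep = detect_delimiter(path),
                     stringsAsFactors = FALSE)
  need <- c("sample_id", "compound", "concentration", "experiment_id",
            "is_vehicle")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0) {
    config_error("sample metadata lacks column(s): %s",
                 paste(miss, collapse = ", "))
  }
  meta$concentration <- as.numeric(meta$concentration)
  meta$is_vehicle <- as.logical(meta$is_vehicle)
  if (anyDuplicated(meta$sample_id)) {
    config_error("duplicated sample_id in metadata")
  }
  meta
}

#' Remove samples with low library size
#'
#' Quality-control step dropping samples whose total read count falls below
#' `min_reads` (default 200,000). The threshold is strict: a sample at
#' exactly `min_reads` is retained.
#'
#' @param counts Integer count matrix (probes x samples).
#' @param min_reads Minimum library size.
#' @return The filtered matrix; removed sample ids in
#'   `attr(, "removed_samples")`.
#' @export
filter_library_size <- function(counts, min_reads = 200000) {
  lib <- colSums(counts)
  drop <- lib < min_reads
  if (all(drop)) {
    config_error("all %d samples fall below the library-size threshold %g",
                 ncol(counts), min_reads)
  }
  if (any(drop)) {
    message(sprintf("filter_library_size: removing %d sample(s): %s",
                    sum(drop), paste(colnames(counts)[drop], collapse = ", ")))
  }
  out <- counts[, !drop, drop = FALSE]
  attr(out, "removed_samples") <- colnames(counts)[drop]
  out
}

#' Harmonize probes across two panel versions
#'
#' Two probe panels measuring the same genes may use different probes. Probes
#' with identical identifiers in both panels are kept outright. For genes
#' measured by differing probes, the gene is kept when the two panels give a
#' similar response to a common reference treatment: the sample standard
#' deviation of the paired per-gene log2 fold changes (for a pair,
#' `|delta| / sqrt(2)`), written SDp, must fall below `sdp_max` (default
#' 0.1). All other probes are excluded.
#'
#' @param log2fc_a,log2fc_b Named per-probe log2 fold changes for the same
#'   reference treatment in panels A and B.
#' @param annot_a,annot_b Probe annotations (`probe_id`, `gene_symbol`) for
#'   the two panels.
#' @param sdp_max Similarity threshold on SDp (log2FC units).
#' @return List of class `harmonization_result` with elements `probes` (per
#'   probe: gene, panel, rule in `shared`/`concordant`/`excluded`, SDp),
#'   `kept_probes`, and `kept_genes`.
#' @export
harmonize_panels <- function(log2fc_a, log2fc_b, annot_a, annot_b,
                             sdp_max = 0.1) {
  annot_a$gene_symbol <- trimws(annot_a$gene_symbol)
  annot_b$gene_symbol <- trimws(annot_b$gene_symbol)
  if (length(intersect(annot_a$gene_symbol, annot_b$gene_symbol)) == 0L) {
    config_error("panels share no genes; cannot harmonize")
  }
  shared <- intersect(annot_a$probe_id, annot_b$probe_id)

  gene_of_a <- setNames(annot_a$gene_symbol, annot_a$probe_id)
  gene_of_b <- setNames(annot_b$gene_symbol, annot_b$probe_id)

  # per-gene mean log2FC over each panel's non-shared probes
  gene_value <- function(annot, lfc) {
    own <- annot[!(annot$probe_id %in% shared), , drop = FALSE]
    v <- lfc[own$probe_id]
    tapply(v, own$gene_symbol, mean, na.rm = TRUE)
  }
  va <- gene_value(annot_a, log2fc_a)
  vb <- gene_value(annot_b, log2fc_b)
  both <- intersect(names(va), names(vb))
  sdp <- abs(va[both] - vb[both]) / sqrt(2)
  concordant_genes <- both[is.finite(sdp) & sdp < sdp_max]

  all_probes <- rbind(
    data.frame(probe_id = annot_a$probe_id, gene_symbol = annot_a$gene_symbol,
               panel = "A", stringsAsFactors = FALSE),
    data.frame(probe_id = annot_b$probe_id, gene_symbol = annot_b$gene_symbol,
               panel = "B", stringsAsFactors = FALSE)
  )
  all_probes <- all_probes[!duplicated(all_probes$probe_id) |
                             !(all_probes$probe_id %in% shared), ]
  rule <- ifelse(all_probes$probe_id %in% shared, "shared",
                 ifelse(all_probes$gene_symbol %in% concordant_genes,
                        "concordant", "excluded"))
  all_probes$rule <- rule
  all_probes$sdp <- unname(sdp[match(all_probes$gene_symbol, both)])
  all_probes$sdp[rule == "shared"] <- NA_real_

  kept <- all_probes$probe_id[rule != "excluded"]
  structure(
    list(probes = all_probes,
         kept_probes = unique(kept),
         kept_genes = unique(all_probes$gene_symbol[rule != "excluded"]),
         sdp = sdp,
         sdp_max = sdp_max),
    class = "harmonization_result"
  )
}

#' Write a harmonization report
#'
#' @param hr A [harmonize_panels()] result.
#' @param path Output TSV.
#' @return Invisibly, `path`.
#' @export
write_harmonization_report <- function(hr, path) {
  write.table(hr$probes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
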