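# End-to-end orchestration: declarative YAML configuration, staged
# execution, TSV report tables and a reproducibility manifest.

#' Default analysis thresholds
#'
#' The significance and selection cut-offs used throughout: adjusted p
#' below 0.05, absolute log2 fold change above 0.585 (1.5-fold), baseMean
#' above 10, library size at least 200,000 reads, ORA |Z| above 2 with
#' permutation p below 0.05, Williams trend p below 0.05 with 1.5-fold
#' change, a 40 percent OCR drop and a 25 percent maximal viability
#' inhibition for the mitotoxic subset.
#'
#' @return Named list of thresholds.
#' @export
default_thresholds <- function() {
  list(
    padj = 0.05,
    lfc = 0.585,
    base_mean = 10,
    library_size = 200000,
    ora_z = 2,
    ora_perm_p = 0.05,
    williams_p = 0.05,
    williams_fc = 1.5,
    ocr_drop = 40,
    viability_ic = 25
  )
}

#' Validate a pipeline configuration
#'
#' Reads a YAML configuration (or takes an equivalent list), applies
#' defaults, rejects unknown keys and checks threshold positivity and path
#' existence. When `simulate` is absent or false, the `counts` and
#' `sample_meta` paths are mandatory.
#'
#' @param config Path to a YAML file or a named list.
#' @return Validated configuration list of class `pipeline_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) config_error("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  known_top <- c("simulate", "sim", "paths", "thresholds", "n_perm_ora",
                 "n_perm_williams", "n_decoy_sets", "seed", "output_dir",
                 "run_bmd_stage")
  unknown <- setdiff(names(config), known_top)
  if (length(unknown) > 0) {
    config_error("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", "))
  }
  thr <- default_thresholds()
  if (!is.null(config$thresholds)) {
    bad <- setdiff(names(config$thresholds), names(thr))
    if (length(bad) > 0) {
      config_error("unknown threshold key(s): %s", paste(bad, collapse = ", "))
    }
    thr[names(config$thresholds)] <- config$thresholds
  }
  if (any(unlist(thr) <= 0)) {
    config_error("all thresholds must be positive")
  }
  out <- list(
    simulate = isTRUE(config$simulate),
    sim = config$sim,
    paths = config$paths,
    thresholds = thr,
    n_perm_ora = config$n_perm_ora %||% 1000L,
    n_perm_williams = config$n_perm_williams %||% 500L,
    n_decoy_sets = config$n_decoy_sets %||% 50L,
    seed = as.integer(config$seed %||% 1L),
    output_dir = config$output_dir %||% tempfile("etcsig_run_"),
    run_bmd_stage = config$run_bmd_stage %||% TRUE
  )
  if (!out$simulate) {
    for (key in c("counts", "sample_meta")) {
      if (is.null(out$paths[[key]])) {
        config_error("missing mandatory path: %s", key)
      }
      if (!file.exists(out$paths[[key]])) {
        config_error("path for '%s' does not exist: %s", key,
                     out$paths[[key]])
      }
    }
  }
  class(out) <- "pipeline_config"
  out
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: data acquisition (simulation or file
#' input), library-size QC, per-compound differential expression at every
#' concentration, reference-concentration selection, merged batch-aware
#' class analysis, intersection and concordance, over-representation and
#' upstream-regulator analysis, Williams/Exp5 benchmark-dose modelling, OCR
#' normalization and the mitotoxic subset. Writes one TSV per report table
#' plus a JSON run manifest recording seeds, thresholds, package version and
#' warning counts. Deterministic given the configured seed.
#'
#' @param config A [validate_config()] result (or something coercible).
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  thr <- config$thresholds
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  n_warn <- 0L
  note <- function(...) message(sprintf(...))

  # -- data ------------------------------------------------------------------
  dat <- stage("data", {
    if (config$simulate) {
      sim_args <- config$sim %||% list()
      sim_args$seed <- sim_args$seed %||% config$seed
      cfg <- do.call(sim_config, sim_args)
      sim <- generate_experiment(cfg)
      gs <- generate_genesets(sim$truth, n_decoy_sets = config$n_decoy_sets,
                              seed = config$seed + 1L)
      net <- generate_regulator_network(sim$truth, seed = config$seed + 2L)
      ocr <- generate_ocr_table(cfg, seed = config$seed + 3L)
      via <- generate_viability_table(cfg, seed = config$seed + 4L)
      list(counts = sim$counts, meta = sim$meta, probes = sim$probes,
           truth = sim$truth, genesets = gs, network = net, ocr = ocr,
           viability = via, sim_config = cfg)
    } else {
      rc <- read_counts(config$paths$counts, config$paths$probes)
      meta <- read_sample_meta(config$paths$sample_meta)
      gs <- if (!is.null(config$paths$genesets)) {
        read_gmt(config$paths$genesets)
      }
      net <- if (!is.null(config$paths$network)) {
        read_network(config$paths$network)
      }
      ocr <- if (!is.null(config$paths$ocr)) {
        read.delim(config$paths$ocr, stringsAsFactors = FALSE)
      }
      via <- if (!is.null(config$paths$viability)) {
        read.delim(config$paths$viability, stringsAsFactors = FALSE)
      }
      list(counts = rc$counts, meta = meta, probes = rc$probes, truth = NULL,
           genesets = gs, network = net, ocr = ocr, viability = via)
    }
  })
  gene_map <- if (!is.null(dat$probes)) {
    setNames(dat$probes$gene_symbol, dat$probes$probe_id)
  }

  # -- qc --------------------------------------------------------------------
  counts <- stage("qc", {
    out <- withCallingHandlers(
      filter_library_size(dat$counts, min_reads = thr$library_size),
      message = function(m) invokeRestart("muffleMessage"))
    out
  })
  meta <- dat$meta[match(colnames(counts), dat$meta$sample_id), ]
  n_warn <- n_warn + length(attr(counts, "removed_samples"))

  # -- per-compound differential expression ----------------------------------
  de_compound <- stage("de", {
    res <- list()
    compounds <- setdiff(unique(meta$compound), "DMSO")
    for (cmp in compounds) {
      exps <- unique(meta$experiment_id[meta$compound == cmp])
      for (d in sort(unique(meta$concentration[meta$compound == cmp]))) {
        sel <- (meta$compound == cmp & meta$concentration == d) |
          (meta$is_vehicle & meta$experiment_id %in% exps)
        sub_meta <- meta[sel, ]
        sub_counts <- counts[, sub_meta$sample_id, drop = FALSE]
        cond <- factor(ifelse(sub_meta$is_vehicle, "vehicle", "treated"),
                       levels = c("vehicle", "treated"))
        sf <- size_factors(sub_counts, pseudo_reference = TRUE)
        disp <- estimate_dispersion(sub_counts, sf, cond)
        de <- nb_wald_test(sub_counts, sf, disp, cond, ref = "vehicle")
        res[[paste(cmp, d, sep = "@")]] <- de
      }
    }
    res
  })

  deg_counts <- stage("reference_selection", {
    lapply(split(names(de_compound),
                 sub("@.*", "", names(de_compound))), function(keys) {
      cnt <- vapply(keys, function(k) {
        nrow(significance_filter(de_compound[[k]], thr$padj, thr$lfc,
                                 thr$base_mean))
      }, numeric(1))
      setNames(cnt, sub(".*@", "", keys))
    })
  })

  viability_loels <- stage("cytotox_loel", {
    if (is.null(dat$viability)) {
      NULL
    } else {
      # viability already percent of control: LOEL from one-sample-ish rule,
      # flag concentrations below the viability-IC threshold instead of a
      # replicate ANOVA when the table carries single values per dose
      lapply(split(dat$viability, dat$viability$compound), function(v) {
        bad <- v$concentration[v$viability < (100 - thr$viability_ic)]
        if (length(bad) > 0) min(bad) else NA_real_
      })
    }
  })

  selections <- stage("reference_selection", {
    sel <- lapply(names(deg_counts), function(cmp) {
      loel <- viability_loels[[cmp]] %||% NA_real_
      data.frame(compound = cmp,
                 concentration = select_reference_concentration(
                   deg_counts[[cmp]], loel),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, sel)
  })

  # -- class analysis --------------------------------------------------------
  class_map <- stage("class", {
    cm <- unique(meta[!meta$is_vehicle, c("compound", "class")])
    setNames(cm$class, cm$compound)
  })
  class_res <- stage("class", {
    ds <- build_class_dataset(counts, meta, selections, class_map)
    classes <- setdiff(unique(ds$meta$class), "vehicle")
    multi_batch <- length(unique(ds$meta$experiment_id)) > 1
    de_by_class <- list()
    for (cl in classes) {
      sel <- ds$meta$class %in% c("vehicle", cl)
      sub_meta <- ds$meta[sel, ]
      sub_counts <- ds$counts[, sub_meta$sample_id, drop = FALSE]
      cond <- factor(ifelse(sub_meta$is_vehicle, "vehicle", cl),
                     levels = c("vehicle", cl))
      covs <- NULL
      if (multi_batch && length(unique(sub_meta$experiment_id)) > 1) {
        covs <- data.frame(exp_id = factor(sub_meta$experiment_id))
      }
      sf <- size_factors(sub_counts, pseudo_reference = TRUE)
      groups <- interaction(cond, sub_meta$experiment_id, drop = TRUE)
      disp <- estimate_dispersion(sub_counts, sf, groups)
      de_by_class[[cl]] <- nb_wald_test(sub_counts, sf, disp, cond,
                                        ref = "vehicle", covariates = covs)
    }
    de_by_class
  })

  sig_by_class <- lapply(class_res, significance_filter,
                         padj_max = thr$padj, lfc_min = thr$lfc,
                         basemean_min = thr$base_mean)

  sets <- stage("sets", {
    gid <- function(x) if (!is.null(gene_map)) unique(unname(gene_map[x])) else x
    intersect_sets(gid(sig_by_class[["CI"]]$gene_id),
                   gid(sig_by_class[["CII"]]$gene_id),
                   gid(sig_by_class[["CIII"]]$gene_id))
  })

  conc_r2 <- stage("sets", {
    inter <- sets$regions$CI_CII_CIII
    if (length(inter) >= 3) {
      lfc <- sapply(class_res, function(de) {
        ids <- if (!is.null(gene_map)) unname(gene_map[de$gene_id]) else de$gene_id
        setNames(de$log2FoldChange, ids)[inter]
      })
      concordance(lfc)
    } else {
      NA_real_
    }
  })

  # -- enrichment ------------------------------------------------------------
  ora_res <- stage("ora", {
    out <- if (is.null(dat$genesets)) NULL else list()
    for (cl in names(class_res)) {
      out[[cl]] <- withCallingHandlers(
        run_ora(class_res[[cl]], dat$genesets,
                basemean_min = thr$base_mean, padj_max = thr$padj,
                lfc_min = thr$lfc, z_min = thr$ora_z,
                p_max = thr$ora_perm_p, n_perm = config$n_perm_ora,
                seed = config$seed + 10L, gene_map = gene_map),
        warning = function(w) {
          n_warn <<- n_warn + 1L
          invokeRestart("muffleWarning")
        })
    }
    out
  })

  upstream_res <- stage("upstream", {
    out <- if (is.null(dat$network)) NULL else list()
    for (cl in names(class_res)) {
      de <- class_res[[cl]]
      if (!is.null(gene_map)) {
        de$gene_id <- unname(gene_map[de$gene_id])
      }
      out[[cl]] <- run_upstream(dat$network, de,
                                basemean_min = thr$base_mean,
                                padj_max_de = thr$padj, lfc_min = thr$lfc)
    }
    out
  })

  # -- dose-response / BMD ---------------------------------------------------
  bmd_res <- stage("bmd", {
    out <- if (config$run_bmd_stage) list() else NULL
    for (cmp in if (config$run_bmd_stage) selections$compound else character(0)) {
      sel <- (meta$compound == cmp) |
        (meta$is_vehicle &
           meta$experiment_id %in% meta$experiment_id[meta$compound == cmp])
      sub_meta <- meta[sel, ]
      sub_counts <- counts[, sub_meta$sample_id, drop = FALSE]
      sf <- size_factors(sub_counts, pseudo_reference = TRUE)
      norm <- normalize_counts(sub_counts, sf)
      out[[cmp]] <- bmd_pipeline(norm, sub_meta$concentration,
                                 n_perm = config$n_perm_williams,
                                 seed = config$seed + 20L,
                                 p_max = thr$williams_p,
                                 fc_min = thr$williams_fc)
    }
    out
  })

  # -- OCR -------------------------------------------------------------------
  ocr_res <- stage("ocr", {
    if (is.null(dat$ocr)) NULL else ocr_percent_of_control(dat$ocr)
  })
  mito <- stage("ocr", {
    if (is.null(ocr_res) || is.null(dat$viability)) {
      NULL
    } else {
      mitotoxic_subset(ocr_res, dat$viability,
                       ocr_drop = thr$ocr_drop,
                       max_viability_ic = thr$viability_ic)
    }
  })

  # -- reports ---------------------------------------------------------------
  outdir <- config$output_dir
  stage("report", {
    for (cl in names(class_res)) {
      write_de_table(class_res[[cl]],
                     file.path(outdir, sprintf("de_class_%s.tsv", cl)))
    }
    write.table(selections, file.path(outdir, "reference_concentrations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    venn <- data.frame(region = names(sets$counts),
                       n_genes = as.integer(sets$counts))
    write.table(venn, file.path(outdir, "venn_regions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_class_sets(sets, class_res, file.path(outdir, "class_sets.tsv"))
    if (!is.null(ora_res)) {
      for (cl in names(ora_res)) {
        write.table(ora_res[[cl]],
                    file.path(outdir, sprintf("ora_%s.tsv", cl)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    if (!is.null(upstream_res)) {
      for (cl in names(upstream_res)) {
        write.table(upstream_res[[cl]],
                    file.path(outdir, sprintf("upstream_%s.tsv", cl)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    if (!is.null(bmd_res)) {
      for (cmp in names(bmd_res)) {
        write.table(bmd_res[[cmp]],
                    file.path(outdir, sprintf("bmd_%s.tsv", cmp)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    if (!is.null(ocr_res)) {
      write.table(ocr_res, file.path(outdir, "ocr_percent.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    if (!is.null(mito)) {
      write.table(mito, file.path(outdir, "mitotoxic_subset.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  })

  manifest <- list(
    package_version = as.character(packageVersion("etcsig")),
    seed = config$seed,
    thresholds = thr,
    n_perm_ora = config$n_perm_ora,
    n_perm_williams = config$n_perm_williams,
    simulate = config$simulate,
    n_samples_removed_qc = length(attr(counts, "removed_samples")),
    n_warnings = n_warn,
    outputs = list.files(outdir)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(
    de_compound = de_compound,
    deg_counts = deg_counts,
    selections = selections,
    de_class = class_res,
    sig_by_class = sig_by_class,
    sets = sets,
    concordance_r2 = conc_r2,
    ora = ora_res,
    upstream = upstream_res,
    bmd = bmd_res,
    ocr = ocr_res,
    mitotoxic = mito,
    truth = dat$truth,
    manifest = manifest,
    output_dir = outdir
  ))
}
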