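# Synthetic experiment generator
#
# Emulates a two-batch targeted transcriptomic study of three classes of
# electron-transport-chain inhibitors: negative-binomial probe counts whose
# means follow Exp5-shaped concentration-response curves for a planted set of
# responsive genes, plus matching gene sets, signed regulator networks and
# respirometry (OCR) / viability endpoint tables.

#' Build a simulation configuration
#'
#' Collects and validates every tunable of the synthetic experiment. The
#' defaults describe the study design the package targets: ~3,000 probes, two
#' experiments (batches) run with different compounds, three inhibitor classes
#' of four compounds each, five-point log-spaced concentration series with
#' three replicates, a shared ("common") transcriptional signature plus small
#' class-unique signatures, and library sizes drawn log-normally around one
#' million reads.
#'
#' @param n_genes Number of genes on the panel.
#' @param n_probes_per_gene Probes per gene (1 or 2).
#' @param n_compounds_per_class Compounds per inhibitor class (classes are
#'   fixed at CI, CII, CIII).
#' @param concentrations Strictly increasing positive treatment
#'   concentrations in uM (vehicle at 0 is added automatically).
#' @param n_replicates Biological replicates per treatment group and per
#'   vehicle group in each batch.
#' @param n_batches Number of experiments (batches); compounds are assigned
#'   round-robin to batches.
#' @param frac_common_signature Fraction of genes responding to all three
#'   classes.
#' @param frac_class_unique Fraction of genes responding to exactly one class
#'   (applied per class).
#' @param effect_log2fc Peak (asymptotic) absolute log2 fold change of
#'   responsive genes.
#' @param exp5_g Shape exponent g of the Exp5 response curve shared by all
#'   responsive genes.
#' @param dispersion Negative-binomial dispersion alpha (variance =
#'   mu + alpha * mu^2).
#' @param library_size_mean,library_size_cv Mean and coefficient of variation
#'   of the log-normal library-size distribution.
#' @param batch_sd Standard deviation (log scale) of the gene-wise
#'   multiplicative batch factor applied to batches beyond the first.
#' @param prob_up Probability that a responsive gene is up- (vs down-)
#'   regulated.
#' @param seed Integer seed; identical seeds give bit-identical output.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 3000L,
                       n_probes_per_gene = 1L,
                       n_compounds_per_class = 4L,
                       concentrations = signif(10^seq(-2, 1, length.out = 5), 3),
                       n_replicates = 3L,
                       n_batches = 2L,
                       frac_common_signature = 0.10,
                       frac_class_unique = 0.03,
                       effect_log2fc = 2,
                       exp5_g = 1,
                       dispersion = 0.05,
                       library_size_mean = 1e6,
                       library_size_cv = 0.4,
                       batch_sd = 0.1,
                       prob_up = 0.5,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_probes_per_gene = as.integer(n_probes_per_gene),
    n_compounds_per_class = as.integer(n_compounds_per_class),
    concentrations = as.numeric(concentrations),
    n_replicates = as.integer(n_replicates),
    n_batches = as.integer(n_batches),
    frac_common_signature = frac_common_signature,
    frac_class_unique = frac_class_unique,
    effect_log2fc = effect_log2fc,
    exp5_g = exp5_g,
    dispersion = dispersion,
    library_size_mean = library_size_mean,
    library_size_cv = library_size_cv,
    batch_sd = batch_sd,
    prob_up = prob_up,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' @noRd
validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1L) config_error("n_genes must be >= 1")
  if (!cfg$n_probes_per_gene %in% 1:2) {
    config_error("n_probes_per_gene must be 1 or 2")
  }
  if (length(cfg$concentrations) == 0L) {
    config_error("concentrations must be a non-empty list of positive values")
  }
  if (any(cfg$concentrations <= 0) ||
      any(diff(cfg$concentrations) <= 0)) {
    config_error("concentrations must be positive and strictly increasing")
  }
  fr <- c(cfg$frac_common_signature, cfg$frac_class_unique)
  if (any(fr < 0) || any(fr > 1) ||
      cfg$frac_common_signature + 3 * cfg$frac_class_unique > 1) {
    config_error(
      "signature fractions must lie in [0,1] and frac_common_signature + 3 * frac_class_unique must be <= 1")
  }
  check_positive_scalar(cfg$dispersion, "dispersion")
  check_positive_scalar(cfg$library_size_mean, "library_size_mean")
  check_positive_scalar(cfg$library_size_cv, "library_size_cv")
  check_positive_scalar(cfg$exp5_g, "exp5_g")
  if (cfg$n_replicates < 1L) config_error("n_replicates must be >= 1")
  if (cfg$n_batches < 1L) config_error("n_batches must be >= 1")
  invisible(cfg)
}

#' Exp5 mean response (unit baseline)
#'
#' `exp5_mean()` evaluates the four-parameter exponential model
#' m(d) = a * (c - (c - 1) * exp(-(b d)^g)); at dose 0 it equals `a` and its
#' asymptote is `a * c`.
#'
#' @param d Dose vector (uM).
#' @param a Baseline response at dose 0.
#' @param b Rate parameter (1/uM), > 0.
#' @param c Fold asymptote relative to baseline.
#' @param g Shape exponent, > 0.
#' @return Numeric vector of modeled responses.
#' @export
exp5_mean <- function(d, a, b, c, g) {
  a * (c - (c - 1) * exp(-(b * d)^g))
}

# Closed-form dose at which the Exp5 curve reaches `target`; NA when the
# target lies outside (a, a*c) or the curve is flat.
#' @noRd
exp5_invert <- function(target, a, b, c, g) {
  if (c == 1) return(NA_real_)
  e <- (c - target / a) / (c - 1)
  if (!is.finite(e) || e <= 0 || e >= 1) return(NA_real_)
  (-log(e))^(1 / g) / b
}

#' Generate a synthetic two-batch dose-response experiment
#'
#' Draws a probe-by-sample integer count matrix from a negative-binomial
#' model. For responsive genes the expected count follows the gene's Exp5
#' curve (relative to a unit baseline) times the sample library size, a
#' gene-wise batch factor and the gene's baseline abundance; vehicle samples
#' (0.1% DMSO analogue, concentration 0) are present in every batch.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `sim_experiment` with elements
#'   \describe{
#'     \item{counts}{integer matrix, probes x samples}
#'     \item{meta}{sample annotation data frame (`sample_id`, `compound`,
#'       `concentration`, `class`, `experiment_id`, `replicate`,
#'       `is_vehicle`)}
#'     \item{probes}{probe annotation (`probe_id`, `gene_symbol`,
#'       `panel_version`)}
#'     \item{truth}{ground truth: per-gene category, direction, Exp5
#'       parameters and true benchmark dose; plus the true log2
#'       fold-change matrix over the concentration grid}
#'   }
#' @export
generate_experiment <- function(config) {
  if (!inherits(config, "sim_config")) {
    config_error("config must be created with sim_config()")
  }
  withr::with_seed(config$seed, generate_experiment_impl(config))
}

#' @noRd
generate_experiment_impl <- function(cfg) {
  classes <- c("CI", "CII", "CIII")
  n <- cfg$n_genes
  gene_ids <- sprintf("G%05d", seq_len(n))

  n_common <- round(cfg$frac_common_signature * n)
  n_unique <- round(cfg$frac_class_unique * n)
  category <- rep("none", n)
  if (n_common > 0) category[seq_len(n_common)] <- "common"
  pos <- n_common
  for (cl in classes) {
    if (n_unique > 0) category[pos + seq_len(n_unique)] <- paste0("unique_", cl)
    pos <- pos + n_unique
  }
  responsive <- category != "none"

  direction <- integer(n)
  direction[responsive] <- ifelse(
    runif(sum(responsive)) < cfg$prob_up, 1L, -1L)

  b <- rep(NA_real_, n)
  rng <- range(cfg$concentrations)
  b[responsive] <- 10^runif(sum(responsive), log10(1 / rng[2]), log10(1 / rng[1]))
  g <- cfg$exp5_g
  c_par <- rep(NA_real_, n)
  c_par[responsive] <- 2^(direction[responsive] * cfg$effect_log2fc)

  # baseline relative abundance per gene; second probes get their own offset
  q <- rlnorm(n, meanlog = log(100), sdlog = 1.2)
  batch_fac <- matrix(1, n, cfg$n_batches)
  if (cfg$n_batches > 1) {
    for (bi in 2:cfg$n_batches) {
      batch_fac[, bi] <- rlnorm(n, 0, cfg$batch_sd)
    }
  }

  # sample sheet: vehicles per batch, then compound x concentration series
  compounds <- unlist(lapply(classes, function(cl) {
    paste0(cl, "_c", seq_len(cfg$n_compounds_per_class))
  }))
  compound_class <- rep(classes, each = cfg$n_compounds_per_class)
  compound_batch <- ((seq_along(compounds) - 1L) %% cfg$n_batches) + 1L

  meta <- data.frame(
    compound = "DMSO",
    concentration = 0,
    class = "vehicle",
    experiment_id = rep(paste0("exp", seq_len(cfg$n_batches)),
                        each = cfg$n_replicates),
    replicate = rep(seq_len(cfg$n_replicates), cfg$n_batches),
    is_vehicle = TRUE,
    stringsAsFactors = FALSE
  )
  for (ci in seq_along(compounds)) {
    block <- expand.grid(
      replicate = seq_len(cfg$n_replicates),
      concentration = cfg$concentrations,
      KEEP.OUT.ATTRS = FALSE
    )
    block$compound <- compounds[ci]
    block$class <- compound_class[ci]
    block$experiment_id <- paste0("exp", compound_batch[ci])
    block$is_vehicle <- FALSE
    meta <- rbind(meta, block[, names(meta)])
  }
  meta$sample_id <- sprintf("S%04d", seq_len(nrow(meta)))
  meta <- meta[, c("sample_id", "compound", "concentration", "class",
                   "experiment_id", "replicate", "is_vehicle")]

  lib_sdlog <- sqrt(log(1 + cfg$library_size_cv^2))
  lib_meanlog <- log(cfg$library_size_mean) - lib_sdlog^2 / 2
  lib_sizes <- rlnorm(nrow(meta), lib_meanlog, lib_sdlog)

  # probe layer
  if (cfg$n_probes_per_gene == 1L) {
    probe_gene <- seq_len(n)
    probe_ids <- paste0(gene_ids, "_P1")
    probe_mult <- rep(1, n)
  } else {
    probe_gene <- rep(seq_len(n), each = 2)
    probe_ids <- paste0(gene_ids[probe_gene], "_P", rep(1:2, n))
    probe_mult <- rlnorm(2 * n, 0, 0.3)
  }
  probes <- data.frame(
    probe_id = probe_ids,
    gene_symbol = gene_ids[probe_gene],
    panel_version = "v2.2",
    stringsAsFactors = FALSE
  )

  # expected fold change per gene for one (class, concentration) cell
  fc_for <- function(cl, d) {
    fc <- rep(1, n)
    if (d > 0) {
      mask <- category == "common" | category == paste0("unique_", cl)
      fc[mask] <- exp5_mean(d, 1, b[mask], c_par[mask], g)
    }
    fc
  }

  batch_of <- as.integer(sub("exp", "", meta$experiment_id))
  counts <- matrix(0L, nrow = length(probe_ids), ncol = nrow(meta),
                   dimnames = list(probe_ids, meta$sample_id))
  cells <- unique(meta[, c("class", "concentration", "experiment_id")])
  for (k in seq_len(nrow(cells))) {
    sel <- meta$class == cells$class[k] &
      meta$concentration == cells$concentration[k] &
      meta$experiment_id == cells$experiment_id[k]
    bi <- as.integer(sub("exp", "", cells$experiment_id[k]))
    fc <- fc_for(cells$class[k], cells$concentration[k])
    w_gene <- q * fc * batch_fac[, bi]
    w <- w_gene[probe_gene] * probe_mult
    w <- w / sum(w)
    for (j in which(sel)) {
      mu <- lib_sizes[j] * w
      counts[, j] <- if (cfg$dispersion < 1e-10) {
        rpois(length(mu), mu)
      } else {
        rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion)
      }
    }
  }

  storage.mode(counts) <- "integer"

  true_lfc <- matrix(0, n, length(cfg$concentrations),
                     dimnames = list(gene_ids, as.character(cfg$concentrations)))
  for (di in seq_along(cfg$concentrations)) {
    d <- cfg$concentrations[di]
    fc <- rep(1, n)
    fc[responsive] <- exp5_mean(d, 1, b[responsive], c_par[responsive], g)
    true_lfc[, di] <- log2(fc)
  }

  true_bmd <- rep(NA_real_, n)
  for (i in which(responsive)) {
    targ <- if (direction[i] > 0) 1.1 else 0.9
    true_bmd[i] <- exp5_invert(targ, 1, b[i], c_par[i], g)
  }

  truth <- list(
    genes = data.frame(
      gene_id = gene_ids, category = category, direction = direction,
      b = b, c = c_par, g = ifelse(responsive, g, NA_real_),
      true_bmd = true_bmd, stringsAsFactors = FALSE
    ),
    true_lfc = true_lfc,
    classes = classes,
    compound_class = setNames(compound_class, compounds),
    seed = cfg$seed
  )

  structure(
    list(counts = counts, meta = meta, probes = probes, truth = truth,
         config = cfg),
    class = "sim_experiment"
  )
}

#' Generate gene-set database with one planted signature set
#'
#' Builds a "signature" set containing the common responsive genes plus
#' `n_decoy_sets` decoy sets of matched size drawn uniformly from the gene
#' universe.
#'
#' @param truth Ground-truth component of a [generate_experiment()] result.
#' @param n_decoy_sets Number of decoy sets (>= 0).
#' @param seed Integer seed.
#' @return Named list of character vectors of class `geneset_db`; the planted
#'   set is named `"signature"`.
#' @export
generate_genesets <- function(truth, n_decoy_sets = 50L, seed = 1L) {
  if (is.null(truth$genes) || nrow(truth$genes) == 0L) {
    config_error("truth must contain a non-empty gene table")
  }
  if (n_decoy_sets < 0) config_error("n_decoy_sets must be >= 0")
  withr::with_seed(seed, {
    universe <- truth$genes$gene_id
    sig <- truth$genes$gene_id[truth$genes$category == "common"]
    db <- list()
    if (length(sig) > 0) db$signature <- sig
    size <- max(length(sig), 10L)
    for (k in seq_len(n_decoy_sets)) {
      db[[paste0("decoy_", sprintf("%03d", k))]] <-
        sample(universe, min(size, length(universe)))
    }
    structure(db, class = c("geneset_db", "list"), source = "synthetic")
  })
}

#' Generate a signed regulator-to-target network with known activity
#'
#' Each synthetic regulator receives signed, weighted edges to responsive
#' target genes. A `frac_consistent` share of its edges agrees with the
#' direction implied by the regulator's true activity state and the target's
#' simulated direction of change: for an activated regulator a consistent edge
#' has expected regulation direction equal to the target's change (e.g. an
#' inhibitory edge onto a down-regulated target), for an inhibited regulator
#' the opposite.
#'
#' @param truth Ground truth from [generate_experiment()].
#' @param targets_per_regulator Edges per regulator (>= 1).
#' @param frac_consistent Fraction of edges consistent with the true state.
#' @param n_regulators Number of regulators (alternating activated/inhibited).
#' @param seed Integer seed.
#' @return Data frame (`regulator`, `target`, `sign`, `weight`) with the true
#'   activity signs in `attr(, "true_activity")`.
#' @export
generate_regulator_network <- function(truth, targets_per_regulator = 25L,
                                       frac_consistent = 1, n_regulators = 6L,
                                       seed = 1L) {
  if (targets_per_regulator < 1L) {
    config_error("targets_per_regulator must be >= 1")
  }
  withr::with_seed(seed, {
    pool <- truth$genes[truth$genes$category != "none", ]
    if (nrow(pool) == 0L) config_error("truth has no responsive genes")
    regs <- sprintf("REG%02d", seq_len(n_regulators))
    true_act <- setNames(rep_len(c(1L, -1L), n_regulators), regs)
    edges <- do.call(rbind, lapply(seq_len(n_regulators), function(i) {
      k <- min(targets_per_regulator, nrow(pool))
      tgt <- pool[sample(nrow(pool), k), ]
      consistent <- runif(k) < frac_consistent
      s_r <- ifelse(consistent,
                    true_act[i] * tgt$direction,
                    -true_act[i] * tgt$direction)
      data.frame(regulator = regs[i], target = tgt$gene_id,
                 sign = as.integer(s_r), weight = 1,
                 stringsAsFactors = FALSE)
    }))
    attr(edges, "true_activity") <- true_act
    edges
  })
}

#' Generate raw oxygen-consumption-rate well data
#'
#' Produces a mitostress-style table of raw basal and maximal OCR (pmol
#' O2/min/well) per compound and concentration, with vehicle and positive
#' control (full ETC shutdown) wells. For compounds of the classes named in
#' `mito_classes` the mitochondrial component declines along a Hill curve
#' with half-maximal concentration `ic50` and maximal fractional drop
#' `drop_max`; other compounds are flat.
#'
#' @param config A [sim_config()] (supplies compounds and concentrations).
#' @param seed Integer seed.
#' @param mito_classes Inhibitor classes whose compounds depress respiration.
#' @param drop_max Maximal fractional drop of the mitochondrial OCR component.
#' @param ic50 Half-effect concentration (uM); default geometric middle of
#'   the concentration range.
#' @param hill Hill exponent of the decline.
#' @param noise_sd Additive Gaussian well noise (pmol O2/min).
#' @param n_wells Replicate wells per condition and phase.
#' @param veh_basal,veh_maximal,nonmito True mean basal, maximal and
#'   non-mitochondrial (positive-control) rates.
#' @return Data frame (`compound`, `concentration`, `phase`, `well`, `ocr`)
#'   including `compound = "DMSO"` vehicle rows and
#'   `compound = "positive_control"` rows.
#' @export
generate_ocr_table <- function(config, seed = 1L,
                               mito_classes = c("CI", "CIII"),
                               drop_max = 0.8, ic50 = NULL, hill = 1.5,
                               noise_sd = 4, n_wells = 3L,
                               veh_basal = 150, veh_maximal = 300,
                               nonmito = 30) {
  if (!inherits(config, "sim_config")) {
    config_error("config must be created with sim_config()")
  }
  conc <- config$concentrations
  if (is.null(ic50)) ic50 <- exp(mean(log(range(conc))))
  classes <- c("CI", "CII", "CIII")
  compounds <- unlist(lapply(classes, function(cl) {
    paste0(cl, "_c", seq_len(config$n_compounds_per_class))
  }))
  compound_class <- rep(classes, each = config$n_compounds_per_class)
  withr::with_seed(seed, {
    rows <- list()
    add <- function(compound, concentration, phase, mu) {
      data.frame(compound = compound, concentration = concentration,
                 phase = phase, well = seq_len(n_wells),
                 ocr = mu + rnorm(n_wells, 0, noise_sd),
                 stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- add("DMSO", 0, "basal", veh_basal)
    rows[[length(rows) + 1L]] <- add("DMSO", 0, "maximal", veh_maximal)
    rows[[length(rows) + 1L]] <- add("positive_control", 0, "basal", nonmito)
    rows[[length(rows) + 1L]] <- add("positive_control", 0, "maximal", nonmito)
    for (ci in seq_along(compounds)) {
      mito <- compound_class[ci] %in% mito_classes
      for (d in conc) {
        f <- if (mito) 1 - drop_max * d^hill / (d^hill + ic50^hill) else 1
        rows[[length(rows) + 1L]] <- add(
          compounds[ci], d, "basal", nonmito + (veh_basal - nonmito) * f)
        rows[[length(rows) + 1L]] <- add(
          compounds[ci], d, "maximal", nonmito + (veh_maximal - nonmito) * f)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate a viability percent-of-control table
#'
#' Companion endpoint to [generate_ocr_table()]: viability declines with a
#' Hill curve centred well above the respiratory effect so that mitotoxic
#' concentrations remain sub-cytotoxic, emulating a resazurin readout already
#' expressed as percent of vehicle control.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param ic50_factor Viability IC50 as a multiple of the top tested
#'   concentration.
#' @param hill Hill exponent.
#' @param noise_sd Additive noise on the percent scale.
#' @return Data frame (`compound`, `concentration`, `viability`).
#' @export
generate_viability_table <- function(config, seed = 1L, ic50_factor = 5,
                                     hill = 2, noise_sd = 2) {
  if (!inherits(config, "sim_config")) {
    config_error("config must be created with sim_config()")
  }
  conc <- config$concentrations
  ic50 <- ic50_factor * max(conc)
  classes <- c("CI", "CII", "CIII")
  compounds <- unlist(lapply(classes, function(cl) {
    paste0(cl, "_c", seq_len(config$n_compounds_per_class))
  }))
  withr::with_seed(seed, {
    grid <- expand.grid(compound = compounds, concentration = conc,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    v <- 100 / (1 + (grid$concentration / ic50)^hill)
    grid$viability <- v + rnorm(nrow(grid), 0, noise_sd)
    grid[order(grid$compound, grid$concentration), ]
  })
}

# Plain-text writers ----------------------------------------------------------

#' Write a synthetic experiment to a directory of TSV files
#'
#' Emits `counts.tsv` (probes x samples), `sample_meta.tsv`, `probes.tsv` and
#' `truth_genes.tsv`, the on-disk contract consumed by the I/O module.
#'
#' @param sim A [generate_experiment()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_experiment <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("counts.tsv", "sample_meta.tsv", "probes.tsv",
                            "truth_genes.tsv"))
  cnt <- data.frame(probe_id = rownames(sim$counts), sim$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(cnt, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$meta, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$probes, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth$genes, paths[4], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' Write a gene-set database as GMT
#'
#' @param db Named list of character vectors (a `geneset_db`).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(db, path) {
  lines <- vapply(names(db), function(nm) {
    paste(c(nm, "synthetic", db[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a regulator network as 4-column TSV
#'
#' Columns: regulator, target, sign (+1/-1), weight.
#'
#' @param net Data frame as returned by [generate_regulator_network()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_network <- function(net, path) {
  write.table(net[, c("regulator", "target", "sign", "weight")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
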