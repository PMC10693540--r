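# Synthetic-data generator: configuration validation, determinism, and
# agreement between the drawn counts and the generating model.

test_that("sim_config rejects invalid parameter combinations", {
  expect_error(sim_config(frac_common_signature = 0.8,
                          frac_class_unique = 0.2), "fractions")
  expect_error(sim_config(concentrations = numeric(0)), "non-empty")
  expect_error(sim_config(concentrations = c(1, 0.5)), "strictly increasing")
  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(sim_config(n_probes_per_gene = 3), "1 or 2")
})

test_that("identical seeds give bit-identical experiments", {
  cfg <- sim_config(n_genes = 120, n_compounds_per_class = 1, seed = 42)
  a <- generate_experiment(cfg)
  b <- generate_experiment(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth$genes, b$truth$genes)
  c2 <- generate_experiment(sim_config(n_genes = 120,
                                       n_compounds_per_class = 1, seed = 43))
  expect_false(identical(a$counts, c2$counts))
})

test_that("every responsive gene carries exactly one signature category", {
  sim <- small_sim(seed = 3)
  cat_tab <- table(sim$truth$genes$category)
  expect_true(all(names(cat_tab) %in%
                    c("none", "common", "unique_CI", "unique_CII",
                      "unique_CIII")))
  resp <- sim$truth$genes[sim$truth$genes$category != "none", ]
  expect_true(all(resp$direction %in% c(-1L, 1L)))
  expect_true(all(is.finite(resp$b) & resp$b > 0))
})

test_that("zero effect size yields only type-I-level significant calls", {
  cfg <- sim_config(n_genes = 800, n_compounds_per_class = 1,
                    effect_log2fc = 0, seed = 11)
  sim <- generate_experiment(cfg)
  de <- de_for_compound(sim, "CI_c1", max(cfg$concentrations))
  expect_lt(mean(de$pvalue < 0.05, na.rm = TRUE), 0.10)
})

test_that("with vanishing dispersion the sample means track the Exp5 curve", {
  cfg <- sim_config(n_genes = 150, n_compounds_per_class = 1,
                    n_replicates = 40, dispersion = 1e-12,
                    library_size_cv = 0.05, batch_sd = 0, seed = 5)
  sim <- generate_experiment(cfg)
  meta <- sim$meta
  d_top <- max(cfg$concentrations)
  sel_t <- meta$compound == "CI_c1" & meta$concentration == d_top
  sel_v <- meta$is_vehicle & meta$experiment_id == "exp1"
  cm <- sim$counts[, c(meta$sample_id[sel_v], meta$sample_id[sel_t])]
  sf <- size_factors(cm, pseudo_reference = TRUE)
  norm <- normalize_counts(cm, sf)
  nv <- sum(sel_v)
  truth <- sim$truth$genes
  resp <- which(truth$category %in% c("common", "unique_CI"))
  ratio <- rowMeans(norm[resp, -(1:nv)]) / rowMeans(norm[resp, 1:nv])
  expected <- exp5_mean(d_top, 1, truth$b[resp], truth$c[resp], truth$g[resp])
  expect_lt(median(abs(ratio / expected - 1)), 0.02)
})

test_that("gene-set generator plants one enriched signature among decoys", {
  sim <- small_sim(seed = 9)
  db <- generate_genesets(sim$truth, n_decoy_sets = 30, seed = 2)
  expect_named(db[1], "signature")
  common <- sim$truth$genes$gene_id[sim$truth$genes$category == "common"]
  expect_setequal(db$signature, common)
  # perfect DE calls: signature Z is maximal across all sets
  res <- run_ora(db = db, universe = sim$truth$genes$gene_id,
                 selected = common, n_perm = 100, seed = 1)
  expect_equal(res$set[which.max(res$Z)], "signature")
  expect_error(generate_genesets(sim$truth, n_decoy_sets = -1), "n_decoy_sets")
  # no responsive genes -> all sets are decoys
  t0 <- sim$truth
  t0$genes$category <- "none"
  db0 <- generate_genesets(t0, n_decoy_sets = 5, seed = 2)
  expect_false("signature" %in% names(db0))
  expect_length(db0, 5)
})

test_that("decoy permutation p-values are approximately uniform", {
  cfg <- sim_config(n_genes = 2000, frac_common_signature = 0.25,
                    frac_class_unique = 0.01, seed = 3)
  sim <- generate_experiment(cfg)
  db <- generate_genesets(sim$truth, n_decoy_sets = 200, seed = 4)
  universe <- sim$truth$genes$gene_id
  selected <- withr::with_seed(5, sample(universe, 1000))
  pp <- vapply(names(db)[-1], function(nm) {
    permutation_pvalue(universe, selected, db[[nm]], n_perm = 400,
                       seed = match(nm, names(db)))$perm_p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pp, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("regulator network sign algebra matches the activation formula", {
  sim <- small_sim(seed = 13)
  truth <- sim$truth
  observed <- setNames(truth$genes$direction, truth$genes$gene_id)
  observed <- observed[observed != 0]

  net <- generate_regulator_network(truth, targets_per_regulator = 16,
                                    frac_consistent = 1, n_regulators = 4,
                                    seed = 1)
  act <- attr(net, "true_activity")
  for (rg in names(act)) {
    edges <- net[net$regulator == rg, ]
    z <- activation_zscore(edges, observed)
    # fully consistent unit-weight edges: z = +/- sqrt(k)
    expect_equal(z$activation_z, act[[rg]] * sqrt(nrow(edges)),
                 tolerance = 1e-12)
  }

  # half-consistent edges: z should hover near zero on average
  zs <- replicate(20, {
    n2 <- generate_regulator_network(truth, targets_per_regulator = 20,
                                     frac_consistent = 0.5, n_regulators = 1,
                                     seed = sample.int(1e6, 1))
    activation_zscore(n2, observed)$activation_z
  })
  expect_lt(abs(mean(zs)), 0.75)

  # inhibitory edges onto down-regulated targets predict activation
  down <- truth$genes[truth$genes$direction == -1, ][1:4, ]
  edges <- data.frame(regulator = "R", target = down$gene_id,
                      sign = -1L, weight = 1)
  z <- activation_zscore(edges, observed)
  expect_equal(z$predicted_state, "activated")
})

test_that("OCR generator respects programmed effects and determinism", {
  cfg <- sim_config(n_genes = 50, n_compounds_per_class = 1, seed = 1)
  # no effect, no noise: percent of control is exactly 100 everywhere
  flat <- generate_ocr_table(cfg, seed = 2, mito_classes = character(0),
                             noise_sd = 0)
  pct <- ocr_percent_of_control(flat)
  treated <- pct[!(pct$compound %in% c("DMSO", "positive_control")), ]
  expect_true(all(abs(treated$percent_of_control[
    treated$phase == "basal"] - 100) < 1e-9))

  # 60% programmed decrease: basal percent reaches ~40% at the top dose
  eff <- generate_ocr_table(cfg, seed = 2, mito_classes = "CI",
                            drop_max = 0.6, hill = 1.5, noise_sd = 0)
  pcte <- ocr_percent_of_control(eff)
  top <- max(cfg$concentrations)
  at_top <- pcte$percent_of_control[pcte$compound == "CI_c1" &
                                      pcte$concentration == top &
                                      pcte$phase == "basal"]
  expect_equal(mean(at_top), 40, tolerance = 0.02)

  expect_identical(generate_ocr_table(cfg, seed = 3),
                   generate_ocr_table(cfg, seed = 3))
})
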