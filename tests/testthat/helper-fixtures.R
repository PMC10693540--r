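# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

# Two-group NB count matrix with a planted fold change in the first
# `n_resp` genes (columns: n_per_group control, then n_per_group treated).
make_two_group_counts <- function(n_genes = 500, n_resp = 0, fc = 1,
                                  alpha = 0.05, n_per_group = 3,
                                  mu_meanlog = log(200), mu_sdlog = 1,
                                  seed = 1) {
  withr::with_seed(seed, {
    mu <- rlnorm(n_genes, mu_meanlog, mu_sdlog)
    fcv <- rep(1, n_genes)
    if (n_resp > 0) fcv[seq_len(n_resp)] <- fc
    draw <- function(m) {
      matrix(rnbinom(n_genes * n_per_group, mu = rep(m, n_per_group),
                     size = 1 / alpha), n_genes, n_per_group)
    }
    cnt <- cbind(draw(mu), draw(mu * fcv))
    rownames(cnt) <- sprintf("g%04d", seq_len(n_genes))
    colnames(cnt) <- sprintf("s%d", seq_len(2 * n_per_group))
    cnt
  })
}

two_group_condition <- function(n_per_group = 3) {
  factor(rep(c("control", "treated"), each = n_per_group),
         levels = c("control", "treated"))
}

# Tiny simulated experiment used across module tests.
small_sim <- function(seed = 7, n_genes = 300, n_compounds = 1,
                      effect = 2, dispersion = 0.05) {
  cfg <- sim_config(n_genes = n_genes, n_compounds_per_class = n_compounds,
                    n_replicates = 3, effect_log2fc = effect,
                    dispersion = dispersion, seed = seed)
  generate_experiment(cfg)
}

# Run the two-group DE stage for one compound at one concentration of a
# simulated experiment.
de_for_compound <- function(sim, compound, concentration) {
  meta <- sim$meta
  exps <- unique(meta$experiment_id[meta$compound == compound])
  sel <- (meta$compound == compound & meta$concentration == concentration) |
    (meta$is_vehicle & meta$experiment_id %in% exps)
  m <- meta[sel, ]
  cm <- sim$counts[, m$sample_id, drop = FALSE]
  cond <- factor(ifelse(m$is_vehicle, "vehicle", "treated"),
                 levels = c("vehicle", "treated"))
  sf <- size_factors(cm, pseudo_reference = TRUE)
  disp <- estimate_dispersion(cm, sf, cond)
  nb_wald_test(cm, sf, disp, cond, ref = "vehicle")
}
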