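test_that("generators are deterministic under a fixed seed", {
  a <- simulate_secretome(secretome_config(n_proteins = 100, seed = 7,
                                           n_hypoxia_luminal = 10,
                                           n_hypoxia_basal = 5,
                                           n_hypoxia_shared = 2,
                                           n_subtype_proteins = 10))
  b <- simulate_secretome(secretome_config(n_proteins = 100, seed = 7,
                                           n_hypoxia_luminal = 10,
                                           n_hypoxia_basal = 5,
                                           n_hypoxia_shared = 2,
                                           n_subtype_proteins = 10))
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$truth, b$truth)

  ta <- simulate_tissue(tissue_config(n_proteins = 80, seed = 5,
                                      n_stroma_exclusive = 10, n_shared = 5))
  tb <- simulate_tissue(tissue_config(n_proteins = 80, seed = 5,
                                      n_stroma_exclusive = 10, n_shared = 5))
  expect_identical(ta$matrix, tb$matrix)

  ca <- make_sim_cohort(n_patients = 50, seed = 9)
  cb <- make_sim_cohort(n_patients = 50, seed = 9)
  expect_identical(ca$cohort$expression, cb$cohort$expression)
  expect_identical(ca$cohort$time, cb$cohort$time)
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(simulate_secretome(secretome_config(
    n_proteins = 50, seed = 42, n_hypoxia_luminal = 5, n_hypoxia_basal = 5,
    n_hypoxia_shared = 0, n_subtype_proteins = 5)))
  expect_identical(runif(1), before)
})

test_that("secretome limit with no effects, noise or missingness is flat up to the subtype baseline", {
  cfg <- secretome_config(n_proteins = 20, replicates = 3, noise_sd = 0,
                          n_hypoxia_luminal = 0, n_hypoxia_basal = 0,
                          n_hypoxia_shared = 0, n_subtype_proteins = 5,
                          subtype_effect = 1.5, missing_slope = 0, seed = 2)
  out <- simulate_secretome(cfg)
  expect_false(anyNA(out$matrix))
  lum <- out$design$sample_id[out$design$subtype == "luminal"]
  bas <- out$design$sample_id[out$design$subtype == "basal"]
  # within a subtype every sample is identical
  expect_equal(max(apply(out$matrix[, lum], 1, function(r) diff(range(r)))), 0)
  expect_equal(max(apply(out$matrix[, bas], 1, function(r) diff(range(r)))), 0)
  diff_sub <- out$matrix[, bas[1]] - out$matrix[, lum[1]]
  expect_equal(unname(sort(unique(round(diff_sub, 10)))), c(0, 1.5))
  expect_equal(sum(diff_sub != 0), 5L)
})

test_that("planted hypoxia effects are recovered in group means", {
  cfg <- secretome_config(n_proteins = 300, replicates = 6,
                          n_hypoxia_luminal = 30, n_hypoxia_basal = 10,
                          n_hypoxia_shared = 5, hypoxia_effect = 2,
                          noise_sd = 0.5, missing_slope = 0, seed = 11)
  out <- simulate_secretome(cfg)
  d <- out$design
  hx <- d$sample_id[d$subtype == "luminal" & d$oxygen == "hypoxia"]
  nx <- d$sample_id[d$subtype == "luminal" & d$oxygen == "normoxia"]
  diffs <- rowMeans(out$matrix[out$truth$hypoxia_luminal, hx]) -
    rowMeans(out$matrix[out$truth$hypoxia_luminal, nx])
  # each planted difference within 3 * se of the planted effect
  tol <- 3 * (0.5 / sqrt(6)) * sqrt(2)
  expect_true(all(abs(diffs - 2) < tol))
  expect_true(mean(diffs) > 1.8 && mean(diffs) < 2.2)
})

test_that("missingness follows the logistic intensity model", {
  cfg <- secretome_config(n_proteins = 4000, replicates = 6, noise_sd = 0.5,
                          n_hypoxia_luminal = 0, n_hypoxia_basal = 0,
                          n_hypoxia_shared = 0, n_subtype_proteins = 0,
                          baseline_mean = 21, baseline_sd = 1.5,
                          missing_midpoint = 20, missing_slope = 1, seed = 4)
  full <- simulate_secretome(secretome_config(
    n_proteins = 4000, replicates = 6, noise_sd = 0.5,
    n_hypoxia_luminal = 0, n_hypoxia_basal = 0, n_hypoxia_shared = 0,
    n_subtype_proteins = 0, baseline_mean = 21, baseline_sd = 1.5,
    missing_midpoint = 20, missing_slope = 0, seed = 4))
  out <- simulate_secretome(cfg)
  # same seed, slope the only change: the underlying intensities coincide
  x <- full$matrix
  miss <- is.na(out$matrix)
  bins <- cut(as.vector(x), breaks = quantile(x, seq(0, 1, 0.1)),
              include.lowest = TRUE)
  for (b in levels(bins)) {
    sel <- bins == b
    n <- sum(sel)
    p_hat <- mean(miss[sel])
    p_model <- mean(plogis((20 - x[sel]) * 1))
    expect_lt(abs(p_hat - p_model), 3 * sqrt(p_model * (1 - p_model) / n) + 1e-12)
  }
})

test_that("tissue generator plants stroma-exclusive and shared effects where stated", {
  out <- simulate_tissue(tissue_config(n_proteins = 200,
                                       patients_per_subtype = 8,
                                       n_stroma_exclusive = 15, n_shared = 10,
                                       stroma_effect = 2, shared_effect = 2,
                                       noise_sd = 0.3, missing_slope = 0,
                                       seed = 6))
  d <- out$design
  expect_true(all(table(d$patient_id) == 2))  # paired compartments
  expect_length(intersect(out$truth$stroma_exclusive, out$truth$shared), 0L)
  mean_grp <- function(ids, comp, sub) {
    cols <- d$sample_id[d$compartment == comp & d$subtype == sub]
    rowMeans(out$matrix[ids, cols, drop = FALSE])
  }
  # stroma-exclusive: effect in stroma only
  se_str <- mean_grp(out$truth$stroma_exclusive, "stroma", "basal") -
    mean_grp(out$truth$stroma_exclusive, "stroma", "luminal")
  se_epi <- mean_grp(out$truth$stroma_exclusive, "epithelium", "basal") -
    mean_grp(out$truth$stroma_exclusive, "epithelium", "luminal")
  expect_true(all(se_str > 1.5))
  expect_true(all(abs(se_epi) < 0.7))
  # shared: effect in both compartments by construction
  sh_str <- mean_grp(out$truth$shared, "stroma", "basal") -
    mean_grp(out$truth$shared, "stroma", "luminal")
  sh_epi <- mean_grp(out$truth$shared, "epithelium", "basal") -
    mean_grp(out$truth$shared, "epithelium", "luminal")
  expect_true(all(sh_str > 1.5) && all(sh_epi > 1.5))
})

test_that("planted-truth ids always refer to generated rows", {
  sec <- simulate_secretome(secretome_config(n_proteins = 120, seed = 8,
                                             n_hypoxia_luminal = 12,
                                             n_hypoxia_basal = 6,
                                             n_hypoxia_shared = 3,
                                             n_subtype_proteins = 10))
  expect_true(all(sec$truth$hypoxia_union %in% rownames(sec$matrix)))
  tis <- simulate_tissue(tissue_config(n_proteins = 120, seed = 8,
                                       n_stroma_exclusive = 12, n_shared = 6))
  expect_true(all(c(tis$truth$stroma_exclusive, tis$truth$shared) %in%
                    rownames(tis$matrix)))
  coh <- make_sim_cohort(n_patients = 40, n_genes = 20, sig_size = 5, seed = 8)
  expect_true(all(coh$truth$signature %in% rownames(coh$cohort$expression)))
})

test_that("generator preconditions are enforced", {
  expect_error(simulate_secretome(secretome_config(replicates = 1)),
               ">= 2 replicates")
  expect_error(simulate_tissue(tissue_config(patients_per_subtype = 2)),
               ">= 3 patients")
  expect_error(simulate_cohort(cohort_config(n_genes = 10,
                                             signature = c("G0001", "NOPE"))),
               "NOPE")
})

test_that("near-zero administrative censoring yields no events and survival ops refuse", {
  sim <- simulate_cohort(cohort_config(n_genes = 20, n_patients = 40,
                                       signature = sprintf("G%04d", 1:5),
                                       censor_time = 1e-9, seed = 2))
  expect_identical(sum(sim$cohort$event), 0L)
  expect_error(signature_strength(sim$cohort, sig_of(sprintf("G%04d", 1:5))),
               "no events")
})

test_that("cohort hazard responds to the planted signature coefficient", {
  null_sim <- make_sim_cohort(n_patients = 400, n_genes = 60, sig_size = 15,
                              beta = 0, seed = 21)
  eff_sim <- make_sim_cohort(n_patients = 400, n_genes = 60, sig_size = 15,
                             beta = log(2), seed = 21)
  s_null <- signature_strength(null_sim$cohort,
                               sig_of(sprintf("G%04d", 1:15)))
  s_eff <- signature_strength(eff_sim$cohort, sig_of(sprintf("G%04d", 1:15)))
  expect_lt(s_eff$p_value, 0.01)
  expect_gt(s_eff$chi_square, s_null$chi_square)
})
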