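groups_ab <- function(a = paste0("a", 1:4), b = paste0("b", 1:4)) {
  list(g1 = a, g2 = b)
}

test_that("valid-value filter applies the 50% rule in both modes", {
  m <- make_matrix(c(1, 2, 3, 4, 5, 6, 7, 8,      # fully observed
                     1, NA, 3, NA, NA, 6, NA, NA, # 2/4 in A, 1/4 in B
                     NA, NA, NA, NA, NA, NA, NA, NA),
                   c("full", "partial", "empty"),
                   c(paste0("a", 1:4), paste0("b", 1:4)))
  g <- groups_ab()
  any_mode <- filter_valid_values(m, g, differential_config())
  all_mode <- filter_valid_values(m, g,
                                  differential_config(filter_mode = "all_groups"))
  expect_identical(rownames(any_mode), c("full", "partial"))
  expect_identical(rownames(all_mode), "full")
  # observed values never altered
  expect_identical(any_mode["full", ], m["full", ])
  # fully observed matrix is retained whole
  expect_identical(filter_valid_values(m["full", , drop = FALSE], g,
                                       differential_config()),
                   m["full", , drop = FALSE])
})

test_that("downshifted-normal imputation draws from the stated distribution and only fills gaps", {
  set.seed(99)
  obs <- rnorm(500, mean = 20, sd = 1)
  col <- c(obs, rep(NA_real_, 10000))
  m <- matrix(col, ncol = 1, dimnames = list(sprintf("p%05d", 1:10500), "s1"))
  out <- impute_downshifted(m, imputation_params(width = 0.3, downshift = 1.8,
                                                 seed = 5))
  expect_identical(out[1:500, 1], m[1:500, 1])          # observed unchanged
  expect_identical(sum(is.na(out)), 0L)
  imp <- out[501:10500, 1]
  mu_target <- mean(obs) - 1.8 * sd(obs)
  sd_target <- 0.3 * sd(obs)
  expect_lt(abs(mean(imp) - mu_target), 3 * sd_target / sqrt(10000))
  expect_lt(abs(sd(imp) - sd_target), 3 * sd_target / sqrt(2 * 10000))
  # deterministic under seed
  out2 <- impute_downshifted(m, imputation_params(seed = 5))
  expect_identical(out, out2)
  # complete matrix returned unchanged
  expect_identical(impute_downshifted(out, imputation_params(seed = 1)), out)
  # a column with one observed value cannot be imputed
  bad <- make_matrix(c(1, NA, NA), c("x", "y", "z"), "only")
  expect_error(impute_downshifted(bad, imputation_params(seed = 1)), "only")
})

test_that("the t test matches hand computation and degenerate conventions", {
  m <- make_matrix(c(1, 2, 3, 2, 3, 4,
                     5, 5, 5, 5, 5, 5),
                   c("hand", "flat"),
                   c(paste0("a", 1:3), paste0("b", 1:3)))
  cfg <- differential_config(apply_filter = FALSE, apply_imputation = FALSE)
  tab <- differential_test(m, list(g1 = paste0("a", 1:3), g2 = paste0("b", 1:3)),
                           cfg)
  hand <- tab[tab$protein_id == "hand", ]
  expect_equal(hand$t_stat, -1.224745, tolerance = 1e-6)
  expect_equal(hand$df, 4)
  expect_equal(hand$p_value, 0.2878641, tolerance = 1e-6)
  expect_equal(hand$log2fc, 1)
  flat <- tab[tab$protein_id == "flat", ]
  expect_identical(flat$t_stat, 0)
  expect_identical(flat$p_value, 1)
  expect_identical(flat$linear_fold, 1)
})

test_that("zero pooled variance with unequal means reports the smallest positive p with a warning", {
  m <- make_matrix(c(1, 1, 1, 2, 2, 2), "shift",
                   c(paste0("a", 1:3), paste0("b", 1:3)))
  cfg <- differential_config(apply_filter = FALSE, apply_imputation = FALSE)
  expect_warning(
    tab <- differential_test(m, list(g1 = paste0("a", 1:3),
                                     g2 = paste0("b", 1:3)), cfg),
    "zero pooled variance")
  expect_identical(tab$p_value, .Machine$double.xmin)
})

test_that("t statistics agree with a first-principles recomputation on random matrices", {
  set.seed(42)
  cfg <- differential_config(apply_filter = FALSE, apply_imputation = FALSE)
  for (rep in 1:5) {
    n1 <- sample(3:4, 1); n2 <- sample(3:4, 1)
    m <- matrix(rnorm(10 * (n1 + n2)), nrow = 10,
                dimnames = list(sprintf("p%02d", 1:10),
                                c(paste0("a", 1:n1), paste0("b", 1:n2))))
    tab <- differential_test(m, list(g1 = paste0("a", 1:n1),
                                     g2 = paste0("b", 1:n2)), cfg)
    for (i in 1:10) {
      tt <- t.test(m[i, 1:n1], m[i, n1 + (1:n2)], var.equal = TRUE)
      expect_equal(tab$t_stat[i], unname(tt$statistic), tolerance = 1e-9)
      expect_equal(tab$p_value[i], tt$p.value, tolerance = 1e-9)
    }
  }
})

test_that("swapping group labels negates t and log2fc and keeps p", {
  set.seed(7)
  m <- matrix(rnorm(40), nrow = 5,
              dimnames = list(sprintf("p%d", 1:5),
                              c(paste0("a", 1:4), paste0("b", 1:4))))
  cfg <- differential_config(apply_filter = FALSE, apply_imputation = FALSE)
  fwd <- differential_test(m, groups_ab(), cfg)
  rev <- differential_test(m, list(g1 = paste0("b", 1:4),
                                   g2 = paste0("a", 1:4)), cfg)
  expect_equal(rev$t_stat, -fwd$t_stat)
  expect_equal(rev$log2fc, -fwd$log2fc)
  expect_equal(rev$p_value, fwd$p_value)
})

test_that("type-I error under the null stays near alpha", {
  set.seed(31)
  m <- matrix(rnorm(2000 * 12, mean = 20), nrow = 2000,
              dimnames = list(sprintf("p%04d", 1:2000),
                              c(paste0("a", 1:6), paste0("b", 1:6))))
  cfg <- differential_config(apply_filter = FALSE, apply_imputation = FALSE)
  tab <- differential_test(m, list(g1 = paste0("a", 1:6),
                                   g2 = paste0("b", 1:6)), cfg)
  rate <- mean(tab$p_value < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("planted effects are detected with high recall through filter and imputation", {
  sec <- simulate_secretome(secretome_config(
    n_proteins = 400, replicates = 6, n_hypoxia_luminal = 30,
    n_hypoxia_basal = 10, n_hypoxia_shared = 5, hypoxia_effect = 2,
    noise_sd = 0.5, seed = 13))
  g <- design_groups(sec$design, "oxygen", c("normoxia", "hypoxia"),
                     within = c(subtype = "luminal"))
  tab <- differential_test(sec$matrix, g, differential_config(),
                           imputation_params(seed = 13))
  called <- tab$protein_id[!is.na(tab$p_value) & tab$p_value < 0.05 &
                             tab$log2fc > 0]
  recall <- mean(sec$truth$hypoxia_luminal %in% called)
  expect_gte(recall, 0.9)
})

test_that("marker purity reproduces the k-fold arithmetic and its edge cases", {
  pats <- sprintf("pt%d", 1:5)
  epi_cols <- paste0(pats, "_E"); str_cols <- paste0(pats, "_S")
  epi <- make_matrix(rep(20, 5), "KRT8", epi_cols)
  stroma <- make_matrix(rep(20 - log2(62), 5), "KRT8", str_cols)
  pairing <- data.frame(patient_id = pats, epithelium = epi_cols,
                        stroma = str_cols)
  est <- estimate_marker_purity(epi, stroma, "KRT8", pairing)
  expect_equal(est$mean_percent, 100 / 62, tolerance = 1e-12)
  expect_equal(round(est$mean_percent, 1), 1.6)
  expect_equal(est$median_percent, 100 / 62, tolerance = 1e-12)

  # equal marker intensity -> 100%; absent stroma signal -> 0%
  eq <- estimate_marker_purity(epi, make_matrix(rep(20, 5), "KRT8", str_cols),
                               "KRT8", pairing)
  expect_equal(eq$mean_percent, 100)
  zero <- estimate_marker_purity(epi,
                                 make_matrix(rep(-Inf, 5), "KRT8", str_cols),
                                 "KRT8", pairing)
  expect_equal(zero$mean_percent, 0)

  # missing pairs dropped with a warning; zero epithelium intensity errors
  stroma_na <- stroma; stroma_na["KRT8", 1] <- NA
  expect_warning(est2 <- estimate_marker_purity(epi, stroma_na, "KRT8",
                                                pairing), "dropped")
  expect_identical(est2$n_pairs, 4L)
  epi_zero <- epi; epi_zero["KRT8", ] <- -Inf
  expect_error(estimate_marker_purity(epi_zero, stroma, "KRT8", pairing),
               "zero epithelium")
})
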