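# Fixture builders shared across test files. Everything is generated in code;
# nothing is read from disk except files the tests themselves write.

# A small intensity matrix with named rows/columns.
make_matrix <- function(values, proteins, samples) {
  matrix(values, nrow = length(proteins), ncol = length(samples),
         dimnames = list(proteins, samples), byrow = TRUE)
}

# A minimal differential table with given ids, p values and fold changes.
make_diff_table <- function(ids, p, log2fc = rep(1, length(ids))) {
  out <- data.frame(protein_id = ids, mean_g1 = 0, mean_g2 = log2fc,
                    log2fc = log2fc, linear_fold = 2^log2fc,
                    t_stat = NA_real_, df = NA_real_, p_value = p,
                    n_valid_g1 = 3L, n_valid_g2 = 3L,
                    stringsAsFactors = FALSE)
  class(out) <- c("differential_table", "data.frame")
  out
}

# A deterministic tiny cohort: expression rows are fixed patterns so scores
# and quartiles are reproducible without RNG.
make_tiny_cohort <- function(n_genes = 6, n_patients = 12) {
  genes <- sprintf("G%02d", seq_len(n_genes))
  patients <- sprintf("P%02d", seq_len(n_patients))
  expr <- outer(seq_len(n_genes), seq_len(n_patients),
                function(g, p) g + ((g * p) %% 7) / 2)
  dimnames(expr) <- list(genes, patients)
  clinical <- data.frame(patient_id = patients,
                         time = seq(5, 5 * n_patients, by = 5),
                         event = rep(c(1L, 0L), length.out = n_patients))
  cohort_data(expr, clinical)
}

# A simulated cohort wrapper with small dimensions for speed.
make_sim_cohort <- function(n_patients = 200, n_genes = 60, sig_size = 15,
                            beta = 0, delta = 0, gamma = 0, seed = 1) {
  sig <- sprintf("G%04d", seq_len(sig_size))
  simulate_cohort(cohort_config(
    n_genes = n_genes, n_patients = n_patients, signature = sig,
    beta = beta, gamma = gamma, delta = delta, seed = seed))
}

sig_of <- function(ids, name = "sig") signature_set(name, ids)

# Independent Efron partial log-likelihood for a single covariate, used as a
# brute-force oracle for Cox fits. Written from the definition, not from the
# package code path.
efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    d_idx <- which(time == t & event == 1)
    r_idx <- which(time >= t)
    d <- length(d_idx)
    eta_r <- sum(exp(beta * x[r_idx]))
    eta_d <- sum(exp(beta * x[d_idx]))
    ll <- ll + beta * sum(x[d_idx])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(eta_r - (l / d) * eta_d)
    }
  }
  ll
}

# Independent greedy reduction oracle built on the public scoring pieces but
# with its own loop, quartile cut and survdiff call.
oracle_greedy <- function(cohort, members) {
  strength <- function(mem) {
    e <- cohort$expression[mem, , drop = FALSE]
    sc <- colSums(e - rowMeans(e))
    hi <- sc > quantile(sc, 0.75, type = 7)
    sd_ <- survival::survdiff(
      survival::Surv(cohort$time, cohort$event) ~ factor(hi))
    c(chi = unname(sd_$chisq),
      p = pchisq(unname(sd_$chisq), 1, lower.tail = FALSE))
  }
  cur <- members
  s0 <- strength(cur)
  tab <- data.frame(step = 0L, size = length(cur), removed = NA_character_,
                    chi_square = s0[["chi"]], p_value = s0[["p"]])
  step <- 0L
  while (length(cur) > 1L) {
    step <- step + 1L
    stats_ <- sapply(cur, function(g) strength(setdiff(cur, g)))
    ord <- order(stats_["p", ], -stats_["chi", ], cur, method = "radix")
    g_out <- cur[ord[1L]]
    cur <- setdiff(cur, g_out)
    tab <- rbind(tab, data.frame(step = step, size = length(cur),
                                 removed = g_out,
                                 chi_square = stats_["chi", ord[1L]],
                                 p_value = stats_["p", ord[1L]]))
  }
  rownames(tab) <- NULL
  tab
}
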