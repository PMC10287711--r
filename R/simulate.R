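# Seeded synthetic-data generators with planted ground truth: secretome
# matrices with subtype baselines, per-subtype hypoxia effects and
# intensity-dependent (MNAR) missingness; paired epithelium/stroma tissue
# proteomes with stroma-exclusive and shared subtype effects; and survival
# cohorts whose hazard is tied to the signature score with an optional
# treatment interaction.

protein_ids <- function(n) sprintf("P%04d", seq_len(n))

# Intensity-dependent missingness: P(missing | x) = logistic((mid - x) * slope).
apply_mnar <- function(m, midpoint, slope) {
  if (slope <= 0) return(m)
  p <- plogis((midpoint - m) * slope)
  m[runif(length(m)) < p] <- NA_real_
  m
}

pick_ids <- function(pool, n, given, what) {
  if (!is.null(given)) {
    given <- as.character(given)
    if (!all(given %in% pool))
      stop_("%s id(s) outside the generated protein universe", what)
    return(given)
  }
  if (n > length(pool)) stop_("not enough proteins to plant %s", what)
  sample(pool, n)
}

#' Configuration for the secretome generator
#'
#' Defaults emulate the discovery secretome design: four (subtype, oxygen)
#' groups with six replicate conditioned-media samples each, hypoxia-
#' responsive protein counts of 128 (luminal), 29 (basal) with 7 shared, a
#' +2 log2 hypoxia effect, residual noise sd 0.5, and logistic
#' intensity-dependent missingness.
#'
#' @param n_proteins Number of proteins.
#' @param replicates Samples per (subtype, oxygen) group (>= 2).
#' @param baseline_mean,baseline_sd Per-protein baseline log2 intensity
#'   distribution.
#' @param subtype_effect Log2 shift added in basal samples for the
#'   `n_subtype_proteins` subtype-baseline proteins.
#' @param n_subtype_proteins Count of proteins with a subtype baseline
#'   difference.
#' @param n_hypoxia_luminal,n_hypoxia_basal Planted hypoxia-responsive
#'   protein counts per subtype (each count includes the shared ones).
#' @param n_hypoxia_shared Overlap between the two planted sets.
#' @param hypoxia_effect Planted log2 increase under hypoxia (> 0).
#' @param noise_sd Residual log2 noise sd (>= 0).
#' @param missing_midpoint,missing_slope Logistic MNAR parameters:
#'   P(missing) = logistic((midpoint - intensity) * slope). `slope = 0`
#'   disables missingness.
#' @param hypoxia_luminal_ids,hypoxia_basal_ids Optional explicit planted id
#'   vectors (override the counts; used to build coherent multi-dataset
#'   scenarios).
#' @param seed Integer seed.
#' @return A list of class `secretome_config`.
#' @export
secretome_config <- function(n_proteins = 1500, replicates = 6,
                             baseline_mean = 25, baseline_sd = 2,
                             subtype_effect = 1, n_subtype_proteins = 150,
                             n_hypoxia_luminal = 128, n_hypoxia_basal = 29,
                             n_hypoxia_shared = 7, hypoxia_effect = 2,
                             noise_sd = 0.5, missing_midpoint = 20,
                             missing_slope = 1,
                             hypoxia_luminal_ids = NULL,
                             hypoxia_basal_ids = NULL, seed = 1L) {
  assert_scalar_number(n_proteins, "n_proteins", 1)
  assert_scalar_number(replicates, "replicates", 0)
  assert_scalar_number(hypoxia_effect, "hypoxia_effect", 0, strict_lower = TRUE)
  assert_scalar_number(noise_sd, "noise_sd", 0)
  for (nm in c("n_subtype_proteins", "n_hypoxia_luminal", "n_hypoxia_basal",
               "n_hypoxia_shared"))
    assert_scalar_number(get(nm), nm, 0)
  if (n_hypoxia_shared > min(n_hypoxia_luminal, n_hypoxia_basal))
    stop_("shared hypoxia count exceeds a per-subtype count")
  structure(as.list(environment()), class = "secretome_config")
}

#' Simulate a secretome experiment with planted hypoxia responses
#'
#' Log2 intensity = per-protein baseline + subtype effect (basal samples of
#' subtype-baseline proteins) + hypoxia effect (hypoxia samples of the
#' planted subtype's responsive proteins) + Normal(0, noise sd); each cell is
#' then independently set missing with the logistic intensity-dependent
#' probability. Deterministic under the config seed.
#'
#' @param config A [secretome_config()].
#' @return A list: `matrix` (proteins x samples, NA = missing), `design`
#'   (sample_id, subtype, oxygen, replicate), `truth` (planted ids per
#'   subtype, their union, the subtype-baseline ids, and the effect sizes).
#' @export
simulate_secretome <- function(config = secretome_config()) {
  stopifnot(inherits(config, "secretome_config"))
  if (config$replicates < 2)
    stop_("need >= 2 replicates per group for downstream t tests")
  with_seed(config$seed, {
    ids <- protein_ids(config$n_proteins)
    design <- expand.grid(replicate = seq_len(config$replicates),
                          oxygen = c("normoxia", "hypoxia"),
                          subtype = c("luminal", "basal"),
                          stringsAsFactors = FALSE)
    design$sample_id <- sprintf("%s_%s_%d",
                                toupper(substr(design$subtype, 1, 3)),
                                ifelse(design$oxygen == "hypoxia", "HX", "NX"),
                                design$replicate)
    design <- design[, c("sample_id", "subtype", "oxygen", "replicate")]

    hyp_lum <- pick_ids(ids, config$n_hypoxia_luminal,
                        config$hypoxia_luminal_ids, "luminal hypoxia")
    if (is.null(config$hypoxia_basal_ids) &&
        is.null(config$hypoxia_luminal_ids)) {
      shared <- sample(hyp_lum, config$n_hypoxia_shared)
      hyp_bas <- c(shared, sample(setdiff(ids, hyp_lum),
                                  config$n_hypoxia_basal -
                                    config$n_hypoxia_shared))
    } else {
      hyp_bas <- pick_ids(ids, config$n_hypoxia_basal,
                          config$hypoxia_basal_ids, "basal hypoxia")
    }
    sub_ids <- sample(ids, config$n_subtype_proteins)

    baseline <- rnorm(config$n_proteins, config$baseline_mean,
                      config$baseline_sd)
    m <- matrix(baseline, nrow = config$n_proteins, ncol = nrow(design),
                dimnames = list(ids, design$sample_id))
    basal_cols <- design$subtype == "basal"
    hyp_cols <- design$oxygen == "hypoxia"
    m[sub_ids, basal_cols] <- m[sub_ids, basal_cols] + config$subtype_effect
    m[hyp_lum, hyp_cols & !basal_cols] <-
      m[hyp_lum, hyp_cols & !basal_cols] + config$hypoxia_effect
    m[hyp_bas, hyp_cols & basal_cols] <-
      m[hyp_bas, hyp_cols & basal_cols] + config$hypoxia_effect
    m <- m + rnorm(length(m), 0, config$noise_sd)
    m <- apply_mnar(m, config$missing_midpoint, config$missing_slope)

    truth <- list(hypoxia_luminal = sort(hyp_lum),
                  hypoxia_basal = sort(hyp_bas),
                  hypoxia_union = sort(union(hyp_lum, hyp_bas)),
                  subtype_proteins = sort(sub_ids),
                  hypoxia_effect = config$hypoxia_effect,
                  subtype_effect = config$subtype_effect)
    list(matrix = m, design = design, truth = truth)
  })
}

#' Configuration for the paired-compartment tissue generator
#'
#' Defaults emulate the microdissection design: paired epithelium and stroma
#' samples for ten patients per subtype, 283 stroma-exclusive subtype-effect
#' proteins, 100 shared-compartment subtype-effect proteins (both +2 log2 in
#' basal), and an epithelium-enriched purity marker planted at 62-fold.
#'
#' @param n_proteins Number of proteins.
#' @param patients_per_subtype Patients per subtype (>= 3).
#' @param n_stroma_exclusive,stroma_effect Count and log2 effect of proteins
#'   whose subtype difference exists only in stroma.
#' @param n_shared,shared_effect Count and log2 effect of proteins whose
#'   subtype difference exists in both compartments.
#' @param baseline_mean,baseline_sd,noise_sd As in [secretome_config()].
#' @param missing_midpoint,missing_slope Logistic MNAR parameters.
#' @param marker_fold Linear epithelium:stroma enrichment of the planted
#'   purity marker protein `"MARKER_KRT8"` (0 disables the marker).
#' @param stroma_ids,shared_ids Optional explicit planted id vectors.
#' @param seed Integer seed.
#' @return A list of class `tissue_config`.
#' @export
tissue_config <- function(n_proteins = 1500, patients_per_subtype = 10,
                          n_stroma_exclusive = 283, stroma_effect = 2,
                          n_shared = 100, shared_effect = 2,
                          baseline_mean = 25, baseline_sd = 2, noise_sd = 0.5,
                          missing_midpoint = 20, missing_slope = 1,
                          marker_fold = 62, stroma_ids = NULL,
                          shared_ids = NULL, seed = 1L) {
  assert_scalar_number(n_proteins, "n_proteins", 1)
  assert_scalar_number(patients_per_subtype, "patients_per_subtype", 0)
  assert_scalar_number(noise_sd, "noise_sd", 0)
  assert_scalar_number(marker_fold, "marker_fold", 0)
  structure(as.list(environment()), class = "tissue_config")
}

#' Simulate paired epithelium/stroma tumor proteomes
#'
#' Each patient contributes one epithelium and one stroma sample.
#' Stroma-exclusive planted proteins carry the subtype effect (basal minus
#' luminal) only in stroma samples; shared planted proteins carry it in both
#' compartments; the two planted sets are disjoint. A purity marker protein
#' is planted `marker_fold`-fold higher (linear) in epithelium and is exempt
#' from missingness so that paired purity ratios are always computable.
#'
#' @param config A [tissue_config()].
#' @return A list: `matrix`, `design` (sample_id, patient_id, subtype,
#'   compartment), `truth` (planted id sets, effects, marker id and fold).
#' @export
simulate_tissue <- function(config = tissue_config()) {
  stopifnot(inherits(config, "tissue_config"))
  if (config$patients_per_subtype < 3)
    stop_("need >= 3 patients per subtype")
  with_seed(config$seed, {
    ids <- protein_ids(config$n_proteins)
    n_pat <- 2L * config$patients_per_subtype
    patients <- sprintf("PT%02d", seq_len(n_pat))
    subtype <- rep(c("luminal", "basal"), each = config$patients_per_subtype)
    design <- data.frame(
      sample_id = as.vector(t(outer(patients, c("EPI", "STR"), paste,
                                    sep = "_"))),
      patient_id = rep(patients, each = 2L),
      subtype = rep(subtype, each = 2L),
      compartment = rep(c("epithelium", "stroma"), times = n_pat),
      stringsAsFactors = FALSE)

    stroma_ids <- pick_ids(ids, config$n_stroma_exclusive, config$stroma_ids,
                           "stroma-exclusive")
    shared_pool <- setdiff(ids, stroma_ids)
    shared_ids <- pick_ids(shared_pool, config$n_shared, config$shared_ids,
                           "shared-compartment")
    if (length(intersect(stroma_ids, shared_ids)))
      stop_("stroma-exclusive and shared planted sets must be disjoint")

    baseline <- rnorm(config$n_proteins, config$baseline_mean,
                      config$baseline_sd)
    m <- matrix(baseline, nrow = config$n_proteins, ncol = nrow(design),
                dimnames = list(ids, design$sample_id))
    basal <- design$subtype == "basal"
    stroma <- design$compartment == "stroma"
    m[stroma_ids, basal & stroma] <-
      m[stroma_ids, basal & stroma] + config$stroma_effect
    m[shared_ids, basal] <- m[shared_ids, basal] + config$shared_effect
    m <- m + rnorm(length(m), 0, config$noise_sd)
    m <- apply_mnar(m, config$missing_midpoint, config$missing_slope)

    marker_id <- NULL
    if (config$marker_fold > 0) {
      marker_id <- "MARKER_KRT8"
      marker <- config$baseline_mean + rnorm(nrow(design), 0, config$noise_sd)
      marker[!stroma] <- marker[!stroma] + log2(config$marker_fold)
      m <- rbind(m, matrix(marker, nrow = 1L,
                           dimnames = list(marker_id, design$sample_id)))
    }

    truth <- list(stroma_exclusive = sort(stroma_ids),
                  shared = sort(shared_ids),
                  stroma_effect = config$stroma_effect,
                  shared_effect = config$shared_effect,
                  marker_id = marker_id, marker_fold = config$marker_fold)
    list(matrix = m, design = design, truth = truth)
  })
}

#' Configuration for the survival-cohort generator
#'
#' Expression is Normal per gene; the standardized signature score z enters
#' an exponential-baseline proportional-hazards model
#' rate = baseline_hazard * exp(beta z + gamma treat + delta z treat), with
#' administrative censoring. Defaults emulate a breast-cancer expression
#' cohort of 852 patients with roughly 35-40% disease deaths over follow-up.
#'
#' @param n_genes,n_patients Dimensions of the expression matrix.
#' @param signature Character vector of signature gene ids (must be drawn
#'   from the generated gene pool `G0001..`); defaults to the first 33 genes.
#' @param gene_mean_mean,gene_mean_sd Distribution of per-gene mean
#'   expression (log2-like scale).
#' @param gene_sd Per-gene expression sd across patients.
#' @param beta Log hazard ratio per unit standardized signature score.
#' @param gamma Treatment main effect (log hazard).
#' @param delta Score-by-treatment interaction (log hazard).
#' @param baseline_hazard Exponential baseline rate per month (> 0).
#' @param treatment_prob Bernoulli treatment-assignment probability in (0,1).
#' @param censor_time Administrative censoring time in months (> 0).
#' @param seed Integer seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_genes = 1000, n_patients = 852, signature = NULL,
                          gene_mean_mean = 8, gene_mean_sd = 2, gene_sd = 1,
                          beta = log(2), gamma = 0, delta = 0,
                          baseline_hazard = 0.002, treatment_prob = 0.5,
                          censor_time = 250, seed = 1L) {
  assert_scalar_number(n_genes, "n_genes", 1)
  assert_scalar_number(n_patients, "n_patients", 4)
  assert_scalar_number(baseline_hazard, "baseline_hazard", 0,
                       strict_lower = TRUE)
  assert_scalar_number(treatment_prob, "treatment_prob", 0, 1, TRUE, TRUE)
  assert_scalar_number(censor_time, "censor_time", 0, strict_lower = TRUE)
  if (is.null(signature)) signature <- sprintf("G%04d", seq_len(min(33, n_genes)))
  structure(as.list(environment()), class = "cohort_config")
}

#' Simulate an expression cohort with hazard tied to a signature score
#'
#' Gene expression is drawn as Normal(per-gene mean, gene sd); the summed
#' mean-centered signature score is standardized internally to z, and each
#' patient's event time is exponential with rate
#' `baseline_hazard * exp(beta z + gamma treat + delta z treat)`, censored
#' administratively at `censor_time`. Clinical covariates (tumor size class,
#' grade class, node status, subtype, endocrine/chemo flags) are generated
#' independently of the hazard; `radiotherapy` is the treatment entering the
#' hazard.
#'
#' @param config A [cohort_config()].
#' @return A list: `cohort` (a [cohort_data]) and `truth` (signature genes,
#'   beta, gamma, delta, the internal z scores and treatment vector).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  missing_sig <- setdiff(config$signature, genes)
  if (length(missing_sig))
    stop_("signature gene(s) absent from the generated pool: %s",
          paste(missing_sig, collapse = ", "))
  with_seed(config$seed, {
    patients <- sprintf("PAT%04d", seq_len(config$n_patients))
    mu <- rnorm(config$n_genes, config$gene_mean_mean, config$gene_mean_sd)
    expr <- matrix(rnorm(config$n_genes * config$n_patients, mu,
                         config$gene_sd),
                   nrow = config$n_genes, ncol = config$n_patients,
                   dimnames = list(genes, patients))
    sig_expr <- expr[config$signature, , drop = FALSE]
    raw <- colSums(sig_expr - rowMeans(sig_expr))
    z <- as.numeric(scale(raw))
    treat <- rbinom(config$n_patients, 1L, config$treatment_prob)
    rate <- config$baseline_hazard *
      exp(config$beta * z + config$gamma * treat + config$delta * z * treat)
    t_event <- rexp(config$n_patients, rate)
    event <- as.integer(t_event <= config$censor_time)
    time <- pmin(t_event, config$censor_time)

    clinical <- data.frame(
      patient_id = patients,
      time = time, event = event,
      tumor_size_class = rbinom(config$n_patients, 1L, 0.4),
      grade_class = sample(1:3, config$n_patients, replace = TRUE),
      node_status = rbinom(config$n_patients, 1L, 0.35),
      subtype = sample(c("luminal", "basal"), config$n_patients,
                       replace = TRUE, prob = c(0.8, 0.2)),
      endocrine = rbinom(config$n_patients, 1L, 0.5),
      chemo = rbinom(config$n_patients, 1L, 0.25),
      radiotherapy = treat,
      stringsAsFactors = FALSE)
    cohort <- cohort_data(expr, clinical,
                          covariates = c("tumor_size_class", "grade_class",
                                         "node_status", "subtype"),
                          treatments = c("endocrine", "chemo", "radiotherapy"))
    truth <- list(signature = config$signature, beta = config$beta,
                  gamma = config$gamma, delta = config$delta,
                  z = z, treatment = treat)
    list(cohort = cohort, truth = truth)
  })
}

#' Simulate a coherent secretome + tissue discovery scenario
#'
#' Builds a paired secretome and tissue dataset over one protein universe in
#' which a planted signature set is hypoxia-responsive in both subtypes'
#' secretomes and stroma-exclusively subtype-differential in tissue — the
#' situation the derivation pipeline is designed to detect. Extra proteins
#' are planted in only one of the two datasets, and a disjoint
#' shared-compartment set exercises the epithelium subtraction, so false
#' intersection calls stay possible.
#'
#' @param n_proteins Size of the shared protein universe.
#' @param n_signature Planted signature size (responsive in both datasets).
#' @param n_hypoxia_extra Luminal-only hypoxia-responsive proteins not in the
#'   tissue planted set.
#' @param n_stroma_extra Stroma-exclusive proteins not hypoxia-responsive.
#' @param n_shared_compartment Proteins with a subtype effect in both tissue
#'   compartments (removed by the epithelium subtraction).
#' @param replicates,patients_per_subtype Group sizes for the two designs.
#' @param effect Planted log2 effect used in both datasets.
#' @param noise_sd Residual log2 noise sd in both datasets.
#' @param seed Integer seed.
#' @return A list: `secretome` and `tissue` (generator outputs) and `truth`
#'   with the planted `signature` ids (the expected derivation result).
#' @export
simulate_discovery <- function(n_proteins = 400, n_signature = 33,
                               n_hypoxia_extra = 10, n_stroma_extra = 10,
                               n_shared_compartment = 20, replicates = 6,
                               patients_per_subtype = 10, effect = 2,
                               noise_sd = 0.5, seed = 1L) {
  with_seed(seed, {
    ids <- protein_ids(n_proteins)
    picks <- sample(ids, n_signature + n_hypoxia_extra + n_stroma_extra +
                      n_shared_compartment)
    sig <- picks[seq_len(n_signature)]
    hyp_extra <- picks[n_signature + seq_len(n_hypoxia_extra)]
    str_extra <- picks[n_signature + n_hypoxia_extra +
                         seq_len(n_stroma_extra)]
    shared <- picks[n_signature + n_hypoxia_extra + n_stroma_extra +
                      seq_len(n_shared_compartment)]
    seeds <- sample.int(.Machine$integer.max, 2L)
    sec <- simulate_secretome(secretome_config(
      n_proteins = n_proteins, replicates = replicates,
      hypoxia_luminal_ids = c(sig, hyp_extra), hypoxia_basal_ids = sig,
      hypoxia_effect = effect, noise_sd = noise_sd, seed = seeds[1L]))
    tis <- simulate_tissue(tissue_config(
      n_proteins = n_proteins, patients_per_subtype = patients_per_subtype,
      stroma_ids = c(sig, str_extra), shared_ids = shared,
      stroma_effect = effect, shared_effect = effect, noise_sd = noise_sd,
      seed = seeds[2L]))
    list(secretome = sec, tissue = tis,
         truth = list(signature = sort(sig),
                      hypoxia_extra = sort(hyp_extra),
                      stroma_extra = sort(str_extra),
                      shared_compartment = sort(shared)))
  })
}
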