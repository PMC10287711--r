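# Perseus-style processing of log2 intensity matrices: valid-value filtering,
# downshifted-normal imputation of missing-not-at-random entries, two-sample
# Student's t tests with fold changes, and the marker-based microdissection
# purity estimate.

#' Imputation parameters for downshifted-normal draws
#'
#' Missing log2 intensities are replaced column-wise by draws from
#' Normal(mean_obs - downshift * sd_obs, (width * sd_obs)^2), where mean_obs
#' and sd_obs are the observed values of that column. The defaults (width 0.3,
#' downshift 1.8) are the conventional settings for left-censored label-free
#' proteomics data.
#'
#' @param width Multiplier on the per-column sd for the imputation sd (> 0).
#' @param downshift Downshift below the column mean, in sd units (>= 0).
#' @param seed Integer seed; identical seed and input give identical output.
#' @return A list of class `imputation_params`.
#' @export
imputation_params <- function(width = 0.3, downshift = 1.8, seed = 1L) {
  assert_scalar_number(width, "width", lower = 0, strict_lower = TRUE)
  assert_scalar_number(downshift, "downshift", lower = 0)
  structure(list(width = width, downshift = downshift, seed = seed),
            class = "imputation_params")
}

#' Differential-testing configuration
#'
#' @param alpha Two-sided significance threshold on the raw p value (the
#'   derivation path uses raw p, no multiplicity correction).
#' @param min_valid_fraction Minimum fraction of valid (observed) values a
#'   protein needs in a group to count as quantified there.
#' @param filter_mode `"any_group"` retains a protein quantified in at least
#'   one group at `min_valid_fraction` (the convention of the processing
#'   software this emulates); `"all_groups"` requires it in every group.
#' @param apply_filter,apply_imputation Toggle the filter / imputation stages
#'   inside [differential_test()].
#' @param var_equal Equal-variance (Student) t when `TRUE` (default); Welch
#'   otherwise.
#' @param annotate_bh Add a Benjamini-Hochberg adjusted p column (annotation
#'   only; never used by the derivation logic).
#' @return A list of class `differential_config`.
#' @export
differential_config <- function(alpha = 0.05, min_valid_fraction = 0.5,
                                filter_mode = c("any_group", "all_groups"),
                                apply_filter = TRUE, apply_imputation = TRUE,
                                var_equal = TRUE, annotate_bh = FALSE) {
  assert_scalar_number(alpha, "alpha", 0, 1, TRUE, TRUE)
  assert_scalar_number(min_valid_fraction, "min_valid_fraction", 0, 1,
                       strict_lower = TRUE)
  structure(list(alpha = alpha, min_valid_fraction = min_valid_fraction,
                 filter_mode = match.arg(filter_mode),
                 apply_filter = isTRUE(apply_filter),
                 apply_imputation = isTRUE(apply_imputation),
                 var_equal = isTRUE(var_equal),
                 annotate_bh = isTRUE(annotate_bh)),
            class = "differential_config")
}

#' Build a two-group contrast from a sample design
#'
#' Returns the sample-id groups for a factor contrast, optionally restricted
#' to samples matching other factor levels (e.g. hypoxia vs normoxia within
#' `subtype = "luminal"`).
#'
#' @param design Sample design data.frame with `sample_id`.
#' @param factor Name of the design column defining the contrast.
#' @param levels Length-2 character vector `(reference, alternative)`; group 2
#'   minus group 1 is the reported fold change. Defaults to the column's first
#'   two levels in sorted order.
#' @param within Named character vector of `factor = level` restrictions.
#' @return Named list of two character vectors of sample ids.
#' @export
design_groups <- function(design, factor, levels = NULL, within = NULL) {
  validate_sample_design(design)
  if (!factor %in% names(design))
    stop_("design has no column '%s'", factor)
  keep <- rep(TRUE, nrow(design))
  for (f in names(within)) {
    if (!f %in% names(design)) stop_("design has no column '%s'", f)
    keep <- keep & !is.na(design[[f]]) & design[[f]] == within[[f]]
  }
  d <- design[keep, , drop = FALSE]
  fac <- d[[factor]]
  if (anyNA(fac))
    stop_("factor '%s' has missing levels for samples in the contrast", factor)
  if (is.null(levels)) levels <- sort(unique(fac))
  if (length(levels) != 2L)
    stop_("a contrast needs exactly two levels; got %d", length(levels))
  groups <- lapply(levels, function(l) d$sample_id[fac == l])
  names(groups) <- levels
  for (l in levels)
    if (length(groups[[l]]) == 0L)
      stop_("contrast group '%s' is empty", l)
  groups
}

check_groups <- function(m, groups) {
  if (!is.list(groups) || length(groups) != 2L)
    stop_("'groups' must be a list of two sample-id vectors")
  ids <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(ids))
    stop_("a sample appears in both contrast groups")
  absent <- setdiff(ids, colnames(m))
  if (length(absent))
    stop_("contrast sample(s) absent from matrix: %s",
          paste(absent, collapse = ", "))
  if (any(lengths(groups) == 0L)) stop_("empty contrast group")
  groups
}

#' Filter proteins on valid (observed) values per group
#'
#' Retains a protein when its fraction of observed values reaches
#' `min_valid_fraction` in at least one group (`any_group`, default) or in
#' every group (`all_groups`). Observed values are never altered.
#'
#' @param m Numeric log2 intensity matrix (NA = missing).
#' @param groups Named list of two sample-id vectors (see [design_groups()]).
#' @param cfg A [differential_config()].
#' @return The row-subset of `m` (all columns kept).
#' @export
filter_valid_values <- function(m, groups, cfg = differential_config()) {
  validate_intensity_matrix(m)
  groups <- check_groups(m, groups)
  frac <- vapply(groups, function(ids) {
    rowMeans(!is.na(m[, ids, drop = FALSE]))
  }, numeric(nrow(m)))
  if (!is.matrix(frac)) frac <- matrix(frac, nrow = nrow(m))
  keep <- if (cfg$filter_mode == "any_group") {
    apply(frac >= cfg$min_valid_fraction, 1L, any)
  } else {
    apply(frac >= cfg$min_valid_fraction, 1L, all)
  }
  m[keep, , drop = FALSE]
}

#' Impute missing values from a downshifted normal distribution
#'
#' Column-wise (per sample) in log2 space: missing entries of each column are
#' drawn independently from a normal centered `downshift` observed-sds below
#' the observed column mean, with sd `width` times the observed column sd.
#' Observed values are never changed; output is deterministic under the seed.
#'
#' @param m Numeric log2 intensity matrix (NA = missing).
#' @param params An [imputation_params()].
#' @return `m` with missing entries filled in.
#' @export
impute_downshifted <- function(m, params = imputation_params()) {
  validate_intensity_matrix(m)
  stopifnot(inherits(params, "imputation_params"))
  if (!anyNA(m)) return(m)
  with_seed(params$seed, {
    for (j in seq_len(ncol(m))) {
      miss <- is.na(m[, j])
      if (!any(miss)) next
      obs <- m[!miss, j]
      if (length(obs) < 2L)
        stop_("column '%s' has %d observed value(s); need >= 2 to impute",
              colnames(m)[j], length(obs))
      mu <- mean(obs) - params$downshift * sd(obs)
      m[miss, j] <- rnorm(sum(miss), mean = mu, sd = params$width * sd(obs))
    }
    m
  })
}

#' Two-sample Student's t test per protein with fold changes
#'
#' Runs the valid-value filter and downshifted-normal imputation (each
#' switchable in `cfg`), then an equal-variance two-sided Student's t test per
#' protein between the two groups. The t statistic follows the
#' (group1 - group2) convention of [stats::t.test()]; the reported fold change
#' is group2 minus group1 on the log2 scale (condition vs reference).
#'
#' Proteins left with fewer than two valid values in a group (possible in
#' `any_group` filter mode without imputation) get `NA` statistics. A protein
#' with zero pooled variance reports t = 0, p = 1 when the means are equal,
#' and the smallest representable positive p with a warning otherwise.
#'
#' @param m Numeric log2 intensity matrix (NA = missing).
#' @param groups Named list of two sample-id vectors; see [design_groups()].
#' @param cfg A [differential_config()].
#' @param imp An [imputation_params()] (used when `cfg$apply_imputation`).
#' @return A data.frame of class `differential_table` with one row per
#'   retained protein: `protein_id`, `mean_g1`, `mean_g2`, `log2fc`
#'   (= mean_g2 - mean_g1), `linear_fold` (= 2^log2fc), `t_stat`, `df`,
#'   `p_value`, `n_valid_g1`, `n_valid_g2` (valid counts before imputation),
#'   and `p_bh` when `cfg$annotate_bh`.
#' @export
differential_test <- function(m, groups, cfg = differential_config(),
                              imp = imputation_params()) {
  validate_intensity_matrix(m)
  groups <- check_groups(m, groups)
  if (any(lengths(groups) < 2L))
    stop_("each contrast group needs >= 2 samples")
  m <- m[, unlist(groups, use.names = FALSE), drop = FALSE]
  if (cfg$apply_filter) m <- filter_valid_values(m, groups, cfg)
  n_valid <- vapply(groups, function(ids) {
    rowSums(!is.na(m[, ids, drop = FALSE]))
  }, numeric(nrow(m)))
  if (!is.matrix(n_valid)) n_valid <- matrix(n_valid, nrow = nrow(m))
  if (cfg$apply_imputation) m <- impute_downshifted(m, imp)

  g1 <- m[, groups[[1L]], drop = FALSE]
  g2 <- m[, groups[[2L]], drop = FALSE]
  n1 <- rowSums(!is.na(g1)); n2 <- rowSums(!is.na(g2))
  m1 <- rowMeans(g1, na.rm = TRUE); m2 <- rowMeans(g2, na.rm = TRUE)
  v1 <- apply(g1, 1L, stats::var, na.rm = TRUE)
  v2 <- apply(g2, 1L, stats::var, na.rm = TRUE)

  ok <- n1 >= 2L & n2 >= 2L
  t_stat <- df <- p <- rep(NA_real_, nrow(m))
  if (cfg$var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df[ok] <- (n1 + n2 - 2)[ok]
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df[ok] <- ((v1 / n1 + v2 / n2)^2 /
                 ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)))[ok]
  }
  t_stat[ok] <- ((m1 - m2) / se)[ok]
  zero_var <- ok & se == 0
  if (any(zero_var)) {
    eq <- zero_var & m1 == m2
    t_stat[eq] <- 0
    t_stat[zero_var & !eq] <- sign(m1 - m2)[zero_var & !eq] * Inf
    if (any(zero_var & !eq))
      warn_("%d protein(s) with zero pooled variance and unequal means; p set to the smallest positive value",
            sum(zero_var & !eq))
  }
  p[ok] <- 2 * pt(-abs(t_stat[ok]), df[ok])
  p[zero_var & t_stat == 0] <- 1
  p[zero_var & is.infinite(t_stat)] <- .Machine$double.xmin

  out <- data.frame(protein_id = rownames(m),
                    mean_g1 = m1, mean_g2 = m2,
                    log2fc = m2 - m1, linear_fold = 2^(m2 - m1),
                    t_stat = t_stat, df = df, p_value = p,
                    n_valid_g1 = n_valid[, 1L], n_valid_g2 = n_valid[, 2L],
                    row.names = NULL, stringsAsFactors = FALSE)
  if (cfg$annotate_bh) out$p_bh <- p.adjust(out$p_value, method = "BH")
  attr(out, "groups") <- names(groups)
  class(out) <- c("differential_table", "data.frame")
  out
}

#' @export
print.differential_table <- function(x, ...) {
  gr <- attr(x, "groups") %||% c("g1", "g2")
  cat(sprintf("Differential table: %d proteins, contrast %s vs %s\n",
              nrow(x), gr[2L], gr[1L]))
  cat(sprintf("  p < 0.05: %d (of %d testable)\n",
              sum(x$p_value < 0.05, na.rm = TRUE), sum(!is.na(x$p_value))))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Estimate epithelial contamination of microdissected stroma from a marker
#'
#' Compares the intensity of an epithelium-specific marker (e.g. a cytokeratin)
#' between matched epithelium and stroma samples of the same patients. Per
#' patient, the linear-scale ratio stroma/epithelium of the marker estimates
#' the epithelial fraction present in the stromal sample; a marker that is
#' k-fold higher in epithelium gives an estimate of 100/k percent.
#'
#' @param epith,stroma Log2 intensity matrices for the two compartments.
#' @param marker_id Row id of the marker, present in both matrices.
#' @param pairing Data.frame with columns `patient_id`, `epithelium`,
#'   `stroma` naming the matched sample columns.
#' @return A list of class `purity_estimate`: `mean_percent`, `median_percent`,
#'   `ratios` (named per-patient linear stroma/epithelium ratios), `n_pairs`.
#' @export
estimate_marker_purity <- function(epith, stroma, marker_id, pairing) {
  validate_intensity_matrix(epith, "epithelium matrix")
  validate_intensity_matrix(stroma, "stroma matrix")
  for (need in c("patient_id", "epithelium", "stroma"))
    if (!need %in% names(pairing))
      stop_("pairing table lacks column '%s'", need)
  if (!marker_id %in% rownames(epith) || !marker_id %in% rownames(stroma))
    stop_("marker '%s' absent from one of the matrices", marker_id)
  e <- epith[marker_id, as.character(pairing$epithelium)]
  s <- stroma[marker_id, as.character(pairing$stroma)]
  complete <- !is.na(e) & !is.na(s)
  if (any(!complete))
    warn_("marker missing for %d pair(s); dropped", sum(!complete))
  if (!any(complete)) stop_("no complete patient pair with the marker observed")
  e <- e[complete]; s <- s[complete]
  if (any(is.infinite(e) & e < 0))
    stop_("zero epithelium marker intensity; ratio undefined")
  ratios <- 2^(s - e)              # linear stroma/epithelium; -Inf log2 -> 0
  names(ratios) <- pairing$patient_id[complete]
  structure(list(mean_percent = 100 * mean(ratios),
                 median_percent = 100 * median(ratios),
                 ratios = ratios, n_pairs = length(ratios)),
            class = "purity_estimate")
}

#' @export
print.purity_estimate <- function(x, ...) {
  cat(sprintf("Marker purity estimate over %d patient pair(s):\n", x$n_pairs))
  cat(sprintf("  mean %.2f%%, median %.2f%% epithelial content in stroma\n",
              x$mean_percent, x$median_percent))
  invisible(x)
}
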