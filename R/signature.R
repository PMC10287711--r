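# Set-logic signature derivation (hypoxia-increased secretome proteins
# intersected with stroma-exclusive subtype differences), probe collapsing,
# summed mean-centered scoring and quartile stratification.

#' Collapse probe-level expression to gene level by max probe
#'
#' For each gene and sample, takes the maximum over that gene's probes.
#' Probes without a map entry are dropped (a count is reported).
#'
#' @param expression Numeric matrix, probes x samples.
#' @param probe_map Data.frame with columns `probe_id`, `gene_id`.
#' @return Numeric matrix, genes x samples.
#' @export
collapse_probes_max <- function(expression, probe_map) {
  validate_intensity_matrix(expression, "probe expression matrix")
  for (need in c("probe_id", "gene_id"))
    if (!need %in% names(probe_map)) stop_("probe map lacks column '%s'", need)
  if (nrow(probe_map) == 0L) stop_("probe map is empty")
  gene <- probe_map$gene_id[match(rownames(expression), probe_map$probe_id)]
  unmapped <- is.na(gene)
  if (all(unmapped)) stop_("no probe in the matrix has a map entry")
  if (any(unmapped))
    message(sprintf("collapse_probes_max: dropping %d unmapped probe(s)",
                    sum(unmapped)))
  expression <- expression[!unmapped, , drop = FALSE]
  gene <- gene[!unmapped]
  idx <- split(seq_len(nrow(expression)), gene)
  out <- t(vapply(idx, function(ix) {
    if (length(ix) == 1L) expression[ix, ]
    else apply(expression[ix, , drop = FALSE], 2L, max)
  }, numeric(ncol(expression))))
  colnames(out) <- colnames(expression)
  out
}

sig_from_table <- function(tab, keep, name) {
  ids <- tab$protein_id[keep & !is.na(keep)]
  signature_set(name, sort(ids), allow_empty = TRUE)
}

#' Derive the hypoxome: proteins increased by hypoxia per subtype
#'
#' From per-subtype hypoxia-vs-normoxia differential tables, selects the
#' proteins with p below `alpha` and a positive log2 fold change (increased
#' under hypoxia), and forms the union over subtypes.
#'
#' @param diff_lum,diff_bas [differential_test()] tables for the
#'   hypoxia-vs-normoxia contrast within the luminal-like and basal-like
#'   groups (group 1 = normoxia, group 2 = hypoxia).
#' @param alpha Significance threshold on the raw p value.
#' @return A list of class `hypoxome`: signature sets `luminal`, `basal`
#'   (per-subtype hypoxia-increased proteins), `shared` (their intersection)
#'   and `union` (the hypoxome), all lexicographically sorted.
#' @export
derive_hypoxome <- function(diff_lum, diff_bas, alpha = 0.05) {
  assert_scalar_number(alpha, "alpha", 0, 1, TRUE, TRUE)
  if (!length(intersect(diff_lum$protein_id, diff_bas$protein_id)))
    warn_("the two differential tables share no proteins; union still formed")
  up <- function(tab) !is.na(tab$p_value) & tab$p_value < alpha & tab$log2fc > 0
  lum <- sig_from_table(diff_lum, up(diff_lum), "hypoxia_up_luminal")
  bas <- sig_from_table(diff_bas, up(diff_bas), "hypoxia_up_basal")
  structure(list(
    luminal = lum, basal = bas,
    shared = signature_set("hypoxia_up_shared",
                           sort(intersect(lum$members, bas$members)),
                           allow_empty = TRUE),
    union = signature_set("hypoxome",
                          sort(union(lum$members, bas$members)),
                          allow_empty = TRUE)),
    class = "hypoxome")
}

#' @export
print.hypoxome <- function(x, ...) {
  cat(sprintf("Hypoxome: %d proteins (luminal %d, basal %d, shared %d)\n",
              length(x$union$members), length(x$luminal$members),
              length(x$basal$members), length(x$shared$members)))
  invisible(x)
}

#' Derive stroma-exclusive subtype differences
#'
#' Proteins differing between subtypes in the stroma (p below `alpha`,
#' either direction) minus those also differing in the epithelium (any
#' direction): subtype differences unique to the stromal compartment.
#'
#' @param diff_stroma,diff_epi [differential_test()] tables for the
#'   basal-vs-luminal contrast within stroma and epithelium respectively.
#' @param alpha Significance threshold on the raw p value.
#' @return A lexicographically sorted [signature_set] named
#'   `"stroma_exclusive"` (possibly empty).
#' @export
derive_stroma_exclusive <- function(diff_stroma, diff_epi, alpha = 0.05) {
  assert_scalar_number(alpha, "alpha", 0, 1, TRUE, TRUE)
  sig <- function(tab) tab$protein_id[!is.na(tab$p_value) & tab$p_value < alpha]
  s <- sig(diff_stroma); e <- sig(diff_epi)
  if (identical(diff_stroma$protein_id, diff_epi$protein_id) &&
      isTRUE(all.equal(diff_stroma$p_value, diff_epi$p_value)))
    warn_("stroma and epithelium tables are identical; exclusive set is empty")
  signature_set("stroma_exclusive", sort(setdiff(s, e)), allow_empty = TRUE)
}

#' Intersect the hypoxome with the stroma-exclusive set
#'
#' The candidate stromal hypoxia signature: proteins both increased by hypoxia
#' in the secretomes and showing stroma-exclusive subtype differences in
#' tissue.
#'
#' @param hypoxome A [signature_set] (e.g. `derive_hypoxome(...)$union`).
#' @param stroma_exclusive A [signature_set].
#' @param name Name for the resulting set.
#' @return A sorted, duplicate-free [signature_set] (possibly empty, with a
#'   warning).
#' @export
intersect_signature <- function(hypoxome, stroma_exclusive,
                                name = "derived_signature") {
  stopifnot(inherits(hypoxome, "signature_set"),
            inherits(stroma_exclusive, "signature_set"))
  members <- sort(intersect(hypoxome$members, stroma_exclusive$members))
  if (length(members) == 0L)
    warn_("empty intersection between '%s' and '%s'",
          hypoxome$name, stroma_exclusive$name)
  signature_set(name, members, allow_empty = TRUE)
}

#' Run the full derivation from two intensity bundles
#'
#' Convenience wrapper chaining the four differential tests and the set
#' logic: hypoxia vs normoxia within each subtype on the secretome matrix,
#' basal vs luminal within each compartment on the tissue matrix, then
#' hypoxome, stroma-exclusive set and their intersection. The secretome
#' contrasts use the filter + imputation defaults; the tissue contrasts use
#' the filter only (missing tissue values are left unimputed and handled by
#' complete-observation t tests).
#'
#' @param secretome,secretome_design Intensity matrix and design with
#'   `subtype` (luminal/basal) and `oxygen` (normoxia/hypoxia) columns.
#' @param tissue,tissue_design Intensity matrix and design with `subtype` and
#'   `compartment` (epithelium/stroma) columns.
#' @param alpha Significance threshold used throughout.
#' @param cfg A [differential_config()] for the secretome contrasts.
#' @param imp An [imputation_params()].
#' @return A list with the four differential tables (`diff_lum`, `diff_bas`,
#'   `diff_stroma`, `diff_epi`), the `hypoxome`, the `stroma_exclusive` set
#'   and the final `signature`.
#' @export
derive_signature <- function(secretome, secretome_design, tissue,
                             tissue_design, alpha = 0.05,
                             cfg = differential_config(alpha = alpha),
                             imp = imputation_params()) {
  diff_lum <- differential_test(
    secretome,
    design_groups(secretome_design, "oxygen", c("normoxia", "hypoxia"),
                  within = c(subtype = "luminal")), cfg, imp)
  diff_bas <- differential_test(
    secretome,
    design_groups(secretome_design, "oxygen", c("normoxia", "hypoxia"),
                  within = c(subtype = "basal")), cfg, imp)
  tissue_cfg <- cfg
  tissue_cfg$apply_imputation <- FALSE
  diff_stroma <- differential_test(
    tissue,
    design_groups(tissue_design, "subtype", c("luminal", "basal"),
                  within = c(compartment = "stroma")), tissue_cfg)
  diff_epi <- differential_test(
    tissue,
    design_groups(tissue_design, "subtype", c("luminal", "basal"),
                  within = c(compartment = "epithelium")), tissue_cfg)
  hyp <- derive_hypoxome(diff_lum, diff_bas, alpha)
  excl <- derive_stroma_exclusive(diff_stroma, diff_epi, alpha)
  list(diff_lum = diff_lum, diff_bas = diff_bas, diff_stroma = diff_stroma,
       diff_epi = diff_epi, hypoxome = hyp, stroma_exclusive = excl,
       signature = intersect_signature(hyp$union, excl))
}

#' Score a signature in an expression cohort
#'
#' Each signature gene is normalized by subtraction — the cohort-wide mean of
#' that gene is subtracted from every patient's value — and the per-patient
#' score is the sum of the normalized values over the signature genes. When
#' no gene is dropped the scores sum to zero across the cohort.
#'
#' @param cohort A [cohort_data] object.
#' @param sig A [signature_set].
#' @param missing_gene_policy What to do with signature genes absent from the
#'   cohort: drop them with a warning (default) or raise an error.
#' @return A data.frame of class `score_vector` with columns `patient_id` and
#'   `score`, and attributes `genes_used`, `genes_dropped`.
#' @export
score_signature <- function(cohort, sig,
                            missing_gene_policy = c("drop_warn", "error")) {
  stopifnot(inherits(cohort, "cohort_data"), inherits(sig, "signature_set"))
  missing_gene_policy <- match.arg(missing_gene_policy)
  present <- sig$members[sig$members %in% rownames(cohort$expression)]
  absent <- setdiff(sig$members, present)
  if (length(absent)) {
    if (missing_gene_policy == "error")
      stop_("signature gene(s) absent from cohort: %s",
            paste(absent, collapse = ", "))
    warn_("dropping %d signature gene(s) absent from cohort: %s",
          length(absent), paste(absent, collapse = ", "))
  }
  if (length(present) == 0L)
    stop_("no signature gene present in the cohort expression matrix")
  e <- cohort$expression[present, , drop = FALSE]
  centered <- e - rowMeans(e)
  out <- data.frame(patient_id = colnames(e), score = colSums(centered),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "genes_used") <- present
  attr(out, "genes_dropped") <- absent
  class(out) <- c("score_vector", "data.frame")
  out
}

#' Stratify patients into signature-score quartiles
#'
#' Quartile boundaries are the 25th/50th/75th percentiles of the scores
#' (linear-interpolation quantile convention). Scores exactly on a boundary
#' go to the lower group, so the high group (Q4) is conservative.
#'
#' @param scores A `score_vector` from [score_signature()].
#' @return The input with added columns `quartile` (factor Q1..Q4) and `high`
#'   (logical, Q4).
#' @export
stratify_quartiles <- function(scores) {
  stopifnot(inherits(scores, "score_vector"))
  s <- scores$score
  if (length(s) < 4L)
    stop_("quartile stratification needs >= 4 patients; got %d", length(s))
  if (diff(range(s)) == 0)
    stop_("all scores identical; no quartile stratification possible")
  q <- quantile(s, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  idx <- 1L + (s > q[1L]) + (s > q[2L]) + (s > q[3L])
  scores$quartile <- factor(paste0("Q", idx), levels = paste0("Q", 1:4))
  scores$high <- idx == 4L
  scores
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf("Signature scores for %d patients (%d gene(s) used",
              nrow(x), length(attr(x, "genes_used"))))
  nd <- length(attr(x, "genes_dropped"))
  cat(if (nd) sprintf(", %d dropped)\n", nd) else ")\n")
  if (!is.null(x$quartile)) print(table(x$quartile))
  invisible(x)
}
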