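---
title: "Deriving and evaluating a stromal hypoxia protein signature"
author: "stromasig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and evaluating a stromal hypoxia protein signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stromasig)
```

## The problem

Hypoxic tumor cells remodel their surroundings in part through the proteins
they secrete. A signature of that remodeling can be read out in two places:
in the conditioned media of breast cancer cell lines cultured under low
oxygen (the secretome), and in the stromal compartment of microdissected
tumors, where secreted proteins accumulate. `stromasig` implements the full
computational path from those two kinds of log2 protein-intensity matrices to
a prognostic protein signature evaluated in an expression cohort:

1. **Differential abundance** per subtype (luminal-like vs basal-like) with
   Perseus-style preprocessing;
2. **Set logic**: proteins increased by hypoxia in the secretomes (the
   "hypoxome"), intersected with proteins whose subtype differences are
   exclusive to tumor stroma;
3. **Scoring** the signature in a gene-expression cohort and stratifying
   patients by score quartiles;
4. **Survival evaluation** (Kaplan-Meier, log-rank, Cox proportional
   hazards, treatment interaction);
5. **Resampling**: a random-selection permutation test of signature
   uniqueness and a greedy leave-one-out signature reduction.

Because the original mass-spectrometry depositions and the clinical cohort
are access-controlled, the package ships seeded synthetic generators that
reproduce the *statistical structure* of each data type, with planted ground
truth used as a recovery oracle throughout the test suite.

## Differential abundance model

All proteomics stages operate on a proteins x samples matrix of log2
intensities in which `NA` is an explicit "not quantified" state. Low-abundance
proteins are likelier to be unquantified (missing not at random), which
motivates the two preprocessing steps:

* **Valid-value filter.** A protein is kept when it is observed in at least
  `min_valid_fraction` (default 0.5) of the samples of at least one contrast
  group. The source wording for this rule is ambiguous between
  retain-if-any-group-passes and remove-if-any-group-fails; the processing
  software it emulates uses the retention convention, so `any_group` is the
  default and `all_groups` is available as `filter_mode` — both are tested.
* **Downshifted-normal imputation.** Missing entries of each sample column
  are drawn from Normal(mean_obs − downshift · sd_obs, (width · sd_obs)²)
  with defaults width 0.3 and downshift 1.8 (in units of the observed column
  sd). This deliberately places imputed values in the left tail, where
  censored low-abundance measurements plausibly live. Imputation is
  column-wise in log2 space and never touches an observed value; it is
  deterministic under its seed.

The test itself is the classical equal-variance two-sample Student's t,
two-sided, per protein; Welch is available behind `var_equal = FALSE` but is
never the default. The derivation path thresholds the *raw* p value at
`alpha = 0.05` with no multiplicity correction — that is the procedure being
reproduced, not a recommendation; a Benjamini-Hochberg column can be added as
an annotation (`annotate_bh`). Fold changes are reported as
`2^(mean_g2 − mean_g1)` (difference of log2 means), not as ratios of linear
means. Degenerate inputs are handled explicitly: zero pooled variance with
equal means gives t = 0, p = 1; with unequal means the p value is reported as
the smallest representable positive number, with a warning.

```{r diff-example}
sec <- simulate_secretome(secretome_config(n_proteins = 300, seed = 7,
                                           n_hypoxia_luminal = 20,
                                           n_hypoxia_basal = 8,
                                           n_hypoxia_shared = 3))
g <- design_groups(sec$design, "oxygen", c("normoxia", "hypoxia"),
                   within = c(subtype = "luminal"))
tab <- differential_test(sec$matrix, g, imp = imputation_params(seed = 7))
head(tab[order(tab$p_value), c("protein_id", "log2fc", "p_value")], 4)
```

## Signature derivation

With four differential tables — hypoxia vs normoxia within each subtype on
the secretome, basal vs luminal within each compartment on tissue — the
derivation is pure set logic:

* **Hypoxome**: per subtype, proteins with p < alpha *and* positive log2
  fold change ("significantly increased"; no fold-change magnitude cut,
  since none is part of the procedure), unioned over subtypes.
* **Stroma-exclusive set**: proteins significant in the stroma contrast
  (either direction) minus proteins significant in the epithelium contrast
  (either direction). Direction is deliberately ignored on both sides: any
  epithelium-significant protein is subtracted.
* **Signature**: the sorted intersection of the two.

Sets are kept lexicographically sorted so GMT output is reproducible.
`derive_signature()` chains all of this; the secretome contrasts run with
filter + imputation, the tissue contrasts with the filter only (tissue
missingness is handled by complete-observation t tests), matching the
discovery procedure.

One caveat this design makes explicit: the epithelium subtraction removes a
truly stroma-exclusive protein whenever the epithelium test is a false
positive, which happens at rate alpha. The expected recall of the
intersection is therefore bounded near `1 − alpha` (~0.95) even at very high
power — a property of the procedure, not of this implementation.

## Scoring, quartiles and survival

In a cohort, probe-level expression is collapsed to genes by **max probe**
(per gene and sample, the maximum over its probes). Each signature gene is
then **normalized by subtraction** — its cohort-wide mean is subtracted —
and a patient's score is the **sum** of normalized values over signature
genes. Scores therefore sum to zero across the cohort when no gene is
dropped, and are invariant to adding a constant to any single gene. Genes
missing from a cohort are dropped with a warning by default
(`missing_gene_policy = "drop_warn"`).

Patients are stratified at the score quartiles (linear-interpolation
quantile convention, type 7). A score exactly on a boundary goes to the
*lower* group, so the signature-high group (Q4) is conservative. The
prognostic read-outs are:

* Kaplan-Meier curves and the two-sided log-rank test (events precede
  censorings at tied times);
* Cox proportional-hazards fits with all covariates entered simultaneously,
  using the Efron tie correction (chosen for accuracy; results from software
  using Breslow ties can differ in the third decimal), convergence at 1e-9
  on the log partial likelihood within 100 iterations, Wald tests and 95%
  confidence intervals from the inverse information;
* a treatment-interaction test: `score_high + treatment +
  score_high x treatment` (+ adjusters), reporting the interaction hazard
  ratio and Wald p.

The Kaplan-Meier estimator, log-rank statistic and Cox partial-likelihood
maximization are delegated to the `survival` package behind this module's
interface; the test suite independently cross-checks them against hand
accumulation of the log-rank 2x2 tables and a brute-force grid maximization
of the Efron partial likelihood.

## Resampling

**Permutation uniqueness.** The candidate signature's strength — the Q4 vs
Q1-3 log-rank chi-square of its score — is compared with the strengths of
`n_permutations` same-size sets drawn uniformly without replacement from a
pool (by construction, the union of the two derivation source sets). The
default B is 10,000, enough to resolve empirical p values near 1e-4, and the
add-one rule `(1 + #{null >= obs}) / (B + 1)` keeps p strictly positive.
Chi-square and p are monotone in each other at 1 df, so ranking by either is
equivalent.

**Greedy reduction.** From the full signature (step 0), every leave-one-out
subset is evaluated and the one with the lowest log-rank p is kept; this
repeats down to a single member. The trajectory records one set per size;
the best step is the minimum-p step, with ties resolved toward the larger
set. Within a step, ties at machine precision prefer the larger chi-square
and then removal of the lexicographically smallest member — an arbitrary but
documented and fully deterministic convention. Because step 0 is part of the
trajectory, the best subset can never be weaker than the full signature.

```{r reduce-example}
sim <- simulate_cohort(cohort_config(n_genes = 40, n_patients = 400,
                                     signature = sprintf("G%04d", 1:6),
                                     beta = log(2), seed = 3))
tr <- greedy_reduce(sim$cohort, signature_set("padded", sprintf("G%04d", 1:10)))
tr
```

## What the synthetic generators emulate — and what they do not

* `simulate_secretome()`: per-protein baselines Normal(25, 2) on the log2
  scale, a subtype baseline shift on a subset of proteins, planted hypoxia
  effects of +2 log2 on per-subtype responsive sets (defaults 128 luminal /
  29 basal with 7 shared, mirroring the discovery counts), residual noise
  sd 0.5, and six replicates per (subtype, oxygen) group. Missingness is
  intensity-dependent: P(missing) = logistic((midpoint − intensity) · slope)
  with midpoint 20 and slope 1, giving a few percent missing overall,
  concentrated in low-abundance proteins — the MNAR pattern the downshifted
  imputation is built for.
* `simulate_tissue()`: paired epithelium/stroma samples for ten patients per
  subtype; stroma-exclusive planted proteins carry the subtype effect only
  in stroma, shared planted proteins in both compartments; an
  epithelium-enriched purity marker is planted at 62-fold. Cell-line or
  patient identity beyond the pairing is not modelled.
* `simulate_cohort()`: expression Normal per gene; the standardized signature
  score z enters an exponential-baseline proportional-hazards model,
  rate = baseline · exp(beta z + gamma treat + delta z·treat), with
  administrative censoring at 250 months and baseline 0.002/month (~35-40%
  events at n = 852). The exponential baseline is the simplest generator
  consistent with proportional hazards; the procedure being evaluated fits
  Cox models and never commits to a baseline form.
* `simulate_discovery()` builds a *coherent* secretome + tissue pair in which
  33 planted proteins are responsive in both datasets (plus 10
  hypoxia-only and 10 stroma-only extras and 20 shared-compartment decoys in
  a 400-protein universe). With independently drawn planted sets, the
  intersection's false positives — planted-in-one-list proteins that are
  falsely significant in the other list at rate ~alpha — would dominate a
  small random overlap; the coherent scenario reflects the biology the
  pipeline assumes (a real shared signal) while keeping both false-positive
  routes open. At the defaults the expected count of false intersection
  calls is ~1.7, i.e. expected precision ~0.95 at recall ~0.95.

None of the generators model batch effects, peptide-level structure,
non-proportional hazards, informative censoring, or correlation between
clinical covariates and expression; passing recovery tests on them
demonstrates that the *procedure* is implemented correctly and is calibrated
under its own assumptions, not that it will perform identically on real
cohort data.

## Numerical conventions and problem sizes

Seeds are explicit everywhere randomness occurs (generator configs,
imputation parameters, the permutation test) and functions restore the
caller's RNG state. Quartile cuts use quantile type 7; boundary ties go
down. The tie-break rules of the reduction are described above. Calibration
checks in the test suite use deliberately modest problem sizes — e.g. 1,000
null log-rank simulations at n = 200, 200 permutation-null repetitions at
B = 199, Cox recovery at n = 500, and recovery of the planted discovery
scenario averaged over five seeds — sizes at which binomial/3-sigma bounds
are already tight enough to detect miscalibration while the whole suite
stays fast.

## Known limitations

* The valid-value filter ambiguity (any-group vs all-groups) is exposed
  rather than resolved; results can differ between modes for sparse data.
* Tissue contrasts use complete-observation t tests rather than imputation;
  proteins quantified in fewer than two samples of a group are reported
  with `NA` statistics and never reach a significance set.
* The Efron/Breslow tie-method choice means hazard ratios can differ in the
  third decimal from software using Breslow ties.
* Identifiers are matched exactly and case-sensitively; mapping protein
  accessions to gene symbols (or probe annotation) is upstream data
  curation, not part of the pipeline.
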