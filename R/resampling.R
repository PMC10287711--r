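# Resampling evaluation of a candidate signature: the random-selection
# permutation test of uniqueness against a pool of source proteins, and the
# greedy recursive leave-one-out signature reduction.

# Cohort-mean-centered expression rows for a gene set; scoring any subset is
# then a colSums over its rows, which keeps the permutation and reduction
# loops cheap.
centered_expression <- function(cohort, genes) {
  present <- genes[genes %in% rownames(cohort$expression)]
  if (length(present) < length(genes))
    warn_("dropping %d gene(s) absent from cohort", length(genes) - length(present))
  if (length(present) == 0L)
    stop_("no gene of the set is present in the cohort")
  e <- cohort$expression[present, , drop = FALSE]
  e - rowMeans(e)
}

# Log-rank strength of a member subset given the centered expression matrix:
# summed score -> quartiles -> Q4 vs Q1-3 log-rank.
strength_from_centered <- function(centered, members, time, event) {
  score <- colSums(centered[members, , drop = FALSE])
  if (diff(range(score)) == 0)
    stop_("all scores identical; no quartile stratification possible")
  q <- quantile(score, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  high <- score > q[3L]
  lr <- logrank_test(time, event, factor(ifelse(high, "Q4", "Q1-3"),
                                         levels = c("Q1-3", "Q4")))
  c(chi_square = lr$chi_square, p_value = lr$p_value)
}

#' Prognostic strength of a signature in a cohort
#'
#' Scores the signature (summed mean-centered expression), stratifies the
#' cohort into score quartiles, and runs a two-sided log-rank test of the
#' upper quartile (Q4) against the rest (Q1-3).
#'
#' @param cohort A [cohort_data] object (>= 4 patients, >= 1 event).
#' @param sig A [signature_set].
#' @return A list: `chi_square`, `p_value`, `n`, `n_high`.
#' @export
signature_strength <- function(cohort, sig) {
  stopifnot(inherits(cohort, "cohort_data"), inherits(sig, "signature_set"))
  scores <- stratify_quartiles(score_signature(cohort, sig))
  lr <- logrank_test(cohort$time, cohort$event,
                     factor(ifelse(scores$high, "Q4", "Q1-3"),
                            levels = c("Q1-3", "Q4")))
  list(chi_square = lr$chi_square, p_value = lr$p_value,
       n = nrow(scores), n_high = sum(scores$high))
}

#' Random-selection permutation test of signature uniqueness
#'
#' Compares the candidate signature's prognostic strength (Q4 vs Q1-3
#' log-rank chi-square) with the null distribution obtained by drawing
#' same-size member sets uniformly without replacement from a pool of source
#' proteins. The empirical p uses the add-one rule
#' `(1 + #\{null >= observed\}) / (B + 1)` and is therefore never zero.
#'
#' @param cohort A [cohort_data] object.
#' @param candidate The candidate [signature_set].
#' @param pool A [signature_set]: the selection universe (at least as large
#'   as the candidate; typically the union of the derivation source sets).
#' @param n_permutations Number of random draws B (>= 1; default 10000).
#' @param seed Integer seed; draws are deterministic under it.
#' @return A list of class `permutation_result`: `observed_chi_square`,
#'   `observed_p`, `null_chi_square` (length B), `empirical_p`,
#'   `n_permutations`.
#' @export
permutation_uniqueness <- function(cohort, candidate, pool,
                                   n_permutations = 10000, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_data"),
            inherits(candidate, "signature_set"),
            inherits(pool, "signature_set"))
  if (n_permutations < 1) stop_("n_permutations must be >= 1")
  k <- length(candidate$members)
  if (length(pool$members) < k)
    stop_("pool (%d) is smaller than the candidate (%d)",
          length(pool$members), k)
  obs <- signature_strength(cohort, candidate)
  pool_centered <- centered_expression(cohort, pool$members)
  pool_members <- rownames(pool_centered)
  if (length(pool_members) < k)
    stop_("pool has fewer scoreable members (%d) than the candidate size (%d)",
          length(pool_members), k)
  null_chi <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      draw <- sample(pool_members, k)
      strength_from_centered(pool_centered, draw, cohort$time,
                             cohort$event)[["chi_square"]]
    }, numeric(1L))
  })
  structure(list(observed_chi_square = obs$chi_square,
                 observed_p = obs$p_value,
                 null_chi_square = null_chi,
                 empirical_p = (1 + sum(null_chi >= obs$chi_square)) /
                   (n_permutations + 1),
                 n_permutations = n_permutations),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Random-selection permutation test (B = %d)\n",
              x$n_permutations))
  cat(sprintf("  observed chi-square = %.4g (log-rank p = %.3g)\n",
              x$observed_chi_square, x$observed_p))
  cat(sprintf("  empirical p = %.4g\n", x$empirical_p))
  invisible(x)
}

#' Greedy recursive leave-one-out signature reduction
#'
#' Starting from the full signature (recorded as step 0), repeatedly
#' evaluates every leave-one-out subset with the Q4-vs-Q1-3 log-rank test
#' and retains the subset with the lowest p value, until one member remains.
#' Ties at machine precision are broken toward the larger chi-square, then
#' toward removing the lexicographically smallest member. The procedure is
#' fully deterministic.
#'
#' @param cohort A [cohort_data] object.
#' @param sig A [signature_set] with >= 2 members.
#' @return An object of class `reduction_trajectory`: `table` (data.frame
#'   with `step`, `size`, `removed`, `chi_square`, `p_value`), `steps` (list
#'   of member vectors per step), `best_step` (0-based index of the minimum-p
#'   step; ties go to the larger set) and `best_members`.
#' @export
greedy_reduce <- function(cohort, sig) {
  stopifnot(inherits(cohort, "cohort_data"), inherits(sig, "signature_set"))
  if (length(sig$members) < 2L)
    stop_("reduction needs a signature with >= 2 members")
  centered <- centered_expression(cohort, sig$members)
  current <- rownames(centered)
  if (length(current) < 2L)
    stop_("fewer than 2 signature members are scoreable in the cohort")

  s0 <- strength_from_centered(centered, current, cohort$time, cohort$event)
  steps <- list(current)
  tab <- data.frame(step = 0L, size = length(current), removed = NA_character_,
                    chi_square = s0[["chi_square"]],
                    p_value = s0[["p_value"]], stringsAsFactors = FALSE)

  step <- 0L
  while (length(current) > 1L) {
    step <- step + 1L
    cand <- lapply(current, function(g) setdiff(current, g))
    stats_ <- vapply(cand, function(mem) {
      strength_from_centered(centered, mem, cohort$time, cohort$event)
    }, c(chi_square = 0, p_value = 0))
    # lowest p; ties -> larger chi-square -> lexicographically smallest
    # removed member (candidates are scanned in sorted-member order)
    ord <- order(stats_["p_value", ], -stats_["chi_square", ],
                 current, method = "radix")
    pick <- ord[1L]
    removed <- current[pick]
    current <- cand[[pick]]
    steps[[step + 1L]] <- current
    tab <- rbind(tab, data.frame(
      step = step, size = length(current), removed = removed,
      chi_square = unname(stats_["chi_square", pick]),
      p_value = unname(stats_["p_value", pick]), stringsAsFactors = FALSE))
  }
  rownames(tab) <- NULL
  best <- which(tab$p_value == min(tab$p_value))
  best <- best[which.max(tab$size[best])]   # ties -> larger set
  structure(list(table = tab, steps = steps, best_step = tab$step[best],
                 best_members = steps[[best]]),
            class = "reduction_trajectory")
}

#' @export
print.reduction_trajectory <- function(x, ...) {
  cat(sprintf("Greedy leave-one-out reduction: %d -> 1 members\n",
              x$table$size[1L]))
  cat(sprintf("  full signature: p = %.3g; best (size %d, step %d): p = %.3g\n",
              x$table$p_value[1L], length(x$best_members), x$best_step,
              min(x$table$p_value)))
  invisible(x)
}
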