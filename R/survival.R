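# Survival evaluation: Kaplan-Meier curves, two-group log-rank tests, Cox
# proportional-hazards fits (Efron tie handling) and the treatment-interaction
# test. Model fitting is delegated to the survival package behind this module
# surface; results are repackaged into the pipeline's own classes.

check_surv <- function(time, event) {
  time <- as.numeric(time); event <- as.numeric(event)
  if (length(time) == 0L) stop_("no survival records")
  if (length(event) != length(time))
    stop_("time and event lengths differ")
  if (anyNA(time) || any(!is.finite(time)) || any(time <= 0))
    stop_("survival time must be finite and strictly positive")
  if (anyNA(event) || !all(event %in% c(0, 1)))
    stop_("event indicator must be 0/1")
  list(time = time, event = as.integer(event))
}

#' Kaplan-Meier estimate of the survival function
#'
#' Product-limit estimator; at tied times events precede censorings, so a
#' subject censored at an event time is still counted in the risk set there.
#'
#' @param time Positive follow-up times (months).
#' @param event 0/1 event indicator (1 = death from disease).
#' @return An object of class `km_curve`: `table` (data.frame with `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`), `n`, `n_events`, and
#'   `surv_fn`, a right-continuous step function with `surv_fn(0) = 1`.
#' @export
kaplan_meier <- function(time, event) {
  d <- check_surv(time, event)
  fit <- survival::survfit(survival::Surv(d$time, d$event) ~ 1,
                           conf.type = "none")
  tab <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    survival = fit$surv)
  fn <- stats::stepfun(tab$time, c(1, tab$survival), right = FALSE)
  structure(list(table = tab, n = length(d$time), n_events = sum(d$event),
                 surv_fn = fn),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d\n", x$n, x$n_events))
  print(utils::head(x$table, 10L), ...)
  invisible(x)
}

#' @export
plot.km_curve <- function(x, xlab = "Time (months)",
                          ylab = "Survival probability", ...) {
  tt <- c(0, x$table$time)
  ss <- c(1, x$table$survival)
  graphics::plot(tt, ss, type = "s", ylim = c(0, 1), xlab = xlab,
                 ylab = ylab, ...)
  invisible(x)
}

#' Two-group log-rank (Mantel-Haenszel) test
#'
#' Observed vs expected events accumulated over the risk sets at each distinct
#' event time; 1-df chi-square, two-sided p. Invariant to swapping the group
#' labels.
#'
#' @param time,event As in [kaplan_meier()].
#' @param group Two-level grouping (factor, character or logical).
#' @return A list of class `logrank_result`: `observed` and `expected` (named
#'   per group), `variance`, `chi_square`, `df`, `p_value`, `n`.
#' @export
logrank_test <- function(time, event, group) {
  d <- check_surv(time, event)
  group <- as.factor(group)
  if (length(group) != length(d$time))
    stop_("group length does not match records")
  if (nlevels(droplevels(group)) != 2L)
    stop_("log-rank test needs exactly two non-empty groups; got %d",
          nlevels(droplevels(group)))
  if (sum(d$event) == 0L) stop_("no events; log-rank test undefined")
  group <- droplevels(group)
  sd_ <- survival::survdiff(survival::Surv(d$time, d$event) ~ group, rho = 0)
  obs <- setNames(as.numeric(sd_$obs), levels(group))
  expd <- setNames(as.numeric(sd_$exp), levels(group))
  v <- if (is.matrix(sd_$var)) sd_$var[1L, 1L] else sd_$var[1L]
  structure(list(observed = obs, expected = expd, variance = v,
                 chi_square = as.numeric(sd_$chisq), df = 1L,
                 p_value = pchisq(as.numeric(sd_$chisq), df = 1L,
                                  lower.tail = FALSE),
                 n = length(d$time)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat("Two-sided log-rank test\n")
  print(data.frame(group = names(x$observed), observed = x$observed,
                   expected = round(x$expected, 3), row.names = NULL))
  cat(sprintf("  chi-square = %.4g on %d df, p = %.4g\n",
              x$chi_square, x$df, x$p_value))
  invisible(x)
}

#' Fit a Cox proportional-hazards model
#'
#' All covariates are entered simultaneously; the partial likelihood is
#' maximized with the Efron tie correction. Wald tests and 95% confidence
#' intervals come from the inverse information.
#'
#' @param time,event As in [kaplan_meier()].
#' @param covariates Data.frame of numeric/binary covariate columns (one row
#'   per record). Factors are allowed and expanded to treatment contrasts.
#' @return An object of class `cox_fit`: `table` (term, coef, se, hr,
#'   ci_lower, ci_upper, z, p_value), `loglik` (null and final log partial
#'   likelihood), `n`, `n_events`, `converged`, `iter`.
#' @export
fit_cox <- function(time, event, covariates) {
  d <- check_surv(time, event)
  if (!is.data.frame(covariates) || ncol(covariates) == 0L)
    stop_("covariates must be a non-empty data.frame")
  if (nrow(covariates) != length(d$time))
    stop_("covariate rows do not match records")
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (anyNA(v)) stop_("covariate '%s' has missing values", nm)
    if (length(unique(v)) < 2L) stop_("covariate '%s' is constant", nm)
  }
  if (sum(d$event) < ncol(covariates) + 1L)
    stop_("too few events (%d) for %d covariate(s)",
          sum(d$event), ncol(covariates))
  dat <- cbind(data.frame(.time = d$time, .event = d$event), covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  inf_warn <- NULL
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 100)),
    warning = function(w) {
      if (grepl("infinite|did not converge|out of iterations",
                conditionMessage(w))) {
        inf_warn <<- conditionMessage(w)
        invokeRestart("muffleWarning")
      }
    })
  if (!is.null(inf_warn))
    stop_("Cox fit did not converge: %s", inf_warn)
  if (anyNA(stats::coef(fit)))
    stop_("Cox fit produced undefined coefficient(s) (collinear covariates?)")
  cf <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  z <- cf / se
  tab <- data.frame(term = names(cf), coef = unname(cf), se = se,
                    hr = exp(unname(cf)),
                    ci_lower = exp(unname(cf) - qnorm(0.975) * se),
                    ci_upper = exp(unname(cf) + qnorm(0.975) * se),
                    z = unname(z),
                    p_value = 2 * stats::pnorm(-abs(unname(z))),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, loglik = fit$loglik, n = fit$n,
                 n_events = fit$nevent, converged = TRUE, iter = fit$iter),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Cox proportional-hazards fit: n = %d, events = %d\n",
              x$n, x$n_events))
  tab <- x$table
  tab$hr_ci <- sprintf("%.*g (%.*g-%.*g)", digits, tab$hr, digits,
                       tab$ci_lower, digits, tab$ci_upper)
  print(data.frame(term = tab$term, coef = round(tab$coef, digits),
                   `HR (95% CI)` = tab$hr_ci,
                   p = signif(tab$p_value, 3), check.names = FALSE,
                   row.names = NULL))
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...) {
  setNames(object$table$coef, object$table$term)
}

#' Test whether a treatment modifies the prognostic effect of a signature
#'
#' Fits `score_high + treatment + score_high:treatment` (plus optional
#' adjusters) in a Cox model and reports the interaction row: its hazard
#' ratio, confidence interval and Wald p answer whether the signature's
#' prognostic value differs between treated and untreated patients.
#'
#' @param time,event As in [kaplan_meier()].
#' @param score_high Binary (0/1 or logical): signature-high group membership.
#' @param treatment Binary (0/1 or logical) treatment flag; must vary.
#' @param adjusters Optional data.frame of additional covariates.
#' @return A list of class `interaction_test`: `fit` (the full [fit_cox()]
#'   object) and `interaction` (its interaction row).
#' @export
test_interaction <- function(time, event, score_high, treatment,
                             adjusters = NULL) {
  score_high <- as.numeric(score_high)
  treatment <- as.numeric(treatment)
  if (length(unique(treatment)) < 2L) stop_("treatment does not vary")
  if (length(unique(score_high)) < 2L) stop_("score_high does not vary")
  if (!all(score_high %in% c(0, 1)) || !all(treatment %in% c(0, 1)))
    stop_("score_high and treatment must be binary 0/1")
  covs <- data.frame(score_high = score_high, treatment = treatment,
                     score_x_treatment = score_high * treatment)
  if (identical(covs$score_x_treatment, covs$score_high) ||
      identical(covs$score_x_treatment, covs$treatment))
    stop_("interaction term is collinear with a main effect")
  if (!is.null(adjusters)) covs <- cbind(covs, adjusters)
  fit <- fit_cox(time, event, covs)
  structure(list(fit = fit,
                 interaction = fit$table[fit$table$term == "score_x_treatment", ]),
            class = "interaction_test")
}

#' @export
print.interaction_test <- function(x, ...) {
  ir <- x$interaction
  cat(sprintf(
    "Signature x treatment interaction: HR = %.3g (%.3g-%.3g), Wald p = %.3g\n",
    ir$hr, ir$ci_lower, ir$ci_upper, ir$p_value))
  print(x$fit)
  invisible(x)
}
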