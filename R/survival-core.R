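# Survival primitives the pipeline composes. Kaplan-Meier, log-rank and Cox
# partial-likelihood maximisation are delegated to the survival package;
# this layer fixes the conventions used throughout (Efron ties, Wald
# p-values, matrix interface) and adds backward elimination and the
# likelihood-ratio comparison.

#' Kaplan-Meier estimate of the survival function
#'
#' @param time follow-up times (months).
#' @param event event indicators (1 = event).
#' @return data.frame `time`, `n_risk`, `n_event`, `surv` (step function
#'   values, starting from S(0) = 1).
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) > 0L, length(time) == length(event))
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = c(0, sf$time),
             n_risk = c(length(time), sf$n.risk),
             n_event = c(0, sf$n.event),
             surv = c(1, sf$surv))
}

#' Two-group log-rank test
#'
#' @param time,event follow-up times and event indicators.
#' @param group two-level grouping vector.
#' @return list `statistic` (1-df chi-square), `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  stopifnot(length(time) == length(event), length(time) == length(group))
  if (nlevels(droplevels(group)) < 2L) {
    stop("log-rank test needs two nonempty groups", call. = FALSE)
  }
  if (sum(event) == 0) return(list(statistic = 0, p = 1))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1L
  list(statistic = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

# Null-model partial log-likelihood (no covariates)
null_loglik <- function(time, event) {
  f <- survival::coxph(survival::Surv(time, event) ~ 1)
  as.numeric(f$loglik[1])
}

#' Cox proportional-hazards fit (matrix interface)
#'
#' Maximises the partial likelihood with the Efron tie approximation and
#' reports per-covariate coefficient, standard error, Wald p-value and
#' hazard ratio `exp(coef)`. A fit is flagged non-converged when the
#' iteration limit is hit or a coefficient diverges (monotone likelihood).
#'
#' @param time,event follow-up times and event indicators.
#' @param x covariate matrix with column names (0 columns allowed: the fit
#'   degenerates to the null model).
#' @return object of class `cox_fit`: `covariates`, `coef`, `se`, `wald_p`,
#'   `hr`, `loglik` (maximised partial log-likelihood), `loglik_null`, `n`,
#'   `n_event`, `converged`.
#' @export
cox_fit <- function(time, event, x) {
  x <- as.matrix(x)
  stopifnot(length(time) == length(event), nrow(x) == length(time) ||
              ncol(x) == 0L)
  if (ncol(x) == 0L) {
    ll0 <- null_loglik(time, event)
    return(structure(list(covariates = character(), coef = numeric(),
                          se = numeric(), wald_p = numeric(), hr = numeric(),
                          loglik = ll0, loglik_null = ll0, n = length(time),
                          n_event = sum(event), converged = TRUE),
                     class = "cox_fit"))
  }
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (any(apply(x, 2, function(v) max(v) == min(v)))) {
    stop("constant covariate supplied to cox_fit", call. = FALSE)
  }
  if (sum(event) < 1) stop("cox_fit requires at least one event",
                           call. = FALSE)
  ctrl <- survival::coxph.control()
  # monotone-likelihood warnings are expected in small fold fits and are
  # captured by the converged flag instead
  fit <- suppressWarnings(
    survival::coxph.fit(x, survival::Surv(time, event),
                        strata = NULL, offset = NULL, init = NULL,
                        control = ctrl, weights = NULL,
                        method = "efron", rownames = NULL))
  ll0 <- as.numeric(fit$loglik[1])   # partial loglik at beta = 0
  coef <- as.numeric(fit$coefficients)
  se <- sqrt(diag(as.matrix(fit$var)))
  converged <- all(is.finite(coef)) && all(is.finite(se)) &&
    fit$iter < ctrl$iter.max && max(abs(coef)) < 20
  wald_p <- 2 * stats::pnorm(-abs(coef / se))
  structure(list(covariates = colnames(x),
                 coef = stats::setNames(coef, colnames(x)),
                 se = stats::setNames(se, colnames(x)),
                 wald_p = stats::setNames(wald_p, colnames(x)),
                 hr = stats::setNames(exp(coef), colnames(x)),
                 loglik = as.numeric(fit$loglik[2]), loglik_null = ll0,
                 n = length(time), n_event = sum(event),
                 converged = converged),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox PH fit:", x$n, "subjects,", x$n_event, "events",
      if (!x$converged) "(NOT converged)" else "", "\n")
  if (length(x$coef)) {
    print(data.frame(coef = round(x$coef, 3), se = round(x$se, 3),
                     p = signif(x$wald_p, 3), hr = round(x$hr, 2)))
  } else cat("(null model)\n")
  invisible(x)
}

#' Backward elimination on Wald p-values
#'
#' Starting from the full covariate set, repeatedly refits the Cox model
#' after dropping the non-forced covariate with the largest Wald p-value
#' exceeding `alpha`, until every non-forced covariate is significant or
#' none remain. Forced covariates are never dropped.
#'
#' @param time,event follow-up times and event indicators.
#' @param x covariate matrix.
#' @param forced covariate names always retained.
#' @param alpha Wald p-value cutoff, default 0.05.
#' @return list `retained` (non-forced covariates surviving elimination),
#'   `fit` (final `cox_fit` on retained + forced), `converged`.
#' @export
backward_eliminate <- function(time, event, x, forced = character(),
                               alpha = 0.05) {
  x <- as.matrix(x)
  stopifnot(all(forced %in% colnames(x)))
  current <- colnames(x)
  converged <- TRUE
  repeat {
    fit <- cox_fit(time, event, x[, current, drop = FALSE])
    converged <- converged && fit$converged
    free <- setdiff(current, forced)
    if (!length(free)) break
    p_free <- fit$wald_p[free]
    worst <- names(p_free)[which.max(p_free)]
    if (max(p_free) <= alpha) break
    current <- setdiff(current, worst)
  }
  list(retained = setdiff(current, forced), fit = fit,
       converged = converged)
}

#' Likelihood-ratio test between nested Cox fits
#'
#' @param nested,full `cox_fit` objects on the same records; the nested
#'   covariates must be a subset of the full covariates.
#' @return list `statistic` (2 * loglik difference), `df`, `p`.
#' @export
likelihood_ratio_test <- function(nested, full) {
  stopifnot(inherits(nested, "cox_fit"), inherits(full, "cox_fit"))
  if (length(setdiff(nested$covariates, full$covariates)) ||
      nested$n != full$n || nested$n_event != full$n_event) {
    stop("models are not nested on the same records", call. = FALSE)
  }
  df <- length(full$covariates) - length(nested$covariates)
  stat <- max(0, 2 * (full$loglik - nested$loglik))
  p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}
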