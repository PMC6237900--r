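# Time-dependent ROC at a fixed survival horizon, with
# cumulative-case/dynamic-control definitions and Kaplan-Meier weighting
# (the Heagerty-Lumley-Pepe KM estimator). Cases at horizon t are subjects
# with an event by t; controls are subjects still event-free at t.

# Kaplan-Meier survival probability at a single time point (fast path used
# inside the ROC sweep and the bootstrap): product over event times u <= t
# of (1 - d(u)/r(u)), computed without per-time scans.
km_surv_at <- function(time, event, t) {
  sel <- time <= t & event == 1
  if (!any(sel)) return(1)
  te <- time[sel]
  dt <- sort(unique(te))
  d <- tabulate(match(te, dt), length(dt))
  st <- sort(time)
  n_le <- findInterval(dt, st)                      # time <= u
  n_eq <- tabulate(match(time, dt), length(dt))     # time == u (any status)
  r <- length(time) - n_le + n_eq                   # time >= u
  prod(1 - d / r)
}

#' Time-dependent ROC curve at a survival horizon
#'
#' Sensitivity and specificity at horizon `t` for the rule "marker > c
#' flags a case", with cumulative cases (event by `t`) and dynamic controls
#' (event-free at `t`). The joint probabilities are estimated with
#' Kaplan-Meier weighting: `P(X > c, T <= t) = (1 - S(t | X > c)) P(X > c)`
#' with `S` the KM estimator on the conditioning subset; sensitivity and
#' specificity follow by Bayes' rule. With no censoring before `t` this
#' reduces exactly to the empirical ROC, whose trapezoid AUC equals the
#' Mann-Whitney concordance between cases and controls. Under censoring the
#' raw estimator can be locally non-monotone; a running-minimum adjustment
#' on the two joint terms restores monotonicity (a no-op when there is no
#' censoring before `t`).
#'
#' @param marker numeric marker values (higher = higher risk).
#' @param time,event follow-up times and event indicators.
#' @param t horizon (months).
#' @return object of class `timedep_roc`: `cutoffs` (increasing, with
#'   -Inf sentinel), `sensitivity`, `specificity`, `auc`, `t`, `n_case_w`
#'   (KM-weighted case mass). If no cases have occurred by `t` the AUC is
#'   `NA` and the object is flagged `degenerate`.
#' @export
survival_roc <- function(marker, time, event, t) {
  stopifnot(length(marker) == length(time), length(time) == length(event))
  keep <- is.finite(marker)
  marker <- marker[keep]; time <- time[keep]; event <- event[keep]
  s_t <- km_surv_at(time, event, t)
  f_t <- 1 - s_t
  cuts <- c(-Inf, sort(unique(marker)))
  # joint terms: f(c) ~ P(X > c, T <= t), g(c) ~ P(X > c, T > t)
  f <- g <- numeric(length(cuts))
  for (i in seq_along(cuts)) {
    sel <- marker > cuts[i]
    p_sel <- mean(sel)
    if (!any(sel)) { f[i] <- 0; g[i] <- 0; next }
    s_c <- km_surv_at(time[sel], event[sel], t)
    f[i] <- (1 - s_c) * p_sel
    g[i] <- s_c * p_sel
  }
  f <- pmin(pmax(cummin(f), 0), f_t)
  g <- pmin(pmax(cummin(g), 0), s_t)
  degenerate <- f_t <= 0 || s_t <= 0
  if (degenerate) {
    sens <- rep(NA_real_, length(cuts)); spec <- sens; auc <- NA_real_
  } else {
    sens <- f / f_t
    spec <- 1 - g / s_t
    # trapezoid over the ROC curve traced in (1 - spec, sens)
    fpr <- 1 - spec
    auc <- sum((fpr[-length(fpr)] - fpr[-1]) *
                 (sens[-length(sens)] + sens[-1]) / 2)
  }
  structure(list(cutoffs = cuts, sensitivity = sens, specificity = spec,
                 auc = auc, t = t, n_case_w = f_t, degenerate = degenerate),
            class = "timedep_roc")
}

#' @export
print.timedep_roc <- function(x, ...) {
  cat("Time-dependent ROC at t =", x$t, ": AUC =",
      if (x$degenerate) "NA (no cases by horizon)" else
        format(x$auc, digits = 4), "\n")
  invisible(x)
}

#' Youden-optimal cutoff of a time-dependent ROC
#'
#' Returns the cutoff maximising sensitivity + specificity - 1; ties are
#' broken toward the smaller cutoff.
#'
#' @param roc a `timedep_roc` object.
#' @return list `cutoff`, `youden`, `sensitivity`, `specificity`.
#' @export
optimal_cutoff <- function(roc) {
  stopifnot(inherits(roc, "timedep_roc"))
  if (roc$degenerate) stop("ROC is degenerate (no cases by horizon)",
                           call. = FALSE)
  j <- roc$sensitivity + roc$specificity - 1
  i <- which(j == max(j))[1]   # cutoffs increasing, so first max = smallest
  list(cutoff = roc$cutoffs[i], youden = j[i],
       sensitivity = roc$sensitivity[i], specificity = roc$specificity[i])
}

#' BCa bootstrap confidence interval for the time-dependent AUC
#'
#' Resamples subjects with replacement, recomputes the horizon-`t` AUC on
#' each resample and forms a bias-corrected accelerated (BCa) interval via
#' the boot package. Resamples on which the AUC is undefined (no cases or
#' no controls by the horizon) are skipped and counted.
#'
#' @param marker,time,event marker values and survival records.
#' @param t horizon (months).
#' @param n_boot number of bootstrap resamples (>= 200).
#' @param level confidence level, default 0.95.
#' @param seed optional integer seed for the resampling.
#' @return list `auc` (point estimate), `lower`, `upper`, `level`,
#'   `n_boot_used`, `n_degenerate`.
#' @export
auc_bootstrap_ci <- function(marker, time, event, t, n_boot = 2000,
                             level = 0.95, seed = NULL) {
  stopifnot(n_boot >= 200)
  dat <- data.frame(marker = marker, time = time, event = event)
  stat <- function(d, idx) {
    r <- survival_roc(d$marker[idx], d$time[idx], d$event[idx], t)
    if (r$degenerate) NA_real_ else r$auc
  }
  obs <- stat(dat, seq_len(nrow(dat)))
  if (is.na(obs)) stop("AUC undefined on the observed data", call. = FALSE)
  run <- function() boot::boot(dat, stat, R = n_boot)
  b <- if (is.null(seed)) run() else with_seed(seed, run())
  ok <- !is.na(b$t[, 1])
  n_bad <- sum(!ok)
  reps <- b$t[ok, 1]
  if (length(unique(round(reps, 12))) == 1L) {
    # constant statistic across resamples: zero-width interval
    return(list(auc = obs, lower = reps[1], upper = reps[1], level = level,
                n_boot_used = length(reps), n_degenerate = n_bad))
  }
  ci <- tryCatch({
    if (n_bad > 0L) b$t <- b$t[ok, , drop = FALSE]
    b$R <- sum(ok)
    out <- boot::boot.ci(b, conf = level, type = "bca")
    c(out$bca[4], out$bca[5])
  }, error = function(e) {
    # fall back to the percentile interval on the usable replicates
    warning("BCa interval unavailable (", conditionMessage(e),
            "); using percentile interval")
    as.numeric(stats::quantile(reps, c((1 - level) / 2, (1 + level) / 2)))
  })
  list(auc = obs, lower = max(0, ci[1]), upper = min(1, ci[2]),
       level = level, n_boot_used = sum(ok), n_degenerate = n_bad)
}
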