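# Final module fitting, scoring and risk / treatment-benefit
# stratification.

#' Fit a prognosis or AT-selection module
#'
#' A single full-data Cox fit on the selected proteins (plus the forced
#' stage covariate for prognosis modules). The module score of a subject is
#' the linear predictor `sum(coef * covariate)` (no baseline term), and the
#' classification cutoff is the median of the training scores.
#'
#' @param time,event derived survival endpoint.
#' @param x covariate matrix holding at least the selected proteins (and a
#'   `stage` column when `force_stage`).
#' @param selection a `selection_result`, or a character vector of protein
#'   ids.
#' @param purpose `"prognosis"` or `"at_selection"` (bookkeeping).
#' @param panel `"MD"` or `"ND"` (bookkeeping).
#' @param force_stage include stage as a forced covariate, default TRUE for
#'   prognosis and FALSE otherwise.
#' @return object of class `module_model`: `panel`, `purpose`, `features`,
#'   `fit` (a `cox_fit`), `scores`, `median_cutoff`.
#' @export
fit_module <- function(time, event, x, selection,
                       purpose = c("prognosis", "at_selection"),
                       panel = "MD",
                       force_stage = NULL) {
  purpose <- match.arg(purpose)
  if (is.null(force_stage)) force_stage <- purpose == "prognosis"
  feats <- if (inherits(selection, "selection_result")) selection$selected
           else as.character(selection)
  covs <- c(if (force_stage) "stage", feats)
  if (!length(covs)) stop("empty module: no selected features and no stage",
                          call. = FALSE)
  x <- as.matrix(x)
  if (length(setdiff(covs, colnames(x)))) {
    stop("covariate matrix lacks: ",
         paste(setdiff(covs, colnames(x)), collapse = ", "), call. = FALSE)
  }
  fit <- cox_fit(time, event, x[, covs, drop = FALSE])
  if (!fit$converged) {
    stop("module Cox fit did not converge (", fit$n_event, " events, ",
         length(covs), " covariates)", call. = FALSE)
  }
  scores <- as.numeric(x[, covs, drop = FALSE] %*% fit$coef)
  structure(list(panel = panel, purpose = purpose, features = feats,
                 force_stage = force_stage, fit = fit,
                 scores = scores, median_cutoff = median(scores)),
            class = "module_model")
}

#' Score subjects with a fitted module
#'
#' @param module a `module_model`.
#' @param x covariate matrix with the module's covariates.
#' @return numeric linear-predictor scores.
#' @export
score_subjects <- function(module, x) {
  covs <- names(module$fit$coef)
  x <- as.matrix(x)
  as.numeric(x[, covs, drop = FALSE] %*% module$fit$coef)
}

#' @export
print.module_model <- function(x, ...) {
  cat("SEPROGADIC", x$purpose, "module,", x$panel, "panel:",
      length(x$features), "protein(s)",
      if (x$force_stage) "+ forced stage", "\n")
  print(x$fit)
  cat("median score cutoff:", format(x$median_cutoff, digits = 4), "\n")
  invisible(x)
}

# KM/log-rank/HR evaluation of a two-group split on one stratum
eval_split <- function(time, event, high) {
  n_low <- sum(!high); n_high <- sum(high)
  out <- list(n_low = n_low, n_high = n_high,
              events_low = sum(event[!high]), events_high = sum(event[high]),
              hr_low_vs_high = NA_real_, logrank_p = NA_real_)
  if (n_low == 0L || n_high == 0L || sum(event) == 0) return(out)
  lr <- logrank_test(time, event, high)
  out$logrank_p <- lr$p
  xm <- matrix(as.numeric(!high), ncol = 1,
               dimnames = list(NULL, "low_risk"))
  fit <- tryCatch(cox_fit(time, event, xm), error = function(e) NULL)
  if (!is.null(fit)) out$hr_low_vs_high <- unname(fit$hr["low_risk"])
  out
}

#' Stratify patients by a module score and evaluate the split
#'
#' Prognosis modules: the median score splits the cohort into low
#' (score <= cutoff) and high risk; the split is evaluated overall and per
#' TNM stage with log-rank p, hazard ratio (low vs high), and the
#' horizon-`t` AUC / sensitivity / specificity of the score. AT-selection
#' modules additionally cross the median split with the actual treatment
#' arm into tCCRT (CCRT, score below cutoff), fCCRT (CCRT, at/above),
#' fCTX (CTX, below) and tCTX (CTX, at/above).
#'
#' @param module a `module_model`.
#' @param clinical clinical table (provides `stage`, `arm`).
#' @param time,event survival endpoint to evaluate on (typically the
#'   PM-derived time/event).
#' @param scores module scores; defaults to the training scores.
#' @param horizon evaluation horizon (months), default 72.
#' @return list `assignment` (per patient: score, risk_group and, for AT
#'   modules, treatment_group), `overall`, `by_stage`, `auc`, `roc_cutoff`
#'   (sensitivity/specificity of the median cutoff), `degenerate`.
#' @export
stratify <- function(module, clinical, time, event, scores = NULL,
                     horizon = 72) {
  stopifnot(inherits(module, "module_model"))
  if (is.null(scores)) scores <- module$scores
  stopifnot(length(scores) == nrow(clinical), length(time) == length(scores))
  cutoff <- module$median_cutoff
  if (stats::sd(scores) == 0) {
    warning("all module scores identical; split is degenerate")
    degenerate <- TRUE
  } else degenerate <- FALSE
  high <- scores > cutoff
  assignment <- data.frame(patient_id = clinical$patient_id,
                           score = scores,
                           risk_group = ifelse(high, "high", "low"),
                           stringsAsFactors = FALSE)
  if (module$purpose == "at_selection") {
    ccrt <- clinical$arm == "CCRT"
    assignment$treatment_group <- ifelse(
      ccrt, ifelse(!high, "tCCRT", "fCCRT"),
      ifelse(!high, "fCTX", "tCTX"))
  }
  overall <- eval_split(time, event, high)
  by_stage <- lapply(split(seq_along(scores), clinical$stage), function(i) {
    eval_split(time[i], event[i], high[i])
  })
  roc <- survival_roc(scores, time, event, horizon)
  cut_stats <- if (!roc$degenerate) {
    i <- max(which(roc$cutoffs <= cutoff))
    list(sensitivity = roc$sensitivity[i], specificity = roc$specificity[i])
  } else list(sensitivity = NA_real_, specificity = NA_real_)
  list(assignment = assignment, overall = overall, by_stage = by_stage,
       auc = roc$auc, roc_cutoff = cut_stats, degenerate = degenerate)
}
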