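# End-to-end orchestration: QC -> normalization -> univariate screen ->
# endpoints -> stability selection -> module fit -> stratification.

# log2 beta-corrected abundance per (sample, protein), replicate runs
# averaged; columns standardized to zero mean / unit sd so Cox
# coefficients are per-SD of log2 abundance.
protein_matrix <- function(corrected, clinical, proteins, representative,
                           standardize = TRUE) {
  rep_map <- stats::setNames(representative$peptide_id,
                             representative$protein_id)
  proteins <- intersect(proteins, names(rep_map))
  d <- corrected[!corrected$is_qc &
                   corrected$peptide_id %in% rep_map[proteins], ,
                 drop = FALSE]
  d$log_ab <- log2(pmax(d$corrected_area, .Machine$double.xmin))
  m <- matrix(NA_real_, nrow(clinical), length(proteins),
              dimnames = list(clinical$patient_id, proteins))
  agg <- tapply(d$log_ab, list(d$sample_id, d$protein_id), mean)
  m[] <- agg[clinical$patient_id, proteins]
  if (anyNA(m)) stop("missing protein measurements for some patients",
                     call. = FALSE)
  if (standardize) m <- scale(m)[, , drop = FALSE]
  m
}

# Per-protein univariate time-dependent ROC screen at the horizon
univariate_screen <- function(x, time, event, horizon) {
  out <- lapply(colnames(x), function(p) {
    roc <- survival_roc(x[, p], time, event, horizon)
    if (roc$degenerate) {
      return(data.frame(protein = p, auc = NA_real_, cutoff = NA_real_,
                        logrank_p = NA_real_, stringsAsFactors = FALSE))
    }
    # orient the marker so that higher values mean higher risk
    flipped <- roc$auc < 0.5
    marker <- if (flipped) -x[, p] else x[, p]
    roc2 <- if (flipped) survival_roc(marker, time, event, horizon) else roc
    oc <- optimal_cutoff(roc2)
    lr <- if (length(unique(marker > oc$cutoff)) == 2L) {
      logrank_test(time, event, marker > oc$cutoff)
    } else list(p = NA_real_)
    data.frame(protein = p, auc = roc2$auc,
               cutoff = if (flipped) -oc$cutoff else oc$cutoff,
               logrank_p = lr$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Run the full analysis pipeline on a cohort
#'
#' Composes the whole workflow: replicate-CV quality control, representative
#' peptide selection, normalizing-peptide screening, NSF computation,
#' ionization-exponent estimation and beta correction, the univariate
#' time-dependent ROC screen, endpoint construction, cross-validated Cox
#' stability selection, module fitting and median-split stratification, and
#' a likelihood-ratio comparison of the prognosis module against the
#' stage-only model.
#'
#' @param cohort a `synthetic_cohort`, or `NULL` if `quant`/`clinical` and
#'   the NP/spike identities are given explicitly.
#' @param quant,clinical tables (ignored when `cohort` is given).
#' @param np_candidates,spike_protein protein ids of the normalizing
#'   candidates and the spiked control (taken from the cohort truth when a
#'   cohort is given).
#' @param panel which quantification panel to model, `"MD"` or `"ND"`.
#' @param cv_threshold,max_violations replicate-CV filter parameters.
#' @param horizon endpoint horizon in months, default 72.
#' @param selection a [selection_config()]; `force_stage` applies to the
#'   prognosis module, while the AT module never forces stage.
#' @param run_univariate run the per-protein univariate screen (default
#'   TRUE).
#' @param out_dir optional directory; key outputs are written as TSV with a
#'   provenance header.
#' @return a list: `qc_report`, `representative`, `np_screen`,
#'   `normalization` (model), `univariate`, `endpoints`, `x` (covariate
#'   matrix incl. stage), `pm` and `at` (each: `selection`, `module`,
#'   `stratification`), `stage_only` (fit, auc, lrt vs PM module).
#' @export
run_pipeline <- function(cohort = NULL, quant = NULL, clinical = NULL,
                         np_candidates = NULL, spike_protein = NULL,
                         panel = c("ND", "MD"),
                         cv_threshold = 0.25, max_violations = 5L,
                         horizon = 72,
                         selection = selection_config(),
                         run_univariate = TRUE,
                         out_dir = NULL) {
  panel <- match.arg(panel)
  if (!is.null(cohort)) {
    stopifnot(inherits(cohort, "synthetic_cohort"))
    quant <- cohort$quant
    clinical <- cohort$clinical
    np_candidates <- cohort$truth$np_candidates
    spike_protein <- cohort$truth$spike_protein
  }
  stopifnot(!is.null(quant), !is.null(clinical),
            !is.null(np_candidates), !is.null(spike_protein))

  stage_fail <- function(stage, e) {
    stop("pipeline stage [", stage, "] failed: ", conditionMessage(e),
         call. = FALSE)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) stage_fail(stage, e))
  }

  qc <- run_stage("qc", compute_replicate_cv(quant, cv_threshold))
  qc_report <- run_stage("qc", filter_peptides(qc, max_violations))
  rep_sel <- run_stage("representative",
                       select_representative_peptide(quant, qc_report))
  np_screen <- run_stage("np_screen",
                         screen_np_candidates(quant, clinical,
                                              np_candidates, spike_protein,
                                              horizon = horizon))
  norm_model <- run_stage("normalize", {
    m <- compute_nsf(quant, np_screen$selected)
    suppressWarnings(estimate_beta(quant, m))
  })
  corrected <- run_stage("normalize", beta_correct(quant, norm_model))

  panel_proteins <- sort(unique(quant$protein_id[quant$panel == panel]))
  panel_proteins <- setdiff(panel_proteins, c(np_candidates, spike_protein))
  xp <- run_stage("protein_matrix",
                  protein_matrix(corrected, clinical, panel_proteins,
                                 rep_sel$representative))

  endpoints <- run_stage("endpoints", {
    pm <- assign_pm_endpoints(clinical, horizon)
    assign_at_endpoints(pm, clinical, horizon)
  })
  x <- cbind(stage = as.integer(clinical$stage), xp)

  univariate <- if (run_univariate) {
    run_stage("univariate",
              univariate_screen(xp, endpoints$derived_time,
                                endpoints$derived_event, horizon))
  } else NULL

  pm_cfg <- selection
  pm_sel <- run_stage("pm_selection",
                      run_selection(endpoints$derived_time,
                                    endpoints$derived_event, x, pm_cfg))
  pm_mod <- run_stage("pm_module",
                      fit_module(endpoints$derived_time,
                                 endpoints$derived_event, x, pm_sel,
                                 purpose = "prognosis", panel = panel,
                                 force_stage = pm_cfg$force_stage))
  pm_strat <- run_stage("pm_stratify",
                        stratify(pm_mod, clinical, endpoints$derived_time,
                                 endpoints$derived_event, horizon = horizon))

  at_cfg <- selection
  at_cfg$force_stage <- FALSE
  at_sel <- run_stage("at_selection",
                      run_selection(endpoints$at_time, endpoints$at_event,
                                    x, at_cfg))
  at <- if (length(at_sel$selected)) {
    at_mod <- run_stage("at_module",
                        fit_module(endpoints$at_time, endpoints$at_event,
                                   x, at_sel, purpose = "at_selection",
                                   panel = panel, force_stage = FALSE))
    at_strat <- run_stage("at_stratify",
                          stratify(at_mod, clinical,
                                   endpoints$derived_time,
                                   endpoints$derived_event,
                                   horizon = horizon))
    list(selection = at_sel, module = at_mod, stratification = at_strat)
  } else list(selection = at_sel, module = NULL, stratification = NULL)

  stage_only <- run_stage("stage_only", {
    fit <- cox_fit(endpoints$derived_time, endpoints$derived_event,
                   x[, "stage", drop = FALSE])
    scores <- as.numeric(x[, "stage", drop = FALSE] %*% fit$coef)
    roc <- survival_roc(scores, endpoints$derived_time,
                        endpoints$derived_event, horizon)
    list(fit = fit, auc = roc$auc,
         lrt_vs_pm = if (pm_mod$force_stage)
           likelihood_ratio_test(fit, pm_mod$fit) else NULL)
  })

  result <- list(qc_report = qc_report, representative = rep_sel,
                 np_screen = np_screen, normalization = norm_model,
                 univariate = univariate, endpoints = endpoints, x = x,
                 pm = list(selection = pm_sel, module = pm_mod,
                           stratification = pm_strat),
                 at = at, stage_only = stage_only,
                 panel = panel, horizon = horizon,
                 selection_config = selection)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

# TSV outputs with a provenance header line
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  header <- sprintf(
    "# seprogadic %s | panel=%s horizon=%g | folds=%d iterations=%d seed=%d",
    as.character(utils::packageVersion("seprogadic")),
    result$panel, result$horizon, result$selection_config$n_folds,
    result$selection_config$n_iterations, result$selection_config$seed)
  emit <- function(df, file) {
    path <- file.path(out_dir, file)
    con <- file(path, "w")
    writeLines(header, con)
    utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
    close(con)
  }
  emit(result$qc_report, "qc_report.tsv")
  emit(result$np_screen$candidates, "np_screen.tsv")
  emit(result$normalization$nsf, "nsf.tsv")
  emit(data.frame(peptide_id = names(result$normalization$beta),
                  beta = as.numeric(result$normalization$beta)),
       "beta.tsv")
  if (!is.null(result$univariate)) emit(result$univariate, "univariate.tsv")
  emit(result$pm$selection$ranking, "pm_selection.tsv")
  fit <- result$pm$module$fit
  emit(data.frame(id = fit$covariates, coef = fit$coef, se = fit$se,
                  p = fit$wald_p, hr = fit$hr), "pm_module.tsv")
  emit(result$pm$stratification$assignment, "pm_assignment.tsv")
  if (!is.null(result$at$module)) {
    atfit <- result$at$module$fit
    emit(data.frame(id = atfit$covariates, coef = atfit$coef, se = atfit$se,
                    p = atfit$wald_p), "at_module.tsv")
    emit(result$at$stratification$assignment, "at_assignment.tsv")
  }
  invisible(out_dir)
}
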