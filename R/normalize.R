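# Normalization of raw MRM peak areas with endogenous reference proteins:
# candidate screening, per-run scaling factors (NSF), per-peptide ionization
# exponents (beta) from pooled QC runs, and beta-corrected abundances.

# A "run" is one LC injection: (sample_id, replicate_index). NSFs are
# computed per run, since instrument drift acts on injections.
run_key <- function(sample_id, replicate_index) {
  paste0(sample_id, "::r", replicate_index)
}

# Three-level prognostic outcome grouping used by the NP screen
outcome_group <- function(clinical, horizon = 72) {
  ifelse(clinical$event == 1L & clinical$dfs_months <= horizon, "recurred",
         ifelse(clinical$dfs_months < horizon, "censored", "no_recurrence"))
}

# Variance-decomposition stability score on the log2 scale (NormFinder
# style): pooled within-group variance plus mean squared deviation of the
# group means from the grand mean; lower is more stable.
np_stability <- function(log_area, group) {
  m <- mean(log_area)
  gs <- split(log_area, group)
  n <- length(log_area)
  between <- sum(vapply(gs, function(x) length(x) * (mean(x) - m)^2,
                        numeric(1))) / n
  within <- sum(vapply(gs, function(x) {
    if (length(x) > 1L) (length(x) - 1L) * stats::var(x) else 0
  }, numeric(1))) / n
  sqrt(between + within)
}

#' Screen endogenous normalizing-peptide candidates
#'
#' Applies the four screening criteria to each candidate: (1) detected
#' (positive peak area) in every clinical run; (2) raw levels not
#' significantly different among the three prognostic outcome groups
#' (recurred within the horizon / censored earlier / no recurrence), one-way
#' ANOVA on log2 areas with p > 0.05; (3) Pearson correlation > 0.5 with
#' the spiked exogenous control across clinical runs; (4) survivors ranked
#' ascending by a variance-decomposition stability score, and the top
#' `n_select` returned as the selected normalizers.
#'
#' @param quant quant table.
#' @param clinical clinical table.
#' @param np_candidates protein ids of the normalizing candidates.
#' @param spike_protein protein id of the spiked exogenous control.
#' @param horizon outcome horizon in months (default 72).
#' @param n_select number of normalizers to select (default 5).
#' @return list with `candidates` (one row per candidate: detection flag,
#'   ANOVA p, Pearson r, stability, passes) and `selected` (peptide ids of
#'   the chosen normalizers, best stability first).
#' @export
screen_np_candidates <- function(quant, clinical, np_candidates,
                                 spike_protein, horizon = 72,
                                 n_select = 5L) {
  validate_quant(quant)
  clin_q <- quant[!quant$is_qc, , drop = FALSE]
  runs <- unique(run_key(clin_q$sample_id, clin_q$replicate_index))
  grp_of <- stats::setNames(outcome_group(clinical, horizon),
                            clinical$patient_id)

  area_by_run <- function(protein) {
    d <- clin_q[clin_q$protein_id == protein, , drop = FALSE]
    stats::setNames(d$raw_peak_area, run_key(d$sample_id, d$replicate_index))
  }
  spike_area <- area_by_run(spike_protein)
  if (!length(spike_area)) {
    stop("spike protein ", spike_protein, " not found in quant table",
         call. = FALSE)
  }

  rows <- lapply(np_candidates, function(p) {
    d <- clin_q[clin_q$protein_id == p, , drop = FALSE]
    pep <- if (nrow(d)) d$peptide_id[1] else NA_character_
    a <- stats::setNames(d$raw_peak_area,
                         run_key(d$sample_id, d$replicate_index))
    detected <- length(a) == length(runs) && all(a > 0)
    anova_p <- pearson_r <- stability <- NA_real_
    if (nrow(d)) {
      g <- factor(grp_of[d$sample_id])
      la <- log2(pmax(d$raw_peak_area, .Machine$double.xmin))
      if (nlevels(droplevels(g)) >= 2L) {
        anova_p <- stats::anova(stats::lm(la ~ g))[["Pr(>F)"]][1]
      }
      common <- intersect(names(a), names(spike_area))
      if (length(common) >= 3L && stats::sd(a[common]) > 0 &&
          stats::sd(spike_area[common]) > 0) {
        pearson_r <- stats::cor(a[common], spike_area[common])
      }
      stability <- np_stability(la, g)
    }
    data.frame(protein_id = p, peptide_id = pep, detected_in_all = detected,
               anova_p = anova_p, pearson_r = pearson_r,
               stability = stability, stringsAsFactors = FALSE)
  })
  cand <- do.call(rbind, rows)
  cand$passes <- cand$detected_in_all &
    !is.na(cand$anova_p) & cand$anova_p > 0.05 &
    !is.na(cand$pearson_r) & cand$pearson_r > 0.5
  cand <- cand[order(cand$stability), , drop = FALSE]
  rownames(cand) <- NULL
  surv <- cand[cand$passes, , drop = FALSE]
  if (nrow(surv) < n_select) {
    stop(nrow(surv), " candidate(s) pass the screen but ", n_select,
         " normalizers are required; relax the screening thresholds or ",
         "monitor more candidates", call. = FALSE)
  }
  list(candidates = cand, selected = surv$peptide_id[seq_len(n_select)])
}

#' Normalization scaling factors from selected normalizing peptides
#'
#' For each normalizing peptide i, its raw area in run s is divided by the
#' across-sample median of that peptide (clinical runs); the per-run NSF is
#' the median of the resulting ratios:
#' `NSF_s = median(N_{1,s}/Nhat_1, ..., N_{k,s}/Nhat_k)`. By construction
#' the median over clinical runs of each ratio is exactly 1. QC runs get
#' NSFs from the same medians so the ionization exponents can be fit on
#' them.
#'
#' @param quant quant table.
#' @param nps peptide ids of the selected normalizers.
#' @return a `normalization_model`: list with `selected_nps`,
#'   `peptide_medians` (Nhat per normalizer), `nsf` (data.frame sample_id,
#'   replicate_index, batch_id, is_qc, nsf) and empty `beta`.
#' @export
compute_nsf <- function(quant, nps) {
  validate_quant(quant)
  np_q <- quant[quant$peptide_id %in% nps, , drop = FALSE]
  if (length(setdiff(nps, np_q$peptide_id))) {
    stop("normalizing peptide(s) absent from quant table: ",
         paste(setdiff(nps, np_q$peptide_id), collapse = ", "),
         call. = FALSE)
  }
  runs <- unique(quant[, c("sample_id", "replicate_index", "batch_id",
                           "is_qc")])
  rownames(runs) <- NULL
  np_q$run <- run_key(np_q$sample_id, np_q$replicate_index)
  n_runs_per_np <- table(np_q$peptide_id)
  if (any(n_runs_per_np < nrow(runs))) {
    stop("missing normalizing-peptide measurement in at least one run; ",
         "no imputation is performed", call. = FALSE)
  }
  clin <- np_q[!np_q$is_qc, , drop = FALSE]
  nhat <- tapply(clin$raw_peak_area, clin$peptide_id, median)[nps]
  ratio <- np_q$raw_peak_area / nhat[np_q$peptide_id]
  nsf <- tapply(ratio, np_q$run, median)
  runs$nsf <- as.numeric(nsf[run_key(runs$sample_id, runs$replicate_index)])
  structure(list(selected_nps = nps,
                 peptide_medians = stats::setNames(as.numeric(nhat), nps),
                 nsf = runs,
                 beta = NULL),
            class = "normalization_model")
}

# NSF lookup aligned with a quant table's rows
nsf_for <- function(quant, model) {
  key <- run_key(model$nsf$sample_id, model$nsf$replicate_index)
  v <- stats::setNames(model$nsf$nsf, key)
  out <- v[run_key(quant$sample_id, quant$replicate_index)]
  if (anyNA(out)) stop("NSF unavailable for some runs", call. = FALSE)
  as.numeric(out)
}

#' Divide raw peak areas by the per-run NSF
#'
#' @param quant quant table.
#' @param model a `normalization_model` from [compute_nsf()].
#' @return the quant table with a `normalized_area` column added.
#' @export
normalize_quant <- function(quant, model) {
  validate_quant(quant)
  quant$normalized_area <- quant$raw_peak_area / nsf_for(quant, model)
  quant
}

#' Estimate per-peptide ionization response exponents from QC runs
#'
#' The pooled QC sample has identical content in every batch, so any
#' systematic area change across QC runs reflects instrumental response.
#' For peptide j, beta_j is the ordinary-least-squares slope of
#' log2(peak area) on log2(NSF) over the QC runs; it is expected close
#' to 1, and estimates are clamped to `clamp` (with a warning) to guard
#' against degenerate fits on few points. If all QC NSFs coincide the slope
#' is undefined and beta = 1 is used with a warning.
#'
#' @param quant quant table (QC runs are taken from it).
#' @param model a `normalization_model` holding per-run NSFs.
#' @param clamp admissible beta interval, default `c(0.5, 2)`.
#' @return the model with `beta` filled (named vector per peptide).
#' @export
estimate_beta <- function(quant, model, clamp = c(0.5, 2)) {
  validate_quant(quant)
  qc <- quant[quant$is_qc, , drop = FALSE]
  if (!nrow(qc)) stop("no QC runs in quant table", call. = FALSE)
  lnsf <- log2(nsf_for(qc, model))
  peptides <- unique(qc$peptide_id)
  denom_by_pep <- tapply(lnsf, qc$peptide_id, stats::var)
  beta <- vapply(peptides, function(p) {
    i <- qc$peptide_id == p
    x <- lnsf[i]
    if (length(x) < 2L || !is.finite(denom_by_pep[[p]]) ||
        denom_by_pep[[p]] == 0) {
      return(NA_real_)
    }
    y <- log2(pmax(qc$raw_peak_area[i], .Machine$double.xmin))
    stats::cov(x, y) / stats::var(x)
  }, numeric(1))
  if (anyNA(beta)) {
    warning("QC NSFs carry no variation for ", sum(is.na(beta)),
            " peptide(s); falling back to beta = 1")
    beta[is.na(beta)] <- 1
  }
  out <- pmin(pmax(beta, clamp[1]), clamp[2])
  n_clamped <- sum(abs(out - beta) > 1e-9)
  if (n_clamped > 0L) {
    warning(n_clamped, " beta estimate(s) outside [", clamp[1], ", ",
            clamp[2], "] were clamped")
  }
  model$beta <- stats::setNames(as.numeric(out), peptides)
  model
}

#' Beta-corrected normalized peak areas
#'
#' Corrects each transition by the per-peptide ionization response:
#' `corrected = raw_peak_area / NSF^beta`. At beta = 1 this reduces to
#' plain NSF normalization, and it inverts the log-log slope relation the
#' exponents are estimated from.
#'
#' @param quant quant table.
#' @param model a `normalization_model` with `beta` filled
#'   (see [estimate_beta()]).
#' @return the quant table with a `corrected_area` column added.
#' @export
beta_correct <- function(quant, model) {
  validate_quant(quant)
  if (is.null(model$beta)) {
    stop("model carries no beta estimates; run estimate_beta() first",
         call. = FALSE)
  }
  nsf <- nsf_for(quant, model)
  if (any(nsf <= 0)) stop("NSF must be positive", call. = FALSE)
  beta <- model$beta[quant$peptide_id]
  beta[is.na(beta)] <- 1
  quant$corrected_area <- quant$raw_peak_area / nsf^as.numeric(beta)
  quant
}

#' @export
print.normalization_model <- function(x, ...) {
  cat("Normalization model:", length(x$selected_nps), "normalizing peptides;",
      nrow(x$nsf), "runs\n")
  cat("NSF range:", format(range(x$nsf$nsf), digits = 4), "\n")
  if (!is.null(x$beta)) {
    cat("beta estimated for", length(x$beta), "peptides, range",
        format(range(x$beta), digits = 4), "\n")
  }
  invisible(x)
}
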