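#' Simulation configuration for a synthetic MRM serum cohort
#'
#' Builds and validates the parameter set that defines a synthetic study
#' cohort: patient mix, batch layout, protein panels, normalization-peptide
#' candidates, ground-truth hazard effects and the noise model of the
#' measurement process. Defaults emulate a 227-patient gastric-cancer serum
#' study measured in 10 analytical batches with one pooled QC run per batch
#' and two triplicated samples per batch.
#'
#' @param n_patients number of patients in the cohort.
#' @param n_batches number of analytical batches; each batch carries one
#'   pooled QC run and two randomly chosen triplicated clinical samples.
#' @param stage_probs probabilities of TNM stages 1b, 2, 3, 4 (sums to 1).
#' @param arm_probs probabilities of adjuvant arms CTX and CCRT (sums to 1).
#' @param n_md_proteins,n_nd_proteins number of representative proteins in
#'   the depleted (MD) and non-depleted (ND) quantification panels.
#' @param n_np_candidates number of endogenous normalizing-peptide
#'   candidates monitored alongside the panels.
#' @param n_np_unstable how many NP candidates carry an outcome-group
#'   dependent mean shift (these should fail the ANOVA screen).
#' @param n_true_prognostic number of proteins with a genuine log-hazard
#'   effect; planted alternately into the MD and ND panels.
#' @param effect_sizes log-hazard coefficients of the true proteins, per
#'   standard deviation of log2 biological abundance.
#' @param stage_coef log-hazard increment per TNM stage step (1b -> 2 -> ...).
#' @param baseline_hazard baseline event rate, events per month, for a
#'   stage-1b patient with average protein levels.
#' @param censor_frac fraction of patients given a uniform random censoring
#'   time on (0, `admin_censor_months`].
#' @param admin_censor_months administrative follow-up horizon in months.
#' @param batch_drift_sd sd (log2 scale) of the batch-level instrumental
#'   response shift; per-run drift within a batch uses half this sd.
#' @param beta_range interval the per-peptide ionization response exponents
#'   are drawn from.
#' @param technical_cv coefficient of variation of the multiplicative
#'   technical (injection-to-injection) noise.
#' @param biological_sd sd (log2 scale) of between-patient biological
#'   abundance variation of panel proteins.
#' @param np_group_shift log2 mean shift per outcome-group step applied to
#'   the unstable NP candidates.
#' @param spike_area constant biological peak area of the spiked exogenous
#'   control protein.
#' @param seed integer seed driving every random draw of the generator.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_patients = 227L,
                       n_batches = 10L,
                       stage_probs = c(0.2555, 0.3877, 0.2687, 0.0881),
                       arm_probs = c(CTX = 107, CCRT = 120) / 227,
                       n_md_proteins = 73L,
                       n_nd_proteins = 20L,
                       n_np_candidates = 15L,
                       n_np_unstable = 3L,
                       n_true_prognostic = 4L,
                       effect_sizes = c(0.8, 0.8, 0.7, 0.7),
                       stage_coef = 0.6,
                       baseline_hazard = 0.0007,
                       censor_frac = 0.42,
                       admin_censor_months = 72,
                       batch_drift_sd = 0.15,
                       beta_range = c(0.8, 1.2),
                       technical_cv = 0.07,
                       biological_sd = 0.5,
                       np_group_shift = 0.3,
                       spike_area = 5e5,
                       seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients), n_batches = as.integer(n_batches),
    stage_probs = stage_probs, arm_probs = arm_probs,
    n_md_proteins = as.integer(n_md_proteins),
    n_nd_proteins = as.integer(n_nd_proteins),
    n_np_candidates = as.integer(n_np_candidates),
    n_np_unstable = as.integer(n_np_unstable),
    n_true_prognostic = as.integer(n_true_prognostic),
    effect_sizes = effect_sizes, stage_coef = stage_coef,
    baseline_hazard = baseline_hazard, censor_frac = censor_frac,
    admin_censor_months = admin_censor_months,
    batch_drift_sd = batch_drift_sd, beta_range = beta_range,
    technical_cv = technical_cv, biological_sd = biological_sd,
    np_group_shift = np_group_shift, spike_area = spike_area,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 1L, cfg$n_batches >= 1L)
  if (length(cfg$stage_probs) != 4L || abs(sum(cfg$stage_probs) - 1) > 1e-8 ||
      any(cfg$stage_probs < 0)) {
    stop("`stage_probs` must be a nonnegative 4-vector summing to 1",
         call. = FALSE)
  }
  if (length(cfg$arm_probs) != 2L || abs(sum(cfg$arm_probs) - 1) > 1e-8 ||
      any(cfg$arm_probs < 0)) {
    stop("`arm_probs` must be a nonnegative 2-vector summing to 1",
         call. = FALSE)
  }
  if (cfg$n_true_prognostic > cfg$n_md_proteins + cfg$n_nd_proteins) {
    stop("more true prognostic proteins than panel proteins", call. = FALSE)
  }
  if (length(cfg$effect_sizes) != cfg$n_true_prognostic) {
    stop("`effect_sizes` must have length `n_true_prognostic`", call. = FALSE)
  }
  stopifnot(
    cfg$baseline_hazard > 0, cfg$admin_censor_months > 0,
    cfg$censor_frac >= 0, cfg$censor_frac <= 1,
    cfg$batch_drift_sd >= 0, cfg$technical_cv >= 0, cfg$biological_sd >= 0,
    cfg$n_np_unstable <= cfg$n_np_candidates,
    length(cfg$beta_range) == 2L, cfg$beta_range[1] <= cfg$beta_range[2],
    cfg$spike_area > 0
  )
  invisible(cfg)
}

# Protein/peptide naming used throughout the generator. True prognostic
# proteins are interleaved across panels so both support recovery tests.
sim_panel_layout <- function(cfg) {
  md <- sprintf("MD%03d", seq_len(cfg$n_md_proteins))
  nd <- sprintf("ND%03d", seq_len(cfg$n_nd_proteins))
  np <- sprintf("NP%02d", seq_len(cfg$n_np_candidates))
  spike <- "SPIKE_BGAL"
  truth_ids <- character(cfg$n_true_prognostic)
  i_md <- 0L; i_nd <- 0L
  for (k in seq_len(cfg$n_true_prognostic)) {
    if ((k %% 2L == 1L && i_md < cfg$n_md_proteins) || i_nd >= cfg$n_nd_proteins) {
      i_md <- i_md + 1L
      truth_ids[k] <- md[i_md]
    } else {
      i_nd <- i_nd + 1L
      truth_ids[k] <- nd[i_nd]
    }
  }
  list(md = md, nd = nd, np = np, spike = spike, true_proteins = truth_ids)
}
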