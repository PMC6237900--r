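#' @importFrom stats rexp rnorm runif rbinom median sd quantile
NULL

# Run a block of code with its own RNG stream, restoring the caller's
# .Random.seed afterwards so simulation calls do not disturb user RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Core biological + outcome draws shared by generate_clinical() and
# generate_quant(); both re-derive the identical state from config$seed so
# the two tables are always mutually consistent.
sim_core <- function(cfg) {
  layout <- sim_panel_layout(cfg)
  proteins <- c(layout$md, layout$nd)
  with_seed(cfg$seed, {
    n <- cfg$n_patients
    stage <- sample.int(4L, n, replace = TRUE, prob = cfg$stage_probs)
    arm <- sample(c("CTX", "CCRT"), n, replace = TRUE, prob = cfg$arm_probs)
    z <- matrix(rnorm(n * length(proteins)), nrow = n,
                dimnames = list(NULL, proteins))
    effects <- stats::setNames(numeric(length(proteins)), proteins)
    effects[layout$true_proteins] <- cfg$effect_sizes
    loghaz <- log(cfg$baseline_hazard) + cfg$stage_coef * (stage - 1L) +
      as.vector(z %*% effects)
    t_event <- rexp(n, rate = exp(loghaz))
    censored <- runif(n) < cfg$censor_frac
    c_time <- ifelse(censored, runif(n, 0, cfg$admin_censor_months), Inf)
    horizon <- cfg$admin_censor_months
    dfs <- pmin(t_event, c_time, horizon)
    event <- as.integer(t_event <= pmin(c_time, horizon))
    list(
      layout = layout, proteins = proteins, stage = stage, arm = arm,
      z = z, effects = effects, dfs = dfs, event = event,
      patient_id = sprintf("P%03d", seq_len(n))
    )
  })
}

#' Generate the clinical table of a synthetic cohort
#'
#' Disease-free survival times follow an exponential proportional-hazards
#' model `h0 * exp(stage_coef * (stage - 1) + sum(effect * z_protein))`; a
#' configurable fraction of patients receives a uniform random censoring
#' time, and all follow-up is administratively censored at the horizon.
#' Treatment arm is assigned independently of every covariate, emulating a
#' randomized trial.
#'
#' @param config a [sim_config()] object.
#' @return a data.frame with columns `patient_id`, `stage` (factor,
#'   `"1b" < "2" < "3" < "4"`), `arm` (`"CTX"`/`"CCRT"`), `dfs_months`,
#'   `event` (1 = recurrence).
#' @export
generate_clinical <- function(config) {
  validate_sim_config(config)
  core <- sim_core(config)
  data.frame(
    patient_id = core$patient_id,
    stage = factor(c("1b", "2", "3", "4")[core$stage],
                   levels = c("1b", "2", "3", "4"), ordered = TRUE),
    arm = core$arm,
    dfs_months = core$dfs,
    event = core$event,
    stringsAsFactors = FALSE
  )
}

#' Generate the quant table and ground truth of a synthetic cohort
#'
#' Emulates batch-wise LC-MRM-MS acquisition: each analytical batch holds
#' one pooled QC run (equal-part mixture of every patient's serum) and its
#' clinical runs, two of which are measured in triplicate. The raw peak
#' area of peptide j in run r of sample s is
#' `A[j, s] * NSF[r]^beta[j] * exp(technical noise)`, where `NSF[r]` is a
#' per-run instrumental response factor (log2-normal: batch-level mean
#' shift plus within-batch run drift) and `beta[j]` a per-peptide
#' ionization response exponent. Normalizing-peptide candidates are
#' constant-abundance proteins, a configurable few of which carry an
#' outcome-group dependent mean shift; a spiked exogenous control has
#' constant abundance in every sample.
#'
#' @param config a [sim_config()] object.
#' @param clinical clinical table from [generate_clinical()] with the same
#'   config (regenerated internally when omitted).
#' @return an object of class `synthetic_cohort`: a list with elements
#'   `quant` (long-format record table), `clinical`, `truth` (per-protein
#'   log-hazard effects, per-run true NSF, per-peptide true beta, the
#'   biological abundance matrix, NP/spike identities) and `config`.
#' @export
generate_quant <- function(config, clinical = NULL) {
  validate_sim_config(config)
  core <- sim_core(config)
  if (is.null(clinical)) {
    clinical <- generate_clinical(config)
  } else {
    stopifnot(identical(clinical$patient_id, core$patient_id))
  }
  layout <- core$layout
  n <- config$n_patients
  horizon <- config$admin_censor_months

  # outcome grouping used for unstable NP candidates: 0 = no recurrence at
  # horizon, 1 = censored earlier, 2 = recurred within horizon
  grp <- ifelse(core$event == 1L, 2L, ifelse(core$dfs < horizon, 1L, 0L))

  peptide_of <- function(p) paste0(p, "_pep1")
  all_proteins <- c(core$proteins, layout$np, layout$spike)
  all_peptides <- peptide_of(all_proteins)

  draws <- with_seed(config$seed + 1000003L, {
    mu_panel <- runif(length(core$proteins), 14, 20)
    mu_np <- runif(config$n_np_candidates, 17, 20)
    beta <- stats::setNames(
      runif(length(all_peptides), config$beta_range[1], config$beta_range[2]),
      all_peptides
    )
    # normalizing-peptide candidates and the spiked control respond with
    # unit exponent by construction: the per-run response factor is defined
    # through them, which is what makes the panel exponents identifiable
    beta[peptide_of(c(layout$np, layout$spike))] <- 1
    batch_of <- sample(rep(seq_len(config$n_batches),
                           length.out = n))
    trip <- lapply(seq_len(config$n_batches), function(b) {
      ids <- which(batch_of == b)
      sample(ids, min(2L, length(ids)))
    })
    batch_mean <- rnorm(config$n_batches, 0, config$batch_drift_sd)
    list(mu_panel = mu_panel, mu_np = mu_np, beta = beta,
         batch_of = batch_of, trip = trip, batch_mean = batch_mean)
  })

  # biological abundance matrix: patients x all proteins (linear scale)
  abundance <- 2^(matrix(draws$mu_panel, n, length(core$proteins),
                         byrow = TRUE) + config$biological_sd * core$z)
  np_ab <- 2^(matrix(draws$mu_np, n, config$n_np_candidates, byrow = TRUE))
  if (config$n_np_unstable > 0L) {
    bad <- seq_len(config$n_np_unstable)
    np_ab[, bad] <- np_ab[, bad] * 2^(config$np_group_shift * grp)
  }
  abundance <- cbind(abundance, np_ab,
                     matrix(config$spike_area, n, 1))
  colnames(abundance) <- all_proteins
  qc_abundance <- colMeans(abundance)

  # run table: one QC run per batch, then each patient's run(s)
  runs <- list()
  for (b in seq_len(config$n_batches)) {
    ids <- which(draws$batch_of == b)
    runs[[length(runs) + 1L]] <- data.frame(
      sample_id = sprintf("QC_B%02d", b), patient = NA_integer_,
      batch_id = b, is_qc = TRUE, replicate_index = 0L)
    for (i in ids) {
      reps <- if (i %in% draws$trip[[b]]) 1:3 else 0L
      runs[[length(runs) + 1L]] <- data.frame(
        sample_id = core$patient_id[i], patient = i,
        batch_id = b, is_qc = FALSE, replicate_index = reps)
    }
  }
  runs <- do.call(rbind, runs)

  quant <- with_seed(config$seed + 2000003L, {
    nsf_run <- 2^(draws$batch_mean[runs$batch_id] +
                    rnorm(nrow(runs), 0, config$batch_drift_sd / 2))
    sdlog <- sqrt(log(1 + config$technical_cv^2))
    n_pep <- length(all_peptides)
    recs <- vector("list", nrow(runs))
    panel <- c(rep("MD", config$n_md_proteins),
               rep("ND", config$n_nd_proteins),
               rep("NP", config$n_np_candidates), "SPIKE")
    for (r in seq_len(nrow(runs))) {
      ab <- if (runs$is_qc[r]) qc_abundance else abundance[runs$patient[r], ]
      pa <- ab * nsf_run[r]^draws$beta * exp(rnorm(n_pep, 0, sdlog))
      recs[[r]] <- data.frame(
        sample_id = runs$sample_id[r], batch_id = runs$batch_id[r],
        is_qc = runs$is_qc[r], replicate_index = runs$replicate_index[r],
        protein_id = all_proteins, peptide_id = all_peptides,
        transition_id = paste0(all_peptides, "_t1"),
        raw_peak_area = unname(pa), panel = panel,
        stringsAsFactors = FALSE)
    }
    attr(recs, "nsf_run") <- nsf_run
    recs
  })
  nsf_run <- attr(quant, "nsf_run")
  quant <- do.call(rbind, quant)
  rownames(quant) <- NULL

  truth <- list(
    effects = core$effects,
    nsf = data.frame(sample_id = runs$sample_id,
                     replicate_index = runs$replicate_index,
                     batch_id = runs$batch_id, is_qc = runs$is_qc,
                     nsf = nsf_run, stringsAsFactors = FALSE),
    beta = draws$beta,
    abundance = abundance,
    np_candidates = layout$np,
    np_unstable = layout$np[seq_len(config$n_np_unstable)],
    spike_protein = layout$spike,
    true_proteins = layout$true_proteins,
    outcome_group = grp
  )
  structure(list(quant = quant, clinical = clinical, truth = truth,
                 config = config),
            class = "synthetic_cohort")
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper running [generate_clinical()] then [generate_quant()].
#'
#' @inheritParams generate_quant
#' @return a `synthetic_cohort` object; see [generate_quant()].
#' @export
simulate_cohort <- function(config = sim_config()) {
  generate_quant(config, generate_clinical(config))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic MRM cohort:", x$config$n_patients, "patients,",
      x$config$n_batches, "batches,", nrow(x$quant), "quant records\n")
  cat("Panels: MD", x$config$n_md_proteins, "/ ND", x$config$n_nd_proteins,
      "proteins;", x$config$n_np_candidates, "NP candidates + spiked control\n")
  invisible(x)
}
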