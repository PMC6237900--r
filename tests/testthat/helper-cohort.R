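# Small cohort configurations reused across tests. Sizes are kept modest so
# the whole suite runs quickly; the defaults of sim_config() itself mirror
# the full study design.

tiny_config <- function(...) {
  args <- list(...)
  base <- list(n_patients = 80L, n_batches = 4L, n_md_proteins = 8L,
               n_nd_proteins = 6L, n_np_candidates = 10L,
               n_np_unstable = 1L, n_true_prognostic = 2L,
               effect_sizes = c(0.8, 0.8), seed = 42L)
  base[names(args)] <- args
  do.call(sim_config, base)
}

# deterministic measurement process: no instrument drift, no technical noise
noise_free_config <- function(...) {
  tiny_config(batch_drift_sd = 0, technical_cv = 0, ...)
}

# drift present but no injection noise: normalization is exactly invertible
drift_only_config <- function(...) {
  tiny_config(technical_cv = 0, ...)
}

# hand-built quant records for toy tests
toy_quant <- function(sample_id, raw, peptide_id = "pepA",
                      protein_id = "protA", batch_id = 1L, is_qc = FALSE,
                      replicate_index = 0L, panel = "MD") {
  data.frame(sample_id = sample_id, batch_id = batch_id, is_qc = is_qc,
             replicate_index = replicate_index, protein_id = protein_id,
             peptide_id = peptide_id,
             transition_id = paste0(peptide_id, "_t1"),
             raw_peak_area = raw, panel = panel, stringsAsFactors = FALSE)
}

# exponential PH survival data with one binary or continuous covariate
sim_surv <- function(n, coef = 0, x = NULL, base_rate = 0.01,
                     cens_rate = 0.005) {
  if (is.null(x)) x <- stats::rnorm(n)
  t_event <- stats::rexp(n, base_rate * exp(coef * x))
  t_cens <- stats::rexp(n, cens_rate)
  list(x = x, time = pmin(t_event, t_cens),
       event = as.integer(t_event <= t_cens))
}

# brute-force pairwise concordance between cases (event by t) and controls
# (still event-free at t); the independent oracle for survival_roc
concordance_auc <- function(marker, time, event, t) {
  case <- time <= t & event == 1
  ctrl <- time > t
  stopifnot(any(case), any(ctrl))
  tot <- 0
  for (i in which(case)) {
    tot <- tot + sum(marker[i] > marker[ctrl]) +
      0.5 * sum(marker[i] == marker[ctrl])
  }
  tot / (sum(case) * sum(ctrl))
}

# quant table with one normalizing peptide per listed area vector
np_quant <- function(areas_by_np) {
  samples <- names(areas_by_np[[1]])
  do.call(rbind, lapply(names(areas_by_np), function(np) {
    toy_quant(samples, unname(areas_by_np[[np]]), peptide_id = np,
              protein_id = np)
  }))
}

# clinical runs with NP areas pinned at 100 (so each median is 100) plus QC
# runs whose NP areas are 100 * nsf and whose target areas are
# const * nsf^beta: the estimated QC NSFs equal `nsf` exactly
qc_beta_quant <- function(nsf, beta, const = 1e5) {
  qc_samples <- sprintf("QC_B%02d", seq_along(nsf))
  clin_samples <- c("s1", "s2", "s3")
  rows <- list()
  for (np in paste0("np", 1:5)) {
    rows[[length(rows) + 1L]] <-
      toy_quant(clin_samples, rep(100, 3), peptide_id = np, protein_id = np)
    rows[[length(rows) + 1L]] <-
      toy_quant(qc_samples, 100 * nsf, peptide_id = np, protein_id = np,
                is_qc = TRUE, batch_id = seq_along(nsf))
  }
  rows[[length(rows) + 1L]] <-
    toy_quant(clin_samples, rep(const, 3), peptide_id = "pepT",
              protein_id = "protT")
  rows[[length(rows) + 1L]] <-
    toy_quant(qc_samples, const * nsf^beta, peptide_id = "pepT",
              protein_id = "protT", is_qc = TRUE, batch_id = seq_along(nsf))
  do.call(rbind, rows)
}

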