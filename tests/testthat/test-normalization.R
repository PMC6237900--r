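test_that("NSF is the median of the five peptide ratios", {
  # engineered so sample s1 has ratios (0.5, 0.8, 1.0, 1.2, 2.0): each
  # peptide's across-sample median is 100 (samples s2..s4 pinned at 100)
  ratios <- c(0.5, 0.8, 1.0, 1.2, 2.0)
  areas <- lapply(seq_along(ratios), function(i) {
    c(s1 = 100 * ratios[i], s2 = 100, s3 = 100, s4 = 100)
  })
  names(areas) <- paste0("np", 1:5)
  model <- compute_nsf(np_quant(areas), paste0("np", 1:5))
  expect_equal(model$peptide_medians, setNames(rep(100, 5), paste0("np", 1:5)))
  nsf <- setNames(model$nsf$nsf, model$nsf$sample_id)
  expect_equal(unname(nsf["s1"]), 1.0)        # median of the five ratios
  expect_equal(unname(nsf["s2"]), 1.0)        # identity sample
})

test_that("NSF is homogeneous: scaling one sample scales its NSF", {
  co <- simulate_cohort(tiny_config())
  nps <- paste0("NP", sprintf("%02d", 2:6), "_pep1")
  m1 <- compute_nsf(co$quant, nps)
  q2 <- co$quant
  pick <- q2$sample_id == "P005" & q2$replicate_index == 0L
  q2$raw_peak_area[pick] <- q2$raw_peak_area[pick] * 3
  m2 <- compute_nsf(q2, nps)
  k1 <- setNames(m1$nsf$nsf, paste(m1$nsf$sample_id, m1$nsf$replicate_index))
  k2 <- setNames(m2$nsf$nsf, paste(m2$nsf$sample_id, m2$nsf$replicate_index))
  # the scaled sample also re-enters the across-sample medians, so
  # homogeneity is exact only up to that one-sample median shift
  expect_equal(unname(k2["P005 0"] / k1["P005 0"]), 3, tolerance = 0.01)
  # and normalization cancels the sample-wide factor
  n1 <- normalize_quant(co$quant, m1)
  n2 <- normalize_quant(q2, m2)
  expect_equal(n2$normalized_area[pick], n1$normalized_area[pick],
               tolerance = 0.01)
  # with the medians held fixed, homogeneity is exact
  ratios <- function(q, m) {
    d <- q[q$peptide_id %in% nps & q$sample_id == "P005" &
             q$replicate_index == 0L, ]
    median(d$raw_peak_area / m$peptide_medians[d$peptide_id])
  }
  expect_equal(ratios(q2, m1), 3 * ratios(co$quant, m1), tolerance = 1e-12)
})

test_that("the median over clinical runs of each NP ratio is exactly 1", {
  co <- simulate_cohort(tiny_config())
  nps <- paste0("NP", sprintf("%02d", 2:6), "_pep1")
  model <- compute_nsf(co$quant, nps)
  clin <- co$quant[!co$quant$is_qc & co$quant$peptide_id %in% nps, ]
  for (np in nps) {
    r <- clin$raw_peak_area[clin$peptide_id == np] / model$peptide_medians[np]
    expect_equal(unname(median(r)), 1)
  }
})

test_that("missing NP measurements raise an error instead of imputing", {
  co <- simulate_cohort(tiny_config())
  nps <- paste0("NP", sprintf("%02d", 2:6), "_pep1")
  q <- co$quant[!(co$quant$peptide_id == nps[1] &
                    co$quant$sample_id == "P003"), ]
  expect_error(compute_nsf(q, nps), "missing")
  expect_error(compute_nsf(co$quant, c(nps, "NOPE_pep1")), "absent")
})

test_that("normalization divides by NSF", {
  areas <- lapply(1:5, function(i) c(s1 = 200, s2 = 100, s3 = 100))
  names(areas) <- paste0("np", 1:5)
  q <- np_quant(areas)
  model <- compute_nsf(q, paste0("np", 1:5))
  target <- toy_quant("s1", 2000, peptide_id = "pepT", protein_id = "protT")
  norm <- normalize_quant(rbind(q, target), model)
  # s1 NSF = 2 (all ratios 2), so 2000 -> 1000
  expect_equal(norm$normalized_area[norm$peptide_id == "pepT"], 1000)
  # NSF = 1 everywhere leaves areas untouched
  flat <- lapply(1:5, function(i) c(s1 = 100, s2 = 100, s3 = 100))
  names(flat) <- paste0("np", 1:5)
  qf <- np_quant(flat)
  normf <- normalize_quant(qf, compute_nsf(qf, paste0("np", 1:5)))
  expect_equal(normf$normalized_area, normf$raw_peak_area)
})

test_that("beta is the log2-log2 OLS slope on QC runs", {
  nsf <- c(0.6, 0.8, 1.0, 1.25, 1.6)
  # note: NP medians make estimated NSF proportional to the true one, which
  # leaves the slope untouched
  for (b in c(0.5, 1, 2)) {
    q <- qc_beta_quant(nsf, beta = b)
    model <- compute_nsf(q, paste0("np", 1:5))
    model <- estimate_beta(q, model)
    expect_equal(unname(model$beta["pepT"]), b, tolerance = 1e-10)
  }
})

test_that("identical QC NSFs fall back to beta = 1 with a warning, and
          wild slopes are clamped", {
  q <- qc_beta_quant(rep(1, 5), beta = 1)
  model <- compute_nsf(q, paste0("np", 1:5))
  expect_warning(model <- estimate_beta(q, model), "no variation")
  expect_true(all(model$beta == 1))
  q2 <- qc_beta_quant(c(0.5, 0.75, 1, 1.5, 2), beta = 4)
  m2 <- compute_nsf(q2, paste0("np", 1:5))
  expect_warning(m2 <- estimate_beta(q2, m2), "clamped")
  expect_equal(unname(m2$beta["pepT"]), 2)
})

test_that("beta correction: PA / NSF^beta, reducing to plain
          normalization at beta = 1", {
  areas <- lapply(1:5, function(i) c(s1 = 400, s2 = 100, s3 = 100))
  names(areas) <- paste0("np", 1:5)
  q <- np_quant(areas)
  model <- compute_nsf(q, paste0("np", 1:5))
  target <- toy_quant("s1", 4000, peptide_id = "pepT", protein_id = "protT")
  qq <- rbind(q, target)
  model$beta <- setNames(rep(1, 6), c(paste0("np", 1:5), "pepT"))
  c1 <- beta_correct(qq, model)
  n1 <- normalize_quant(qq, model)
  expect_equal(c1$corrected_area, n1$normalized_area)
  # s1 NSF = 4; with beta 0.5, 4000 / 4^0.5 = 2000
  model$beta["pepT"] <- 0.5
  c2 <- beta_correct(qq, model)
  expect_equal(c2$corrected_area[c2$peptide_id == "pepT"], 2000)
})

test_that("with the generative NSF and beta, correction recovers
          biological abundance exactly (round trip)", {
  co <- simulate_cohort(drift_only_config())
  truth <- co$truth
  model <- structure(list(
    selected_nps = paste0("NP", sprintf("%02d", 2:6), "_pep1"),
    peptide_medians = NULL,
    nsf = truth$nsf,
    beta = truth$beta), class = "normalization_model")
  corr <- beta_correct(co$quant, model)
  clin <- corr[!corr$is_qc, ]
  idx <- match(clin$sample_id, co$clinical$patient_id)
  expected <- truth$abundance[cbind(idx, match(clin$protein_id,
                                               colnames(truth$abundance)))]
  expect_equal(clin$corrected_area, expected, tolerance = 1e-10)
})

test_that("QC-run variance shrinks after beta correction when drift is
          present", {
  co <- simulate_cohort(tiny_config())
  nps <- paste0("NP", sprintf("%02d", 2:6), "_pep1")
  # a few slopes on 4 QC points land outside the clamp; that is expected
  model <- suppressWarnings(
    estimate_beta(co$quant, compute_nsf(co$quant, nps)))
  corr <- beta_correct(co$quant, model)
  qc <- corr[corr$is_qc, ]
  for (p in c("MD002_pep1", "ND003_pep1")) {
    raw_cv <- sd(qc$raw_peak_area[qc$peptide_id == p]) /
      mean(qc$raw_peak_area[qc$peptide_id == p])
    cor_cv <- sd(qc$corrected_area[qc$peptide_id == p]) /
      mean(qc$corrected_area[qc$peptide_id == p])
    expect_lt(cor_cv, raw_cv)
  }
})

test_that("NP screening applies the four criteria and ranks by
          stability", {
  # stronger drift than the defaults so the spike correlation criterion is
  # clearly identifiable at this reduced cohort size
  co <- simulate_cohort(tiny_config(n_patients = 120L, n_batches = 6L,
                                    batch_drift_sd = 0.3))
  scr <- screen_np_candidates(co$quant, co$clinical,
                              co$truth$np_candidates,
                              co$truth$spike_protein)
  cand <- scr$candidates
  # the group-shifted candidate fails the ANOVA criterion ...
  bad <- cand[cand$protein_id %in% co$truth$np_unstable, ]
  expect_true(all(bad$anova_p <= 0.05))
  expect_false(any(bad$passes))
  # ... and ranks worse on stability than every stable candidate
  expect_true(all(bad$stability > max(cand$stability[cand$passes])))
  expect_length(scr$selected, 5L)
  # candidates are ranked ascending by stability
  expect_equal(cand$stability, sort(cand$stability))
  # selected set is the 5 most stable passers
  expect_equal(scr$selected, cand$peptide_id[cand$passes][1:5])

  # a candidate absent from one sample fails detection
  q2 <- co$quant[!(co$quant$protein_id == "NP05" &
                     co$quant$sample_id == "P001"), ]
  scr2 <- screen_np_candidates(q2, co$clinical, co$truth$np_candidates,
                               co$truth$spike_protein)
  expect_false(scr2$candidates$detected_in_all[
    scr2$candidates$protein_id == "NP05"])

  # too few survivors is an error telling the user to relax thresholds
  expect_error(
    screen_np_candidates(co$quant, co$clinical, co$truth$np_candidates[1:4],
                         co$truth$spike_protein),
    "relax")
})
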