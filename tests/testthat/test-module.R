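mod_data <- function(n = 300, seed = 17) {
  set.seed(seed)
  stage <- sample(1:4, n, replace = TRUE, prob = c(0.26, 0.39, 0.27, 0.08))
  x <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("pA", "pB", "pC")))
  lp <- 0.5 * stage + 0.8 * x[, "pA"] - 0.7 * x[, "pB"]
  t_event <- rexp(n, 0.0015 * exp(lp))
  t_cens <- runif(n, 0, 150)
  cl <- data.frame(patient_id = sprintf("p%03d", 1:n),
                   stage = factor(c("1b", "2", "3", "4")[stage],
                                  levels = c("1b", "2", "3", "4"),
                                  ordered = TRUE),
                   arm = sample(c("CTX", "CCRT"), n, replace = TRUE),
                   dfs_months = pmin(t_event, t_cens, 72),
                   event = as.integer(t_event <= pmin(t_cens, 72)),
                   stringsAsFactors = FALSE)
  list(clinical = cl, x = cbind(stage = stage, x),
       true_coef = c(stage = 0.5, pA = 0.8, pB = -0.7))
}

test_that("fitted module scores are the linear predictor, the cutoff is
          the training median, and hr = exp(coef)", {
  d <- mod_data()
  ep <- assign_pm_endpoints(d$clinical)
  mod <- fit_module(ep$derived_time, ep$derived_event, d$x,
                    c("pA", "pB"), purpose = "prognosis", panel = "MD")
  expect_true("stage" %in% mod$fit$covariates)
  expect_equal(mod$scores,
               as.numeric(d$x[, mod$fit$covariates] %*% mod$fit$coef))
  expect_equal(mod$median_cutoff, median(mod$scores))
  expect_equal(mod$fit$hr, exp(mod$fit$coef))
  # generative coefficients sit inside their 95% Wald intervals
  ci_lo <- mod$fit$coef - 1.96 * mod$fit$se
  ci_hi <- mod$fit$coef + 1.96 * mod$fit$se
  for (v in names(d$true_coef)) {
    expect_gt(d$true_coef[v], ci_lo[v] - 1e-9)
    expect_lt(d$true_coef[v], ci_hi[v] + 1e-9)
  }
  expect_error(fit_module(ep$derived_time, ep$derived_event, d$x,
                          character(), force_stage = FALSE), "empty")
  expect_error(fit_module(ep$derived_time, ep$derived_event, d$x, "nope"),
               "lacks")
})

test_that("a module with real protein signal beats the stage-only model", {
  d <- mod_data(seed = 19)
  ep <- assign_pm_endpoints(d$clinical)
  mod <- fit_module(ep$derived_time, ep$derived_event, d$x, c("pA", "pB"))
  stage_fit <- cox_fit(ep$derived_time, ep$derived_event,
                       d$x[, "stage", drop = FALSE])
  lrt <- likelihood_ratio_test(stage_fit, mod$fit)
  expect_lt(lrt$p, 0.001)
  auc_mod <- survival_roc(mod$scores, ep$derived_time, ep$derived_event,
                          72)$auc
  stage_scores <- as.numeric(d$x[, "stage"] * stage_fit$coef)
  auc_stage <- survival_roc(stage_scores, ep$derived_time,
                            ep$derived_event, 72)$auc
  expect_gt(auc_mod, auc_stage)
})

test_that("median-split stratification separates risk groups and reports
          per-stage statistics", {
  d <- mod_data(seed = 23)
  ep <- assign_pm_endpoints(d$clinical)
  mod <- fit_module(ep$derived_time, ep$derived_event, d$x, c("pA", "pB"))
  st <- stratify(mod, d$clinical, ep$derived_time, ep$derived_event)
  expect_equal(sum(st$assignment$risk_group == "low") +
                 sum(st$assignment$risk_group == "high"), 300)
  expect_lt(st$overall$hr_low_vs_high, 1)
  expect_lt(st$overall$logrank_p, 0.05)
  expect_named(st$by_stage, c("1b", "2", "3", "4"))
  expect_gt(st$auc, 0.5)
  expect_gte(st$roc_cutoff$sensitivity, 0)
  # an empty or event-free stratum reports NA statistics rather than failing
  empty_eval <- seprogadic:::eval_split(c(1, 2, 3), c(0, 0, 0),
                                        c(TRUE, TRUE, FALSE))
  expect_true(is.na(empty_eval$hr_low_vs_high))
})

test_that("AT stratification partitions the cohort into the four
          treatment-benefit groups", {
  d <- mod_data(seed = 29)
  ep <- assign_at_endpoints(assign_pm_endpoints(d$clinical), d$clinical)
  mod <- fit_module(ep$at_time, ep$at_event, d$x, c("pA", "pB"),
                    purpose = "at_selection", force_stage = FALSE)
  st <- stratify(mod, d$clinical, ep$derived_time, ep$derived_event)
  tg <- st$assignment$treatment_group
  expect_equal(sort(unique(tg)), c("fCCRT", "fCTX", "tCCRT", "tCTX"))
  expect_equal(length(tg), 300)
  # groups partition arms: tCCRT/fCCRT exhaust CCRT, tCTX/fCTX exhaust CTX
  expect_equal(sum(tg %in% c("tCCRT", "fCCRT")),
               sum(d$clinical$arm == "CCRT"))
  expect_equal(sum(tg %in% c("tCTX", "fCTX")),
               sum(d$clinical$arm == "CTX"))
  # below-cutoff CCRT is tCCRT; below-cutoff CTX is fCTX
  below <- st$assignment$score <= mod$median_cutoff
  expect_true(all(tg[below & d$clinical$arm == "CCRT"] == "tCCRT"))
  expect_true(all(tg[below & d$clinical$arm == "CTX"] == "fCTX"))
})

test_that("degenerate constant scores are flagged", {
  d <- mod_data(seed = 31)
  ep <- assign_pm_endpoints(d$clinical)
  mod <- fit_module(ep$derived_time, ep$derived_event, d$x, c("pA", "pB"))
  expect_warning(
    st <- stratify(mod, d$clinical, ep$derived_time, ep$derived_event,
                   scores = rep(1, 300)),
    "degenerate")
  expect_true(st$degenerate)
})
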