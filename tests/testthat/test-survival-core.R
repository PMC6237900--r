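test_that("Kaplan-Meier estimate matches the hand-computed product
          limit", {
  # three events, no censoring: S drops to 2/3, 1/3, 0
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(1, 2/3, 1/3, 0))
  expect_equal(km$n_risk, c(3, 3, 2, 1))
  # no events: S stays 1
  km2 <- km_estimate(c(5, 10, 15), c(0, 0, 0))
  expect_true(all(km2$surv == 1))
  # uncensored data: S(t) equals the empirical survivor fraction
  set.seed(1)
  tt <- rexp(40, 0.1)
  km3 <- km_estimate(tt, rep(1, 40))
  for (t0 in quantile(tt, c(0.25, 0.5, 0.9))) {
    expect_equal(min(km3$surv[km3$time <= t0]), mean(tt > t0))
  }
})

test_that("log-rank statistic equals the hand-computed O-E form on a toy
          and is zero on identical groups", {
  # group A: events at months 1 and 2; group B: two censored at 5.
  # risk tables give E_A = 1/2 + 1/3 = 5/6, V = 1/4 + 2/9 = 17/36,
  # chi-square = (2 - 5/6)^2 / (17/36) = 49/17
  lr <- logrank_test(c(1, 2, 5, 5), c(1, 1, 0, 0), c("A", "A", "B", "B"))
  expect_equal(lr$statistic, 49 / 17, tolerance = 1e-10)
  expect_equal(lr$p, pchisq(49 / 17, 1, lower.tail = FALSE))

  d <- sim_surv(30, coef = 0)
  dup <- logrank_test(rep(d$time, 2), rep(d$event, 2),
                      rep(c("A", "B"), each = 30))
  expect_equal(dup$statistic, 0, tolerance = 1e-10)
  # no events at all: statistic 0, p 1
  none <- logrank_test(c(1, 2, 3, 4), rep(0, 4), c(1, 1, 2, 2))
  expect_equal(none, list(statistic = 0, p = 1))
})

test_that("log-rank p-values are uniform under exchangeable groups", {
  set.seed(99)
  p <- replicate(400, {
    d <- sim_surv(60, coef = 0)
    logrank_test(d$time, d$event, rep(c("A", "B"), 30))$p
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("Cox fit recovers a doubled hazard and reports hr = exp(coef)", {
  set.seed(7)
  x <- rbinom(2000, 1, 0.5)
  d <- sim_surv(2000, coef = log(2), x = x)
  fit <- cox_fit(d$time, d$event, cbind(trt = d$x))
  expect_equal(unname(fit$coef["trt"]), log(2), tolerance = 0.1)
  expect_equal(unname(fit$hr["trt"]), exp(unname(fit$coef["trt"])))
  expect_true(fit$converged)
  # printed-table arithmetic: a coefficient of 0.512 is an HR of 1.67
  expect_equal(round(exp(0.512), 2), 1.67)
})

test_that("Cox Wald test is calibrated under the null", {
  set.seed(11)
  z <- replicate(400, {
    d <- sim_surv(120, coef = 0)
    f <- cox_fit(d$time, d$event, cbind(x = d$x))
    unname(f$coef / f$se)
  })
  rej <- mean(abs(z) >= 1.96)
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})

test_that("cox_fit rejects degenerate inputs", {
  expect_error(cox_fit(c(1, 2, 3), c(1, 0, 1), cbind(x = c(1, 1, 1))),
               "constant")
  expect_error(cox_fit(c(1, 2, 3), c(0, 0, 0), cbind(x = c(1, 2, 3))),
               "event")
  # zero-column matrix degenerates to the null model
  f0 <- cox_fit(c(1, 2, 3), c(1, 0, 1), matrix(nrow = 3, ncol = 0))
  expect_length(f0$coef, 0)
  expect_equal(f0$loglik, f0$loglik_null)
})

test_that("backward elimination keeps forced and truly predictive
          covariates and discards noise", {
  set.seed(21)
  n <- 400
  x_true <- rnorm(n)
  noise <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("n", 1:4)))
  d <- sim_surv(n, coef = 0.9, x = x_true)
  xm <- cbind(strong = x_true, noise, stage = sample(1:4, n, replace = TRUE))
  be <- backward_eliminate(d$time, d$event, xm, forced = "stage")
  expect_true("strong" %in% be$retained)
  expect_true("stage" %in% be$fit$covariates)   # forced despite being noise
  expect_true(all(be$fit$wald_p[setdiff(be$retained, "stage")] <= 0.05))

  # pure noise, nothing forced: empty set most of the time; every retained
  # covariate must be significant
  set.seed(22)
  empties <- replicate(20, {
    d0 <- sim_surv(150, coef = 0)
    nm <- matrix(rnorm(150 * 5), 150, dimnames = list(NULL, paste0("n", 1:5)))
    be0 <- backward_eliminate(d0$time, d0$event, nm)
    length(be0$retained) == 0L
  })
  expect_gt(mean(empties), 0.5)
})

test_that("likelihood-ratio test: chi-square arithmetic, identity and
          nesting checks", {
  set.seed(31)
  d <- sim_surv(300, coef = 0.5)
  x2 <- cbind(x = d$x, z = rnorm(300))
  full <- cox_fit(d$time, d$event, x2)
  nested <- cox_fit(d$time, d$event, x2[, "x", drop = FALSE])
  lrt <- likelihood_ratio_test(nested, full)
  expect_equal(lrt$df, 1L)
  expect_equal(lrt$p, pchisq(lrt$statistic, 1, lower.tail = FALSE))
  # identical fits compare with p = 1
  expect_equal(likelihood_ratio_test(full, full)$p, 1)
  # an LR statistic of 3.841459 on 1 df sits exactly at p = 0.05
  expect_equal(pchisq(3.841459, 1, lower.tail = FALSE), 0.05,
               tolerance = 1e-6)
  other <- cox_fit(d$time, d$event, x2[, "z", drop = FALSE])
  expect_error(likelihood_ratio_test(other, nested), "nested")
})

test_that("adding null covariates gives uniform LRT p-values", {
  set.seed(41)
  p <- replicate(300, {
    d <- sim_surv(80, coef = 0.5)
    xm <- cbind(x = d$x, z = rnorm(80))
    likelihood_ratio_test(cox_fit(d$time, d$event, xm[, "x", drop = FALSE]),
                          cox_fit(d$time, d$event, xm))$p
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})
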