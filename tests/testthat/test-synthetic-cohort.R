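# Synthetic cohort generator: configuration validation, closed-form oracles
# for the hazard sampler, detection/censoring snap rules, and distributional
# checks at Monte-Carlo tolerances.

test_that("config validation rejects malformed inputs", {
  expect_error(cohort_config(covariate_freqs = list(gender = c(male = 0.7,
                                                               female = 0.7))),
               "frequency")
  expect_error(cohort_config(visit_schedule = c(0.5, 1)), "start at 0")
  expect_error(cohort_config(visit_schedule = c(0, 1, 1)), "increasing")
  hz <- default_hazard(); hz$lambda_base <- 0
  expect_error(cohort_config(hazard = hz), "lambda_base")
  expect_error(cohort_config(missing_baseline_hba1c = 1.5), "missing")
})

test_that("n = 0 gives an empty cohort; fixed seed is bit-identical", {
  co <- generate_cohort(cohort_config(n_subjects = 0, seed = 1))
  expect_equal(nrow(co$subjects), 0L)
  expect_equal(nrow(co$labs), 0L)
  a <- generate_cohort(cohort_config(n_subjects = 150, seed = 9))
  b <- generate_cohort(cohort_config(n_subjects = 150, seed = 9))
  expect_identical(a, b)
})

test_that("baseline labs and categoricals match configured distributions", {
  co <- generate_cohort(cohort_config(n_subjects = 2000, seed = 3))
  g0 <- co$labs$glucose[co$labs$time == 0]
  expect_equal(length(g0), 2000L)
  expect_lt(abs(mean(g0) - 107.35), 3 * 7.84 / sqrt(2000))
  h0 <- co$labs$hba1c[co$labs$time == 0]
  expect_lt(abs(mean(h0, na.rm = TRUE) - 5.91), 3 * 0.51 / sqrt(2000))
  # categorical block: female frequency within 3 binomial SEs of 0.665
  pf <- mean(co$subjects$gender == "female")
  expect_lt(abs(pf - 0.665), 3 * sqrt(0.665 * 0.335 / 2000))
})

test_that("null-hazard event fraction matches the exponential closed form", {
  hz <- default_hazard()
  hz$coef[] <- 0; hz$coef_change[] <- 0; hz$lambda_base <- 0.1
  cfg <- cohort_config(
    n_subjects = 4000, hazard = hz,
    visit_schedule = seq(0, 30, by = 0.1),
    censoring = list(admin_min = 29, admin_max = 30, dropout_rate = 0),
    missing_baseline_hba1c = 0, seed = 6
  )
  co <- generate_cohort(cfg)
  p2 <- mean(co$subjects$X <= 2 & co$subjects$D == 1)
  expect_lt(abs(p2 - (1 - exp(-0.2))), 3 * sqrt(0.18 * 0.82 / 4000))
})

test_that("biomarker paths: degenerate and deterministic drift cases", {
  base <- data.frame(glucose = c(100, 110), hba1c = c(5.5, 6.2))
  dr <- default_drift()
  dr$glucose[c("mean", "sd_increment", "sd_between")] <- list(0, 0, 0)
  dr$hba1c[c("mean", "sd_increment", "sd_between")] <- list(0, 0, 0)
  p <- simulate_biomarker_paths(base, c(0, 1, 2, 3), dr)
  expect_equal(p$glucose, rep(c(100, 110), each = 4))
  expect_equal(p$hba1c, rep(c(5.5, 6.2), each = 4))
  # deterministic drift: +2 mg/dL/yr -> baseline + 6 at year 3
  dr$glucose$mean <- 2
  p <- simulate_biomarker_paths(base, c(0, 1, 2, 3), dr)
  expect_equal(p$glucose[p$time == 3], c(106, 116))
})

test_that("biomarker year-1 change has the configured mean", {
  set.seed(21)
  n <- 5000
  base <- data.frame(glucose = rep(100, n), hba1c = rep(5.5, n))
  dr <- default_drift()
  mu <- dr$glucose$mean
  sigma <- sqrt(dr$glucose$sd_increment^2 + dr$glucose$sd_between^2)
  p <- simulate_biomarker_paths(base, c(0, 1), dr)
  chg <- p$glucose[p$time == 1] - p$glucose[p$time == 0]
  expect_lt(abs(mean(chg) - mu), 3 * sigma / sqrt(n))
})

test_that("event sampler obeys closed-form hazard oracles", {
  hz <- default_hazard()
  hz$coef[] <- 0; hz$coef_change[] <- 0
  hz$lambda_base <- 0.25
  path <- data.frame(time = 0, glucose = 107.35, hba1c = 5.91)
  set.seed(4)
  d <- simulate_event_time(hz, path, n = 1e4)
  expect_lt(abs(mean(d) - 4), 3 * 4 / sqrt(1e4)) # Exp(0.25): mean 4, sd 4

  # covariate fixed at +1 SD-unit with coefficient log 2 doubles the hazard:
  # median onset log(2) / (2 * lambda)
  hz2 <- hz
  hz2$coef <- c(glucose = log(2), hba1c = 0)
  hz2$centers <- c(glucose = 0, hba1c = 5.91)
  path2 <- data.frame(time = 0, glucose = 1, hba1c = 5.91)
  set.seed(5)
  d2 <- simulate_event_time(hz2, path2, n = 1e4)
  med_expected <- log(2) / (2 * 0.25)
  # asymptotic SE of the sample median of Exp(0.5): 1/(2 f(m) sqrt(n))
  se_med <- 1 / (2 * (0.5 * exp(-0.5 * med_expected)) * sqrt(1e4))
  expect_lt(abs(median(d2) - med_expected), 3 * se_med)

  # piecewise path jumping at year 1: survivor function is the product of
  # two exponential segments
  hz3 <- hz2
  path3 <- data.frame(time = c(0, 1), glucose = c(0, 1), hba1c = 5.91)
  set.seed(6)
  d3 <- simulate_event_time(hz3, path3, n = 2e4)
  # S(2) = exp(-0.25 * 1) * exp(-0.5 * 1)
  s2 <- exp(-0.25) * exp(-0.5)
  expect_lt(abs(mean(d3 > 2) - s2), 3 * sqrt(s2 * (1 - s2) / 2e4))
  # non-finite hazards are refused
  hz_bad <- hz2
  hz_bad$coef <- c(glucose = 1e6, hba1c = 0)
  expect_error(simulate_event_time(hz_bad, path2), "non-finite")
})

test_that("detection snaps to the next visit and censoring to the last one", {
  sched <- c(0, 1, 2, 3, 4, 5, 6)
  none <- list(admin_min = 50, admin_max = 50, dropout_rate = 0)
  out <- apply_censoring_and_detection(1.4, sched, none)
  expect_equal(out$X, 2.0)
  expect_equal(out$D, 1L)
  # onset exactly at a visit is detected there
  out <- apply_censoring_and_detection(3, sched, none)
  expect_equal(out$X, 3.0)
  expect_equal(out$D, 1L)
  # administrative censoring before onset
  out <- apply_censoring_and_detection(
    10, sched, list(admin_min = 6, admin_max = 6, dropout_rate = 0))
  expect_equal(out$X, 6.0)
  expect_equal(out$D, 0L)
})

test_that("default-config median follow-up is near 6.11 years (reverse KM)", {
  co <- generate_cohort(cohort_config(n_subjects = 5000, seed = 11))
  rkm <- survival::survfit(survival::Surv(X, 1 - D) ~ 1, data = co$subjects)
  med <- unname(summary(rkm)$table["median"])
  # censoring snaps to a quarterly contact grid, so the achievable medians
  # are multiples of 0.25; accept within one grid step of 6.11
  expect_lt(abs(med - 6.11), 0.26)
})

test_that("interval detection: every event time lies on the visit schedule", {
  cfg <- cohort_config(n_subjects = 800, seed = 14)
  co <- generate_cohort(cfg)
  ev <- co$subjects[co$subjects$D == 1, ]
  expect_true(all(ev$X %in% cfg$visit_schedule))
  expect_true(all(ev$true_onset <= ev$X))
  expect_true(all(co$subjects$X > 0))
})

test_that("null cohort KM matches exp(-lambda t) at t = 1, 2, 3", {
  hz <- default_hazard()
  hz$coef[] <- 0; hz$coef_change[] <- 0; hz$lambda_base <- 0.1
  cfg <- cohort_config(
    n_subjects = 5000, hazard = hz,
    visit_schedule = seq(0, 12, by = 0.05),
    censoring = list(admin_min = 11, admin_max = 12, dropout_rate = 0),
    missing_baseline_hba1c = 0, seed = 15
  )
  co <- generate_cohort(cfg)
  km <- survival::survfit(survival::Surv(X, D) ~ 1, data = co$subjects)
  for (tt in 1:3) {
    s_hat <- summary(km, times = tt)$surv
    s_true <- exp(-0.1 * tt)
    expect_lt(abs(s_hat - s_true), 3 * sqrt(s_true * (1 - s_true) / 5000))
  }
})

test_that("misspecification scenario violates proportional hazards", {
  # a baseline-labs Cox model fit to misspecified-generator data should fail
  # the PH score test far more often than the nominal 5%
  reject <- vapply(1:20, function(s) {
    co <- generate_cohort(misspec_cohort_config(n_subjects = 600, seed = 100 + s))
    fr <- build_landmark_frame(co, 0, 2, spec = labs_spec())
    cz <- survival::cox.zph(survival::coxph(
      survival::Surv(time, status) ~ glucose_b + hba1c_b, data = fr$data))
    cz$table["GLOBAL", "p"] < 0.05
  }, logical(1))
  expect_gt(mean(reject), 0.25)
})
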