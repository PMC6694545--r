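#' @title Synthetic DPP-like cohort generator
#' @description Generates longitudinal diabetes-prevention cohorts with known
#'   ground truth: multinomial baseline categoricals matching published
#'   marginal frequencies, truncated-normal baseline labs, Gaussian
#'   random-walk biomarker paths with subject-specific drift, event times
#'   drawn from a piecewise-exponential proportional hazards model on the
#'   (piecewise-constant) covariate path, interval detection of onset at
#'   scheduled visits, and independent administrative-end plus dropout
#'   censoring snapped to the last attended visit.
#' @name synthetic_cohort
NULL

#' Default categorical frequency blocks for a DPP-like cohort
#'
#' Marginal frequencies for age group, gender, BMI group, smoking status and
#' race/ethnicity typical of a high-diabetes-risk prevention trial
#' population. Each block is renormalized to sum to exactly 1.
#'
#' @param arm `"placebo"` or `"metformin"`; the published marginals differ
#'   only slightly between arms, so the overall-cohort values are used for
#'   both.
#' @return named list of named probability vectors.
#' @export
dpp_covariate_freqs <- function(arm = c("placebo", "metformin")) {
  arm <- match.arg(arm)
  norm <- function(x) x / sum(x)
  list(
    age_group = norm(c("<40" = 0.139, "40-44" = 0.149, "45-49" = 0.205,
                       "50-54" = 0.183, "55-59" = 0.124, "60-64" = 0.098,
                       "65+" = 0.103)),
    gender    = norm(c(male = 0.335, female = 0.665)),
    bmi_group = norm(c("<30" = 0.323, "30-34" = 0.301, "35+" = 0.375)),
    smoking   = norm(c(no = 0.858, yes = 0.066, not_available = 0.076)),
    race      = norm(c(white = 0.578, black = 0.214, hispanic = 0.160,
                       other = 0.048))
  )
}

#' Default biomarker drift specification
#'
#' Gaussian random-walk parameters per biomarker: mean annual change,
#' SD of annual increments, between-subject drift SD, and a physiological
#' floor. Defaults: glucose +1 mg/dL/yr (increment SD 4, between-subject SD
#' 1.5, floor 40); HbA1c +0.02 %/yr (increment SD 0.15, between-subject SD
#' 0.04, floor 3).
#'
#' @return named list with `glucose` and `hba1c` components.
#' @export
default_drift <- function() {
  list(
    glucose = list(mean = 1.0, sd_increment = 4.0, sd_between = 1.5,
                   floor = 40),
    hba1c   = list(mean = 0.02, sd_increment = 0.15, sd_between = 0.04,
                   floor = 3)
  )
}

#' Default event-hazard specification
#'
#' Proportional hazards on current (drifting) lab values:
#' `lambda(t) = lambda_base * arm_multiplier *
#'   exp(m(t) * [coef'(labs(t) - centers) + coef_change'(labs(t) - labs(0))])`
#' with `m(t) = 1 + tv_slope * t` (so `tv_slope != 0` breaks proportional
#' hazards). Defaults give roughly an 18% event fraction by year 2 in the
#' placebo arm; the metformin multiplier (0.65) mirrors the roughly
#' one-third lower 2-year diabetes incidence under metformin.
#'
#' @param arm treatment arm.
#' @return named list; see [cohort_config()].
#' @export
default_hazard <- function(arm = c("placebo", "metformin")) {
  arm <- match.arg(arm)
  list(
    lambda_base = 0.08,                # events/year at centered covariates
    coef = c(glucose = log(1.08), hba1c = log(1.5)),  # on current values
    coef_change = c(glucose = 0, hba1c = 0),          # extra effect of change
    centers = c(glucose = 107.35, hba1c = 5.91),
    use = "current",                   # "current" or "baseline" lab values
    tv_slope = 0,                      # >0: biomarker effect grows with time
    arm_multiplier = if (arm == "metformin") 0.65 else 1.0
  )
}

#' Cohort generator configuration
#'
#' Assembles and validates the full configuration of the synthetic cohort
#' generator. Defaults emulate the placebo arm of a diabetes prevention
#' trial: baseline fasting glucose ~ N(107.35, 7.84^2) truncated at 0, HbA1c
#' ~ N(5.91, 0.51^2) truncated at 0, visits at 0 and 0.5 years then annually
#' through year 8, proportional hazards on current (drifting) lab values, and
#' independent censoring tuned to a median follow-up of about 6.1 years.
#'
#' @param n_subjects number of subjects.
#' @param arm treatment arm label.
#' @param covariate_freqs named list of categorical frequency blocks; see
#'   [dpp_covariate_freqs()].
#' @param glucose_baseline,hba1c_baseline `c(mean =, sd =)` of the baseline
#'   lab distribution (mg/dL and %, respectively).
#' @param drift per-biomarker list with `mean` (annual change), `sd_increment`
#'   (SD of annual random-walk increments), `sd_between` (SD of
#'   subject-specific drift) and `floor` (physiological minimum).
#' @param hazard list: `lambda_base` (> 0, per year), `coef` on centered
#'   current lab values, `coef_change` on raw changes-from-baseline,
#'   `centers`, `use` (`"current"` or `"baseline"`), `tv_slope`
#'   (time-varying-effect switch: the biomarker effect is multiplied by
#'   `1 + tv_slope * t`, violating proportional hazards when nonzero) and
#'   `arm_multiplier`.
#' @param visit_schedule strictly increasing visit times in years, starting
#'   at 0.
#' @param censoring list: `admin_min`/`admin_max` (uniform administrative end,
#'   years), `dropout_rate` (exponential dropout, per year; 0 disables) and
#'   optional `contact_grid` of attended contact times to which censoring is
#'   snapped (default: quarterly visits through the end of the lab schedule;
#'   outcome labs are only drawn at `visit_schedule` times, but censoring
#'   happens at the last attended contact of any kind).
#' @param missing_baseline_hba1c fraction of subjects with missing baseline
#'   HbA1c (exercises the exclusion path).
#' @param seed RNG seed; fixed seed implies a bit-identical cohort.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 1027,
                          arm = c("placebo", "metformin"),
                          covariate_freqs = dpp_covariate_freqs(),
                          glucose_baseline = c(mean = 107.35, sd = 7.84),
                          hba1c_baseline = c(mean = 5.91, sd = 0.51),
                          drift = default_drift(),
                          hazard = default_hazard(arm),
                          visit_schedule = c(0, 0.5, 1:8),
                          censoring = list(admin_min = 4.6, admin_max = 8.35,
                                           dropout_rate = 0.02),
                          missing_baseline_hba1c = 8 / 2057,
                          seed = NULL) {
  arm <- match.arg(arm)
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 0L) {
    stop("`n_subjects` must be a non-negative integer", call. = FALSE)
  }
  for (nm in names(covariate_freqs)) {
    p <- covariate_freqs[[nm]]
    if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-6) {
      stop("invalid frequency block `", nm,
           "`: probabilities must lie in [0,1] and sum to 1", call. = FALSE)
    }
  }
  for (lab in c("glucose_baseline", "hba1c_baseline")) {
    v <- get(lab)
    if (!all(c("mean", "sd") %in% names(v)) || v[["sd"]] < 0) {
      stop("`", lab, "` needs named mean and sd with sd >= 0", call. = FALSE)
    }
  }
  for (bm in names(drift)) {
    d <- drift[[bm]]
    if (d$sd_increment < 0 || d$sd_between < 0) {
      stop("drift SDs must be >= 0 for `", bm, "`", call. = FALSE)
    }
  }
  if (!is.numeric(hazard$lambda_base) || hazard$lambda_base <= 0) {
    stop("`hazard$lambda_base` must be > 0", call. = FALSE)
  }
  if (visit_schedule[1L] != 0 || any(diff(visit_schedule) <= 0)) {
    stop("`visit_schedule` must be strictly increasing and start at 0",
         call. = FALSE)
  }
  if (censoring$admin_min > censoring$admin_max || censoring$dropout_rate < 0) {
    stop("invalid censoring specification", call. = FALSE)
  }
  if (missing_baseline_hba1c < 0 || missing_baseline_hba1c > 1) {
    stop("`missing_baseline_hba1c` must lie in [0,1]", call. = FALSE)
  }
  structure(
    list(n_subjects = n_subjects, arm = arm,
         covariate_freqs = covariate_freqs,
         glucose_baseline = glucose_baseline, hba1c_baseline = hba1c_baseline,
         drift = drift, hazard = hazard, visit_schedule = visit_schedule,
         censoring = censoring,
         missing_baseline_hba1c = missing_baseline_hba1c, seed = seed),
    class = "cohort_config"
  )
}

#' Misspecification scenario configuration
#'
#' A preset under which the baseline-only static model is misspecified: the
#' biomarker effect on the hazard grows with time (`tv_slope > 0`, violating
#' proportional hazards) and acts on the current, drifting lab values. The
#' dynamic landmark model, refit at each landmark, can track this; a single
#' baseline fit cannot.
#'
#' @param ... overrides passed to [cohort_config()].
#' @return a `cohort_config`.
#' @export
misspec_cohort_config <- function(...) {
  hz <- default_hazard()
  hz$tv_slope <- 0.5
  hz$lambda_base <- 0.06
  hz$coef <- c(glucose = log(1.10), hba1c = log(1.6))
  cohort_config(hazard = hz, ...)
}

# exact truncated-normal (at `lower`) sampler via inverse CDF
rtruncnorm_lower <- function(n, mean, sd, lower = 0) {
  if (sd == 0) return(rep(pmax(mean, lower), n))
  plo <- stats::pnorm((lower - mean) / sd)
  u <- stats::runif(n, plo, 1)
  mean + sd * stats::qnorm(u)
}

#' Simulate biomarker paths
#'
#' Gaussian random walk on the visit schedule with subject-specific drift:
#' for visit gap `dt`, the increment is
#' `drift_i * dt + N(0, sd_increment^2 * dt)` where
#' `drift_i ~ N(mean, sd_between^2)`. Values are floored at the configured
#' physiological minimum. Uses the current RNG state.
#'
#' @param baseline data.frame with columns `glucose` and `hba1c` (one row per
#'   subject).
#' @param schedule visit times, starting at 0.
#' @param drift drift specification as in [cohort_config()].
#' @return data.frame `(id, time, glucose, hba1c)` in subject-major order,
#'   where `id` indexes rows of `baseline`.
#' @export
simulate_biomarker_paths <- function(baseline, schedule,
                                     drift = default_drift()) {
  stopifnot(is.data.frame(baseline), schedule[1L] == 0)
  n <- nrow(baseline)
  k <- length(schedule)
  out <- list(id = rep(seq_len(n), each = k),
              time = rep(schedule, times = n))
  for (bm in c("glucose", "hba1c")) {
    d <- drift[[bm]]
    base <- as.numeric(baseline[[bm]])
    path <- matrix(0, nrow = n, ncol = k)
    path[, 1L] <- base
    if (k > 1L) {
      subj_drift <- stats::rnorm(n, d$mean, d$sd_between)
      for (j in 2L:k) {
        dt <- schedule[j] - schedule[j - 1L]
        inc <- subj_drift * dt +
          stats::rnorm(n, 0, d$sd_increment * sqrt(dt))
        path[, j] <- pmax(path[, j - 1L] + inc, d$floor)
      }
    }
    out[[bm]] <- as.vector(t(path))
  }
  as.data.frame(out)
}

# piecewise-constant hazard rates: one row per subject, one column per
# segment (segments start at the schedule times; last value held to Inf)
segment_rate_matrix <- function(hazard, schedule, Gm, Hm) {
  g <- if (hazard$use == "baseline") Gm[, 1L] else Gm
  h <- if (hazard$use == "baseline") Hm[, 1L] else Hm
  lp <- hazard$coef[["glucose"]] * (g - hazard$centers[["glucose"]]) +
    hazard$coef[["hba1c"]] * (h - hazard$centers[["hba1c"]]) +
    hazard$coef_change[["glucose"]] * (g - Gm[, 1L]) +
    hazard$coef_change[["hba1c"]] * (h - Hm[, 1L])
  if (!is.matrix(lp)) lp <- matrix(lp, nrow = nrow(Gm), ncol = ncol(Gm))
  mult <- pmax(1 + hazard$tv_slope * schedule, 0)
  rate <- hazard$lambda_base * hazard$arm_multiplier *
    exp(sweep(lp, 2L, mult, "*"))
  if (any(!is.finite(rate))) stop("non-finite hazard rate", call. = FALSE)
  rate
}

# exact inverse-transform draw per row of the rate matrix
pc_hazard_onset <- function(rate, schedule) {
  n <- nrow(rate)
  k <- ncol(rate)
  if (k > 2L) {
    dur <- diff(schedule)
    cum <- cbind(0, t(apply(sweep(rate[, -k, drop = FALSE], 2L, dur, "*"),
                            1L, cumsum)))
  } else if (k == 2L) {
    cum <- cbind(0, rate[, 1L, drop = TRUE] * diff(schedule))
  } else {
    cum <- matrix(0, nrow = n, ncol = 1L)
  }
  target <- -log(stats::runif(n))
  seg <- rowSums(cum <= target) # rows are nondecreasing; first col is 0
  i <- cbind(seq_len(n), seg)
  schedule[seg] + (target - cum[i]) / rate[i]
}

#' Simulate a latent event time from a piecewise-constant hazard
#'
#' Inverse-transform sampling: the covariate path is piecewise-constant
#' between visits (last value held after the final visit), so the cumulative
#' hazard is piecewise-linear and inversion is exact within each piece.
#'
#' @param hazard hazard specification as in [cohort_config()].
#' @param path data.frame `(time, glucose, hba1c)` for one subject, sorted by
#'   time, first row at time 0.
#' @param n number of independent draws (same path).
#' @return numeric vector of `n` latent onset times in years.
#' @export
simulate_event_time <- function(hazard, path, n = 1) {
  stopifnot(is.data.frame(path), nrow(path) >= 1L, path$time[1L] == 0)
  k <- nrow(path)
  Gm <- matrix(path$glucose, nrow = n, ncol = k, byrow = TRUE)
  Hm <- matrix(path$hba1c, nrow = n, ncol = k, byrow = TRUE)
  rate <- segment_rate_matrix(hazard, path$time, Gm, Hm)
  pc_hazard_onset(rate, path$time)
}

#' Apply interval detection and censoring
#'
#' Onset is detected at the first visit at or after the latent onset time;
#' censoring is the minimum of the administrative end and the dropout time,
#' snapped down to the last attended visit (never earlier than the first
#' post-baseline visit). `X = min(detection, censoring)` and `D = 1` iff the
#' detection visit occurs no later than censoring.
#'
#' @param true_onset numeric vector of latent onset times.
#' @param visit_schedule visit times.
#' @param censoring censoring spec as in [cohort_config()]; draws use the
#'   current RNG state.
#' @return data.frame `(X, D, detect_time, censor_time)`.
#' @export
apply_censoring_and_detection <- function(true_onset, visit_schedule,
                                          censoring) {
  stopifnot(length(visit_schedule) >= 1L)
  n <- length(true_onset)
  post <- censoring$contact_grid
  if (is.null(post)) {
    post <- sort(unique(c(seq(0.25, max(visit_schedule), by = 0.25),
                          visit_schedule[visit_schedule > 0])))
  }
  post <- post[post > 0]
  if (length(post) == 0L) stop("need at least one post-baseline contact",
                               call. = FALSE)
  # detection: first visit >= onset (Inf when onset is beyond the last visit)
  idx <- findInterval(true_onset, visit_schedule, left.open = TRUE) + 1L
  detect <- ifelse(idx > length(visit_schedule), Inf, visit_schedule[idx])
  admin <- stats::runif(n, censoring$admin_min, censoring$admin_max)
  drop_t <- if (censoring$dropout_rate > 0) {
    stats::rexp(n, censoring$dropout_rate)
  } else {
    rep(Inf, n)
  }
  raw_c <- pmin(admin, drop_t)
  # snap to the last attended visit; everyone attends the first follow-up
  snap_idx <- findInterval(raw_c, post)
  censor <- post[pmax(snap_idx, 1L)]
  D <- as.integer(detect <= censor)
  X <- pmin(detect, censor)
  data.frame(X = X, D = D, detect_time = detect, censor_time = censor)
}

#' Generate a synthetic cohort
#'
#' @param config a [cohort_config()].
#' @return an object of class `dl_cohort`: a list with
#'   `subjects` (data.frame: `id`, `arm`, `age_group`, `gender`, `bmi_group`,
#'   `smoking`, `race`, `X`, `D`, `true_onset`) and
#'   `labs` (data.frame: `id`, `time`, `glucose`, `hba1c`; one row per
#'   attended visit up to and including exit, with baseline HbA1c set to `NA`
#'   for the configured missing fraction). Latent onset times are retained in
#'   `true_onset` for simulation diagnostics only and are never used by the
#'   estimation code.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_subjects
  if (n == 0L) {
    return(new_cohort(
      subjects = data.frame(id = integer(0), arm = character(0),
                            age_group = character(0), gender = character(0),
                            bmi_group = character(0), smoking = character(0),
                            race = character(0), X = numeric(0),
                            D = integer(0), true_onset = numeric(0)),
      labs = data.frame(id = integer(0), time = numeric(0),
                        glucose = numeric(0), hba1c = numeric(0))
    ))
  }

  draw_cat <- function(p) names(p)[
    sample.int(length(p), n, replace = TRUE, prob = p)]
  fq <- config$covariate_freqs
  subjects <- data.frame(
    id = seq_len(n),
    arm = config$arm,
    age_group = draw_cat(fq$age_group),
    gender = draw_cat(fq$gender),
    bmi_group = draw_cat(fq$bmi_group),
    smoking = draw_cat(fq$smoking),
    race = draw_cat(fq$race),
    stringsAsFactors = FALSE
  )

  baseline <- data.frame(
    glucose = rtruncnorm_lower(n, config$glucose_baseline[["mean"]],
                               config$glucose_baseline[["sd"]]),
    hba1c = rtruncnorm_lower(n, config$hba1c_baseline[["mean"]],
                             config$hba1c_baseline[["sd"]])
  )
  labs <- simulate_biomarker_paths(baseline, config$visit_schedule,
                                   config$drift)

  k <- length(config$visit_schedule)
  Gm <- matrix(labs$glucose, nrow = n, ncol = k, byrow = TRUE)
  Hm <- matrix(labs$hba1c, nrow = n, ncol = k, byrow = TRUE)
  rate <- segment_rate_matrix(config$hazard, config$visit_schedule, Gm, Hm)
  onset <- pc_hazard_onset(rate, config$visit_schedule)
  obs <- apply_censoring_and_detection(onset, config$visit_schedule,
                                       config$censoring)
  subjects$X <- obs$X
  subjects$D <- obs$D
  subjects$true_onset <- onset

  # labs observed only at attended visits (time <= X)
  labs <- labs[labs$time <= subjects$X[labs$id], , drop = FALSE]
  rownames(labs) <- NULL

  # missing baseline HbA1c fraction (exclusion-path exercise)
  miss <- stats::runif(n) < config$missing_baseline_hba1c
  if (any(miss)) {
    labs$hba1c[labs$time == 0 & labs$id %in% which(miss)] <- NA_real_
  }
  new_cohort(subjects = subjects, labs = labs)
}

new_cohort <- function(subjects, labs) {
  structure(list(subjects = subjects, labs = labs), class = "dl_cohort")
}

#' @export
print.dl_cohort <- function(x, ...) {
  cat("<dl_cohort> n =", nrow(x$subjects),
      "| events =", sum(x$subjects$D),
      "| lab rows =", nrow(x$labs), "\n")
  invisible(x)
}
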