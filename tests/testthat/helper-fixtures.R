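# Shared fixtures and independent oracles. Everything here is built in code;
# oracles are deliberately naive (grid search, exhaustive enumeration, hand
# arithmetic) and independent of the implementation paths they check.

# --- 5-subject Cox fixture (distinct event times, no ties) -----------------
# z chosen so the partial likelihood has an interior maximum (early event on
# a low covariate value, late event on a high one)
fix5 <- function() {
  data.frame(
    time = c(1, 2, 3, 4, 5),
    status = c(1, 1, 0, 1, 0),
    z = c(0, 1, 1, 2, 0)
  )
}

# log partial likelihood of the fix5 data at coefficient beta (no ties, so
# Efron and Breslow coincide); works for any single-covariate tie-free data
log_partial_likelihood <- function(beta, data) {
  ev <- which(data$status == 1)
  sum(vapply(ev, function(i) {
    at_risk <- data$time >= data$time[i]
    beta * data$z[i] - log(sum(exp(beta * data$z[at_risk])))
  }, numeric(1)))
}

# dense grid-search maximizer of the partial likelihood, to 1e-3
grid_search_beta <- function(data, lo = -5, hi = 5, by = 1e-3) {
  grid <- seq(lo, hi, by = by)
  ll <- vapply(grid, log_partial_likelihood, numeric(1), data = data)
  grid[which.max(ll)]
}

# hand/brute-force Breslow cumulative hazard at the event times
breslow_oracle <- function(data, beta) {
  et <- sort(unique(data$time[data$status == 1]))
  vapply(et, function(tk) {
    sum(data$status == 1 & data$time == tk) /
      sum(exp(beta * data$z[data$time >= tk]))
  }, numeric(1))
}

# --- toy 7-subject cohort for landmark-frame tests -------------------------
toy_cohort <- function() {
  subjects <- data.frame(
    id = 1:7,
    arm = "placebo",
    X = c(0.5, 1.0, 3.0, 2.0, 5.0, 4.0, 4.0),
    D = c(1L, 0L, 1L, 1L, 0L, 0L, 0L),
    stringsAsFactors = FALSE
  )
  labs <- rbind(
    data.frame(id = 1, time = 0, glucose = 99, hba1c = 5.4),
    data.frame(id = 2, time = c(0, 0.5, 1.0), glucose = c(101, 102, 103),
               hba1c = c(5.5, 5.5, 5.6)),
    data.frame(id = 3, time = c(0, 0.5, 1.0), glucose = c(100, 105, 110),
               hba1c = c(5.5, 5.6, 5.8)),
    data.frame(id = 4, time = c(0, 0.5), glucose = c(95, 100),
               hba1c = c(5.0, 5.2)),
    data.frame(id = 5, time = c(0, 1.0), glucose = c(108, 108),
               hba1c = c(6.0, 6.0)),
    data.frame(id = 6, time = c(0, 0.5, 1.0), glucose = c(120, 118, 121),
               hba1c = c(6.5, 6.3, 6.6)),
    data.frame(id = 7, time = 0, glucose = 100, hba1c = NA)
  )
  dlpred:::new_cohort(subjects = subjects, labs = labs)
}

labs_spec <- function(changes = FALSE) {
  dpp_covariate_spec(include_changes = changes, labs_only = TRUE)
}

# --- exhaustive unweighted metric oracles (uncensored data) ----------------
auc_oracle <- function(p, event) {
  cases <- which(event == 1)
  ctrls <- which(event == 0)
  s <- 0
  for (i in cases) for (j in ctrls) {
    s <- s + (p[i] < p[j]) + 0.5 * (p[i] == p[j])
  }
  s / (length(cases) * length(ctrls))
}

nri_oracle <- function(risk_new, risk_old, event) {
  pc <- function(sel) {
    up <- 100 * mean(risk_new[sel] > risk_old[sel])
    down <- 100 * mean(risk_new[sel] < risk_old[sel])
    c(up = up, down = down)
  }
  ev <- pc(event == 1)
  ne <- pc(event == 0)
  list(up_event = ev[["up"]], down_event = ev[["down"]],
       up_nonevent = ne[["up"]], down_nonevent = ne[["down"]])
}

# uncensored frame (every subject observed to event or past tau)
uncensored_frame <- function(time, event, tau, t0 = 0) {
  # event == 1: event at `time` (<= tau); event == 0: followed past tau
  data.frame(id = seq_along(time), time = time, status = as.integer(event))
}

# small deterministic PH cohort config for recovery tests: single effective
# covariate (standardized glucose), no drift, near-continuous detection
recovery_config <- function(n, seed, beta = log(1.5)) {
  hz <- default_hazard()
  hz$coef <- c(glucose = beta, hba1c = 0)
  hz$coef_change <- c(glucose = 0, hba1c = 0)
  hz$centers <- c(glucose = 10, hba1c = 5.91)
  hz$use <- "baseline"
  hz$lambda_base <- 0.12
  dr <- default_drift()
  dr$glucose[c("mean", "sd_increment", "sd_between")] <- list(0, 0, 0)
  dr$hba1c[c("mean", "sd_increment", "sd_between")] <- list(0, 0, 0)
  cohort_config(
    n_subjects = n, glucose_baseline = c(mean = 10, sd = 1),
    hazard = hz, drift = dr,
    visit_schedule = seq(0, 8, by = 0.25),
    censoring = list(admin_min = 4, admin_max = 8, dropout_rate = 0.01),
    missing_baseline_hba1c = 0, seed = seed
  )
}
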