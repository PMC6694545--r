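#' @title Landmark risk sets and dynamic / static predictions
#' @description Builds the risk set at a landmark time `t0` with
#'   change-from-baseline lab covariates, fits the updated (landmark) Cox
#'   model, and produces predicted survival probabilities to `tau = t0 +
#'   horizon` from both the dynamic landmark model and the static baseline
#'   model evaluated with current lab values.
#' @name landmarking
NULL

#' Last lab values at or before a landmark time
#'
#' Carry-forward extraction: returns the most recent `(glucose, hba1c)` pair
#' measured at or before `t0`; `NA` when no measurement exists at or before
#' `t0`.
#'
#' @param labs data.frame `(time, glucose, hba1c)` for one subject, sorted by
#'   time.
#' @param t0 landmark time in years.
#' @return named list `glucose`, `hba1c`, `time` (measurement time; `NA` if
#'   none).
#' @export
extract_current_labs <- function(labs, t0) {
  ok <- which(labs$time <= t0)
  if (length(ok) == 0L) {
    return(list(glucose = NA_real_, hba1c = NA_real_, time = NA_real_))
  }
  i <- ok[length(ok)]
  list(glucose = labs$glucose[i], hba1c = labs$hba1c[i], time = labs$time[i])
}

# vectorized carry-forward over the whole cohort (data.table backend)
labs_carry_forward <- function(labs, t0) {
  dt <- data.table::as.data.table(labs)[time <= t0]
  if (nrow(dt) == 0L) {
    return(data.frame(id = integer(0), time = numeric(0),
                      glucose = numeric(0), hba1c = numeric(0)))
  }
  data.table::setorderv(dt, c("id", "time"))
  as.data.frame(dt[, utils::tail(.SD, 1L), by = "id"])
}

#' Build a landmark frame
#'
#' The risk set at landmark time `t0`: exactly the subjects still event-free
#' and under observation past `t0` (`X > t0`), with covariate vector
#' `Z(t0)` = baseline categoricals + baseline labs + change-from-baseline
#' labs (current minus baseline, current = last measurement at or before
#' `t0`). Excluded subjects are logged with a reason: `event_before_landmark`,
#' `censored_before_landmark`, or `missing_baseline_lab`.
#'
#' At `t0 = 0` the change covariates are identically zero and the frame is
#' the full cohort minus missing-baseline-lab exclusions.
#'
#' @param cohort a `dl_cohort` (see [generate_cohort()] / [read_cohort()]).
#' @param t0 landmark time, years (>= 0).
#' @param horizon prediction window `t`, years; predictions target
#'   `tau = t0 + horizon`.
#' @param spec covariate spec for the dynamic model; defaults to
#'   [dpp_covariate_spec()] with change terms.
#' @return object of class `landmark_frame`: list with `t0`, `horizon`,
#'   `tau`, `spec`, `data` (data.frame: `id`, `time` = X, `status` = D,
#'   covariate columns incl. `glucose_b`, `hba1c_b`, `glucose_chg`,
#'   `hba1c_chg`, and current labs `glucose_cur`, `hba1c_cur`), and
#'   `excluded` (data.frame `id`, `reason`).
#' @export
build_landmark_frame <- function(cohort, t0, horizon,
                                 spec = dpp_covariate_spec(include_changes = TRUE)) {
  stopifnot(inherits(cohort, "dl_cohort"), t0 >= 0, horizon > 0)
  sub <- cohort$subjects
  base <- labs_carry_forward(cohort$labs, 0)
  cur <- labs_carry_forward(cohort$labs, t0)

  base_g <- base$glucose[match(sub$id, base$id)]
  base_h <- base$hba1c[match(sub$id, base$id)]
  cur_g <- cur$glucose[match(sub$id, cur$id)]
  cur_h <- cur$hba1c[match(sub$id, cur$id)]

  reason <- rep(NA_character_, nrow(sub))
  reason[is.na(base_g) | is.na(base_h)] <- "missing_baseline_lab"
  gone <- is.na(reason) & sub$X <= t0
  reason[gone & sub$D == 1] <- "event_before_landmark"
  reason[gone & sub$D == 0] <- "censored_before_landmark"
  reason[is.na(reason) & (is.na(cur_g) | is.na(cur_h))] <- "missing_labs"

  keep <- is.na(reason)
  if (!any(keep)) stop("empty risk set at t0 = ", t0, call. = FALSE)

  data <- data.frame(
    id = sub$id[keep],
    arm = sub$arm[keep],
    time = sub$X[keep],
    status = as.integer(sub$D[keep]),
    sub[keep, intersect(c("age_group", "gender", "bmi_group", "smoking",
                          "race"), names(sub)), drop = FALSE],
    glucose_b = base_g[keep],
    hba1c_b = base_h[keep],
    glucose_cur = cur_g[keep],
    hba1c_cur = cur_h[keep],
    stringsAsFactors = FALSE
  )
  data$glucose_chg <- data$glucose_cur - data$glucose_b
  data$hba1c_chg <- data$hba1c_cur - data$hba1c_b
  rownames(data) <- NULL

  structure(
    list(t0 = t0, horizon = horizon, tau = t0 + horizon, spec = spec,
         data = data,
         excluded = data.frame(id = sub$id[!keep],
                               reason = reason[!keep],
                               stringsAsFactors = FALSE)),
    class = "landmark_frame"
  )
}

#' @export
print.landmark_frame <- function(x, ...) {
  cat("<landmark_frame> t0 =", x$t0, "| tau =", x$tau,
      "| n =", nrow(x$data), "| events =", sum(x$data$status),
      "| excluded =", nrow(x$excluded), "\n")
  invisible(x)
}

# row subset of a frame by subject id (train/test splitting)
frame_subset <- function(frame, ids) {
  out <- frame
  out$data <- frame$data[frame$data$id %in% ids, , drop = FALSE]
  out
}

#' Fit the dynamic landmark Cox model on a frame
#'
#' Delegates to [fit_cox()] with the frame's risk set (all subjects have
#' `X > t0`, so the plain partial likelihood on the frame coincides with the
#' left-truncated one). The returned fit carries `t0` and a baseline
#' cumulative hazard that is 0 at and before `t0`. Change covariates that are
#' constant on the frame (identically zero at `t0 = 0`, or under a drift-free
#' generator) are dropped and recorded, which makes the `t0 = 0` landmark
#' fit coincide with the static baseline fit exactly.
#'
#' @param frame a [build_landmark_frame()] result.
#' @param ties_method passed to [fit_cox()].
#' @return a `cox_fit` with the frame's `t0`.
#' @export
fit_landmark_model <- function(frame, ties_method = "efron") {
  stopifnot(inherits(frame, "landmark_frame"))
  if (sum(frame$data$status) == 0) {
    stop("no events in risk set after t0 = ", frame$t0, call. = FALSE)
  }
  fit_cox(frame$data, spec = frame$spec, ties_method = ties_method,
          t0 = frame$t0)
}

#' Dynamic landmark predictions
#'
#' `p_D = exp(-Lambda0(tau | t0) * exp(alpha' Z(t0)))` for every subject in
#' the frame.
#'
#' @param fit a landmark `cox_fit` with `fit$t0 == frame$t0`.
#' @param frame the landmark frame to predict for.
#' @param tau prediction time; defaults to the frame's `tau`.
#' @return data.frame `(id, t0, tau, model, p_hat)` with `model = "dynamic"`.
#' @export
predict_dynamic <- function(fit, frame, tau = frame$tau) {
  stopifnot(inherits(fit, "cox_fit"), inherits(frame, "landmark_frame"))
  if (!isTRUE(all.equal(fit$t0, frame$t0))) {
    stop("fit and frame have different landmark times", call. = FALSE)
  }
  p <- predict_survival(fit, frame$data, tau)
  data.frame(id = frame$data$id, t0 = frame$t0, tau = tau,
             model = "dynamic", p_hat = as.numeric(p),
             stringsAsFactors = FALSE)
}

#' Static-model predictions at a landmark
#'
#' Mirrors current practice with a single baseline model: the static fit's
#' coefficients are applied to a covariate vector whose baseline lab values
#' are replaced by the labs measured at `t0`, and the *unconditional*
#' survival `P(T > tau | Z)` is reported even though the subject is known to
#' have survived to `t0`. Set `conditional = TRUE` for the algebraic
#' conditional variant `P(T > tau | T > t0, Z)` (see
#' [conditional_survival_static()]); this variant is exposed for completeness
#' but is not the default comparator.
#'
#' @param static_fit a `cox_fit` with `t0 = 0`.
#' @param frame the landmark frame to predict for.
#' @param tau prediction time; defaults to the frame's `tau`.
#' @param conditional use the conditional-survival transformation.
#' @return data.frame `(id, t0, tau, model, p_hat)` with `model = "static"`.
#' @export
predict_static_at_landmark <- function(static_fit, frame, tau = frame$tau,
                                       conditional = FALSE) {
  stopifnot(inherits(static_fit, "cox_fit"), inherits(frame, "landmark_frame"))
  if (static_fit$t0 != 0) {
    stop("the static model must be a baseline (t0 = 0) fit", call. = FALSE)
  }
  newdata <- frame$data
  newdata$glucose_b <- newdata$glucose_cur
  newdata$hba1c_b <- newdata$hba1c_cur
  p <- if (conditional) {
    conditional_survival_static(static_fit, newdata, frame$t0, tau)
  } else {
    predict_survival(static_fit, newdata, tau)
  }
  data.frame(id = frame$data$id, t0 = frame$t0, tau = tau,
             model = "static", p_hat = as.numeric(p),
             stringsAsFactors = FALSE)
}
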