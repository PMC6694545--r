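#' @title Censoring-robust accuracy metrics
#' @description Inverse-probability-of-censoring-weighted (IPCW) estimators
#'   of discrimination (AUC), calibration (Brier score, survival
#'   Hosmer-Lemeshow), and reclassification (NRI) for survival predictions at
#'   `(tau, t0)`. All metrics consume predicted *survival* probabilities;
#'   "higher risk" always means lower `p_hat`, and the risk conversion
#'   `1 - p_hat` happens only inside this module.
#' @name accuracy_metrics
NULL

new_accuracy_estimate <- function(metric, value, t0, tau, model_tag = NA,
                                  n_eff = NA_real_, ci = NULL,
                                  p_value = NULL) {
  structure(
    list(metric = metric, value = value, t0 = t0, tau = tau,
         model_tag = model_tag, n_eff = n_eff, ci = ci, p_value = p_value),
    class = "accuracy_estimate"
  )
}

#' @export
print.accuracy_estimate <- function(x, ...) {
  cat("<accuracy_estimate>", x$metric,
      if (!is.na(x$model_tag)) paste0("[", x$model_tag, "]"),
      "t0 =", x$t0, "tau =", x$tau, ":", format(x$value, digits = 4), "\n")
  if (!is.null(x$ci)) cat("  95% CI:", format(x$ci, digits = 4), "\n")
  if (!is.null(x$p_value)) cat("  p =", format(x$p_value, digits = 3), "\n")
  invisible(x)
}

#' Kaplan-Meier estimator of the censoring survival function
#'
#' Treats censoring as the event (`1 - D`); the resulting step function
#' `G(t) = P(C > t)` feeds the IPCW weights. Estimation is done within
#' whatever stratum (typically a treatment arm) the frame represents.
#'
#' @param frame a landmark frame or data.frame with `time` and `status`.
#' @return a [step_function()] equal to 1 before the first censoring time.
#' @export
censoring_km <- function(frame) {
  data <- if (inherits(frame, "landmark_frame")) frame$data else frame
  stopifnot(nrow(data) > 0L)
  sf <- survival::survfit(survival::Surv(data$time, 1 - data$status) ~ 1)
  keep <- sf$n.event > 0
  step_function(sf$time[keep], sf$surv[keep], before = 1)
}

#' IPCW weights for a (tau, t0) evaluation
#'
#' Events in `(t0, tau]` receive weight `G(t0)/G(X)`, survivors past `tau`
#' receive `G(t0)/G(tau)`, and subjects censored within the window receive 0.
#' Weights where the relevant `G` evaluates to 0 are set to 0 with a warning.
#'
#' @param frame landmark frame or data.frame with `time`, `status`.
#' @param tau prediction time.
#' @param t0 landmark time.
#' @param G censoring survival [step_function()]; defaults to
#'   [censoring_km()] of the frame.
#' @return numeric weight vector aligned with the frame rows.
#' @export
ipcw_weights <- function(frame, tau, t0 = 0, G = censoring_km(frame)) {
  data <- if (inherits(frame, "landmark_frame")) frame$data else frame
  stopifnot(tau > t0)
  g0 <- sf_eval(G, t0)
  w <- numeric(nrow(data))
  case <- data$status == 1 & data$time > t0 & data$time <= tau
  ctrl <- data$time > tau
  gx <- sf_eval(G, data$time[case])
  gt <- sf_eval(G, tau)
  if (any(gx == 0) || (any(ctrl) && gt == 0)) {
    warning("censoring survival reached 0 inside the evaluation window; ",
            "affected weights set to 0")
  }
  w[case] <- ifelse(gx > 0, g0 / gx, 0)
  w[ctrl] <- if (gt > 0) g0 / gt else 0
  w
}

#' IPCW area under the ROC curve
#'
#' Weighted proportion, over case-control pairs (case: event in `(t0, tau]`;
#' control: survival past `tau`), of pairs in which the case received the
#' lower predicted survival probability; prediction ties count 1/2. Pair
#' weights are the product of the two subjects' IPCW weights.
#'
#' @param predictions numeric vector of predicted survival probabilities
#'   aligned with the frame rows, or a prediction data.frame with `id` and
#'   `p_hat` (matched to the frame by `id`).
#' @param frame landmark frame (or data.frame with `time`, `status`).
#' @param tau,t0 evaluation window.
#' @param G optional censoring survival function.
#' @param model_tag label stored in the result.
#' @return an `accuracy_estimate` with `metric = "auc"`.
#' @export
auc_ipcw <- function(predictions, frame, tau = NULL, t0 = NULL,
                     G = censoring_km(frame), model_tag = NA) {
  e <- metric_inputs(predictions, frame, tau, t0, G)
  case <- e$status == 1 & e$time > e$t0 & e$time <= e$tau
  ctrl <- e$time > e$tau
  if (!any(case & e$w > 0)) stop("no cases in (t0, tau]; AUC undefined",
                                 call. = FALSE)
  if (!any(ctrl & e$w > 0)) stop("no controls past tau; AUC undefined",
                                 call. = FALSE)
  pc <- e$p[case]; wc <- e$w[case]
  pk <- e$p[ctrl]; wk <- e$w[ctrl]
  cmp <- outer(pc, pk, function(a, b) (a < b) + 0.5 * (a == b))
  wt <- outer(wc, wk)
  new_accuracy_estimate("auc", sum(cmp * wt) / sum(wt), e$t0, e$tau,
                        model_tag, n_eff = sum(e$w))
}

#' IPCW Brier score
#'
#' `sum(w_i * (I(T_i > tau) - p_i)^2) / sum(w_i)` over subjects at risk at
#' `t0`, with IPCW weights.
#'
#' @inheritParams auc_ipcw
#' @return an `accuracy_estimate` with `metric = "brier"`.
#' @export
brier_ipcw <- function(predictions, frame, tau = NULL, t0 = NULL,
                       G = censoring_km(frame), model_tag = NA) {
  e <- metric_inputs(predictions, frame, tau, t0, G)
  if (sum(e$w) == 0) stop("total IPCW weight is 0; Brier score undefined",
                          call. = FALSE)
  ind <- as.numeric(e$time > e$tau) # 1 = survived past tau (weight 0 if censored)
  new_accuracy_estimate("brier", sum(e$w * (ind - e$p)^2) / sum(e$w),
                        e$t0, e$tau, model_tag, n_eff = sum(e$w))
}

#' Survival Hosmer-Lemeshow calibration statistic
#'
#' Subjects are partitioned into `g` strata by quantiles of predicted risk
#' `1 - p_hat`. Within each stratum the observed event proportion `O_g` is
#' the IPCW-weighted event fraction and the expected proportion `E_g` is the
#' mean predicted risk; the statistic is
#' `sum_g n_g (O_g - E_g)^2 / (E_g (1 - E_g))` with `n_g` the stratum's
#' effective (total-weight) size, referred to a chi-squared distribution with
#' `g - 1` degrees of freedom. Strata with degenerate `E_g` in `{0, 1}` are
#' skipped with a warning and the degrees of freedom reduced.
#'
#' @inheritParams auc_ipcw
#' @param g number of risk strata (default 5).
#' @return an `accuracy_estimate` with `metric = "hl"`, `p_value` attached,
#'   and attribute `df`.
#' @export
hl_statistic <- function(predictions, frame, tau = NULL, t0 = NULL, g = 5,
                         G = censoring_km(frame), model_tag = NA) {
  e <- metric_inputs(predictions, frame, tau, t0, G)
  risk <- 1 - e$p
  if (length(unique(risk)) < g) {
    stop("fewer than g = ", g, " distinct prediction values", call. = FALSE)
  }
  keep <- e$w > 0
  risk <- risk[keep]; w <- e$w[keep]
  ev <- as.numeric(e$status[keep] == 1 & e$time[keep] > e$t0 &
                     e$time[keep] <= e$tau)
  breaks <- unique(stats::quantile(risk, probs = seq(0, 1, length.out = g + 1)))
  if (length(breaks) < 3L) stop("predictions too discrete to stratify",
                                call. = FALSE)
  stratum <- cut(risk, breaks, include.lowest = TRUE)
  stat <- 0
  used <- 0L
  for (lv in levels(stratum)) {
    s <- stratum == lv
    if (!any(s)) next
    n_g <- sum(w[s])
    O_g <- sum(w[s] * ev[s]) / n_g
    E_g <- mean(risk[s])
    if (E_g <= 0 || E_g >= 1) {
      warning("Hosmer-Lemeshow stratum with degenerate expected risk ",
              "skipped; degrees of freedom reduced")
      next
    }
    stat <- stat + n_g * (O_g - E_g)^2 / (E_g * (1 - E_g))
    used <- used + 1L
  }
  if (used < 2L) stop("too few usable strata for the Hosmer-Lemeshow test",
                      call. = FALSE)
  df <- used - 1L
  out <- new_accuracy_estimate("hl", stat, e$t0, e$tau, model_tag,
                               n_eff = sum(w),
                               p_value = chisq_pvalue(stat, df))
  attr(out, "df") <- df
  out
}

#' Upper-tail chi-squared p-value
#'
#' @param stat non-negative test statistic.
#' @param df degrees of freedom (>= 1).
#' @return `P(chi^2_df >= stat)`.
#' @export
chisq_pvalue <- function(stat, df) {
  if (!is.numeric(df) || df < 1) stop("`df` must be >= 1", call. = FALSE)
  if (!is.numeric(stat) || any(stat < 0)) {
    stop("`stat` must be >= 0", call. = FALSE)
  }
  stats::pchisq(stat, df = df, lower.tail = FALSE)
}

#' Net reclassification components
#'
#' Category-free (continuous) NRI components comparing the dynamic model
#' against the static model. Among events in `(t0, tau]`: the IPCW-weighted
#' percentage whose dynamic risk `1 - p_D` is strictly higher than their
#' static risk (`up_event`) and strictly lower (`down_event`); likewise among
#' survivors past `tau` (`up_nonevent`, `down_nonevent`). Exact prediction
#' ties are excluded from both directions and reported separately, so each
#' group's components sum to at most 100.
#'
#' @param pred_dynamic,pred_static predicted survival probabilities (vectors
#'   aligned with the frame, or prediction data.frames with `id`, `p_hat`).
#' @inheritParams auc_ipcw
#' @return list with `up_event`, `down_event`, `up_nonevent`,
#'   `down_nonevent`, `tie_event`, `tie_nonevent` (percentages) and `nri`
#'   (combined, via [combine_nri()]).
#' @export
nri_components <- function(pred_dynamic, pred_static, frame, tau = NULL,
                           t0 = NULL, G = censoring_km(frame)) {
  d <- metric_inputs(pred_dynamic, frame, tau, t0, G)
  s <- metric_inputs(pred_static, frame, tau, t0, G)
  risk_d <- 1 - d$p
  risk_s <- 1 - s$p
  case <- d$status == 1 & d$time > d$t0 & d$time <= d$tau
  ctrl <- d$time > d$tau
  if (!any(case & d$w > 0)) stop("no events in (t0, tau]; NRI undefined",
                                 call. = FALSE)
  if (!any(ctrl & d$w > 0)) stop("no non-events past tau; NRI undefined",
                                 call. = FALSE)
  pct <- function(sel) {
    w <- d$w[sel]
    total <- sum(w)
    up <- min(100, 100 * sum(w * (risk_d[sel] > risk_s[sel])) / total)
    down <- min(100, 100 * sum(w * (risk_d[sel] < risk_s[sel])) / total)
    tie <- max(0, 100 - up - down)
    c(up = up, down = down, tie = tie)
  }
  ev <- pct(case)
  ne <- pct(ctrl)
  list(up_event = ev[["up"]], down_event = ev[["down"]],
       up_nonevent = ne[["up"]], down_nonevent = ne[["down"]],
       tie_event = ev[["tie"]], tie_nonevent = ne[["tie"]],
       nri = combine_nri(ev[["up"]], ev[["down"]], ne[["up"]], ne[["down"]]))
}

#' Combine NRI components
#'
#' `(up_event - down_event) - (up_nonevent - down_nonevent)`: the net
#' percentage of events moved toward higher risk plus the net percentage of
#' non-events moved toward lower risk.
#'
#' @param up_event,down_event percentages of events whose risk the new model
#'   moved up / down.
#' @param up_nonevent,down_nonevent the same among non-events.
#' @return combined NRI in percentage points.
#' @export
combine_nri <- function(up_event, down_event, up_nonevent, down_nonevent) {
  comp <- c(up_event, down_event, up_nonevent, down_nonevent)
  tol <- 1e-8 # floating-point slack from weighted-percentage arithmetic
  if (any(comp < -tol | comp > 100 + tol)) {
    stop("NRI components must be percentages in [0, 100]", call. = FALSE)
  }
  comp <- pmin(pmax(comp, 0), 100)
  (comp[1L] - comp[2L]) - (comp[3L] - comp[4L])
}

# normalizes metric inputs: aligns predictions with frame rows, resolves
# (tau, t0), computes weights
metric_inputs <- function(predictions, frame, tau, t0, G) {
  data <- if (inherits(frame, "landmark_frame")) frame$data else frame
  if (is.null(t0)) {
    t0 <- if (inherits(frame, "landmark_frame")) frame$t0 else 0
  }
  if (is.null(tau)) {
    if (!inherits(frame, "landmark_frame")) {
      stop("`tau` is required", call. = FALSE)
    }
    tau <- frame$tau
  }
  if (is.data.frame(predictions)) {
    idx <- match(data$id, predictions$id)
    if (anyNA(idx)) stop("predictions do not cover all frame rows",
                         call. = FALSE)
    p <- predictions$p_hat[idx]
  } else {
    if (length(predictions) != nrow(data)) {
      stop("prediction vector length must match the frame", call. = FALSE)
    }
    p <- as.numeric(predictions)
  }
  if (any(p < 0 | p > 1)) stop("predictions must lie in [0, 1]",
                               call. = FALSE)
  w <- ipcw_weights(data, tau, t0, G)
  list(p = p, w = w, time = data$time, status = data$status,
       tau = tau, t0 = t0)
}
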