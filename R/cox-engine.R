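#' @title Cox proportional hazards engine
#' @description Partial-likelihood fitting (delegated to the survival
#'   package), Breslow baseline cumulative hazard, absolute survival
#'   predictions, and the conditional-survival transformation used by the
#'   static comparator. Fits are performed on internally centered covariates
#'   for numerical stability; the stored baseline hazard refers to the
#'   centering point and predictions are invariant to it.
#' @name cox_engine
NULL

new_cox_fit <- function(coefficients, vcov, baseline_cumhaz, spec, centers,
                        t0 = 0, ties_method = "efron", n = NA_integer_,
                        n_events = NA_integer_, dropped = character()) {
  structure(
    list(coefficients = coefficients, vcov = vcov,
         baseline_cumhaz = baseline_cumhaz, spec = spec, centers = centers,
         t0 = t0, ties_method = ties_method, n = n, n_events = n_events,
         dropped = dropped),
    class = "cox_fit"
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("<cox_fit> t0 =", x$t0, "| n =", x$n, "| events =", x$n_events,
      "| ties =", x$ties_method, "\n")
  print(round(x$coefficients, 4))
  if (length(x$dropped)) {
    cat("dropped (constant) terms:", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

# linear predictor on the fit's centered scale, for rows of `data`
cox_lp <- function(fit, data) {
  x <- build_model_matrix(fit$spec, data)
  terms <- names(fit$coefficients)
  x <- x[, terms, drop = FALSE]
  drop(sweep(x, 2L, fit$centers, "-") %*% fit$coefficients)
}

#' Fit a Cox proportional hazards model
#'
#' Maximizes the Cox partial likelihood on a landmark frame (or a plain
#' data.frame with `time` and `status` columns) and attaches the Breslow
#' baseline cumulative hazard. For a landmark fit (`t0 > 0`) only subjects
#' with `time > t0` may be present and the baseline cumulative hazard is zero
#' at and before `t0`.
#'
#' Design-matrix columns that are constant (e.g. change-from-baseline labs at
#' the baseline landmark, which are identically zero) are unidentifiable and
#' are dropped; their names are recorded in the fit's `dropped` field.
#'
#' @param frame a [build_landmark_frame()] result, or a data.frame with
#'   columns `time`, `status` plus the covariates named by `spec`.
#' @param spec a [covariate_spec()]; defaults to the frame's own spec.
#' @param ties_method `"efron"` (default) or `"breslow"`. Interval detection
#'   at scheduled visits creates heavy ties, so the Efron approximation is the
#'   sensible default.
#' @param t0 landmark time; taken from `frame` when it is a landmark frame.
#' @return an object of class `cox_fit` with elements `coefficients`, `vcov`,
#'   `baseline_cumhaz` (a [step_function()]), `spec`, `centers`, `t0`,
#'   `ties_method`, `n`, `n_events`, `dropped`.
#' @export
fit_cox <- function(frame, spec = NULL, ties_method = c("efron", "breslow"),
                    t0 = NULL) {
  ties_method <- match.arg(ties_method)
  if (inherits(frame, "landmark_frame")) {
    data <- frame$data
    if (is.null(spec)) spec <- frame$spec
    if (is.null(t0)) t0 <- frame$t0
  } else {
    data <- frame
    if (is.null(spec)) stop("`spec` is required for plain data input",
                            call. = FALSE)
    if (is.null(t0)) t0 <- 0
  }
  stopifnot(is.data.frame(data), all(c("time", "status") %in% names(data)))
  if (nrow(data) == 0L) stop("empty risk set", call. = FALSE)
  if (sum(data$status) == 0) stop("no events in risk set", call. = FALSE)
  if (any(data$time <= t0)) {
    stop("all subjects in a landmark fit must have time > t0", call. = FALSE)
  }

  x <- build_model_matrix(spec, data)
  if (ncol(x) == 0L) stop("covariate specification produces no terms",
                          call. = FALSE)
  const <- apply(x, 2L, function(col) max(col) == min(col))
  dropped <- colnames(x)[const]
  x <- x[, !const, drop = FALSE]
  if (ncol(x) == 0L) {
    stop("all covariate columns are constant; model is unidentifiable",
         call. = FALSE)
  }
  centers <- colMeans(x)
  xc <- sweep(x, 2L, centers, "-")

  y <- survival::Surv(data$time, data$status)
  warn <- NULL
  cf <- withCallingHandlers(
    survival::coxph.fit(xc, y, strata = NULL, offset = NULL, init = NULL,
                        control = survival::coxph.control(eps = 1e-9,
                                                          iter.max = 100),
                        weights = NULL,
                        method = ties_method,
                        rownames = rownames(xc)),
    warning = function(w) {
      warn <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    }
  )
  beta <- cf$coefficients
  names(beta) <- colnames(xc)
  if (anyNA(beta) || any(!is.finite(beta))) {
    bad <- colnames(xc)[!is.finite(beta) | is.na(beta)]
    stop("Cox fit failed (non-finite coefficient) for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  se <- sqrt(diag(as.matrix(cf$var)))
  if (any(abs(beta) > 25) || any(!is.finite(se))) {
    bad <- colnames(xc)[abs(beta) > 25 | !is.finite(se)]
    stop("monotone likelihood / possible separation in covariate(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(warn) && grepl("did not converge", warn, fixed = TRUE)) {
    stop("Cox partial likelihood did not converge: ", warn, call. = FALSE)
  }
  vc <- as.matrix(cf$var)
  dimnames(vc) <- list(names(beta), names(beta))

  fit <- new_cox_fit(
    coefficients = beta, vcov = vc, baseline_cumhaz = NULL, spec = spec,
    centers = centers, t0 = t0, ties_method = ties_method,
    n = nrow(data), n_events = as.integer(sum(data$status)),
    dropped = dropped
  )
  eta <- drop(xc %*% beta)
  fit$baseline_cumhaz <- breslow_steps(data$time, data$status, eta, t0)
  fit
}

# Breslow estimator from raw ingredients:
#   Lambda0(t) = sum_{event times tk <= t, tk > t0} d_k / sum_{X_j >= tk} exp(eta_j)
breslow_steps <- function(time, status, eta, t0 = 0) {
  ev <- status == 1 & time > t0
  if (!any(ev)) return(step_function(numeric(0), numeric(0), before = 0))
  et <- sort(unique(time[ev]))
  risk <- exp(eta)
  denom <- vapply(et, function(tk) sum(risk[time >= tk]), numeric(1))
  d <- vapply(et, function(tk) sum(time[ev] == tk), numeric(1))
  step_function(et, cumsum(d / denom), before = 0)
}

#' Breslow baseline cumulative hazard of a fitted Cox model
#'
#' Recomputes the Breslow step function from a fit and the frame it was (or
#' could have been) fit on. For landmark fits, event times and risk sets are
#' restricted to `t > t0` and the estimate is 0 at and before `t0`.
#'
#' @param fit a `cox_fit`.
#' @param frame a landmark frame or data.frame with `time`, `status` and the
#'   spec's covariate columns.
#' @return a [step_function()].
#' @export
breslow_cumhaz <- function(fit, frame) {
  data <- if (inherits(frame, "landmark_frame")) frame$data else frame
  eta <- cox_lp(fit, data)
  breslow_steps(data$time, data$status, eta, fit$t0)
}

#' Predicted survival probability
#'
#' Evaluates `exp(-Lambda0(tau) * exp(beta'z))` for each row of `newdata`.
#' When `tau` lies beyond the last observed event time the cumulative hazard
#' is clamped at its final value and the result carries an `extrapolated`
#' attribute.
#'
#' @param fit a `cox_fit`.
#' @param newdata data.frame of covariate values (spec columns).
#' @param tau prediction time (scalar, study clock).
#' @return numeric vector of survival probabilities in `[0, 1]`, with
#'   attribute `extrapolated` (logical scalar).
#' @export
predict_survival <- function(fit, newdata, tau) {
  stopifnot(inherits(fit, "cox_fit"), length(tau) == 1L, tau >= 0)
  eta <- cox_lp(fit, newdata)
  lam <- sf_eval(fit$baseline_cumhaz, tau)
  p <- exp(-lam * exp(eta))
  attr(p, "extrapolated") <- tau > sf_last_knot(fit$baseline_cumhaz)
  p
}

#' Conditional survival from the static model
#'
#' The static baseline model implies
#' `P(T > tau | T > t0, Z) = exp(-(Lambda0(tau) - Lambda0(t0)) exp(beta'Z))`;
#' this is the algebraic conditioning of the unconditional prediction, not a
#' refit, and is exposed as a variant of the static comparator.
#'
#' @param fit a `cox_fit` with `t0 = 0`.
#' @param newdata data.frame of covariate values.
#' @param t0 conditioning (landmark) time.
#' @param tau prediction time, `tau >= t0`.
#' @return numeric vector of conditional survival probabilities.
#' @export
conditional_survival_static <- function(fit, newdata, t0, tau) {
  stopifnot(inherits(fit, "cox_fit"))
  if (tau < t0) stop("`tau` must be >= `t0`", call. = FALSE)
  eta <- cox_lp(fit, newdata)
  inc <- sf_eval(fit$baseline_cumhaz, tau) - sf_eval(fit$baseline_cumhaz, t0)
  p <- exp(-inc * exp(eta))
  attr(p, "extrapolated") <- tau > sf_last_knot(fit$baseline_cumhaz)
  p
}

#' Hazard ratio table
#'
#' @param fit a `cox_fit`.
#' @param level confidence level (default 0.95).
#' @return data.frame with `term`, `hr`, `ci_lo`, `ci_hi`, `p_value` and
#'   significance `stars` (`*` p < 0.05, `***` p < 0.001).
#' @export
hazard_ratio_table <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "cox_fit"))
  se <- sqrt(diag(fit$vcov))
  z <- stats::qnorm(1 - (1 - level) / 2)
  b <- fit$coefficients
  p <- 2 * stats::pnorm(-abs(b / se))
  stars <- ifelse(p < 0.001, "***", ifelse(p < 0.05, "*", ""))
  data.frame(
    term = names(b),
    hr = exp(b),
    ci_lo = exp(b - z * se),
    ci_hi = exp(b + z * se),
    p_value = p,
    stars = stars,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Serialize / restore a Cox fit as JSON
#'
#' @param fit a `cox_fit`.
#' @param path optional file path; when omitted the JSON string is returned.
#' @return `cox_fit_to_json`: JSON string (invisibly, when writing to file);
#'   `cox_fit_from_json`: a `cox_fit`.
#' @export
cox_fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "cox_fit"))
  obj <- list(
    coefficients = as.list(fit$coefficients),
    vcov = fit$vcov,
    centers = as.list(fit$centers),
    baseline_cumhaz = list(knots = fit$baseline_cumhaz$knots,
                           values = fit$baseline_cumhaz$values,
                           before = fit$baseline_cumhaz$before),
    spec = list(factors = fit$spec$factors, numeric = fit$spec$numeric),
    t0 = fit$t0, ties_method = fit$ties_method,
    n = fit$n, n_events = fit$n_events, dropped = fit$dropped
  )
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname cox_fit_to_json
#' @param json JSON string or file path produced by [cox_fit_to_json()].
#' @export
cox_fit_from_json <- function(json) {
  if (length(json) == 1L && file.exists(json)) json <- readLines(json)
  obj <- jsonlite::fromJSON(paste(json, collapse = ""))
  spec <- covariate_spec(factors = as.list(obj$spec$factors),
                         numeric = obj$spec$numeric %||% character())
  vc <- as.matrix(obj$vcov)
  cf <- unlist(obj$coefficients)
  dimnames(vc) <- list(names(cf), names(cf))
  new_cox_fit(
    coefficients = cf,
    vcov = vc,
    baseline_cumhaz = step_function(obj$baseline_cumhaz$knots %||% numeric(0),
                                    obj$baseline_cumhaz$values %||% numeric(0),
                                    obj$baseline_cumhaz$before %||% 0),
    spec = spec,
    centers = unlist(obj$centers),
    t0 = obj$t0, ties_method = obj$ties_method,
    n = obj$n, n_events = obj$n_events,
    dropped = obj$dropped %||% character()
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
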