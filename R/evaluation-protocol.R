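#' @title Evaluation protocol: cross-validation, bootstrap, full study
#' @description Orchestrates the static-vs-dynamic comparison: repeated
#'   2/3-train / 1/3-test splits with metric averaging, subject-level
#'   bootstrap confidence intervals for static-vs-dynamic differences, and
#'   the assembled study report across arms and landmark times.
#' @name evaluation_protocol
NULL

#' Protocol configuration
#'
#' @param t0_list landmark times (years).
#' @param horizon prediction window `t` (years); `tau = t0 + horizon`.
#' @param cv_reps number of random train/test splits.
#' @param cv_train_fraction training fraction per split.
#' @param bootstrap_reps bootstrap resamples for difference CIs (0 disables).
#' @param cv_reps_boot reduced number of CV splits inside each bootstrap
#'   resample (cost control; the estimand, a mean over splits, is unchanged).
#' @param seed base RNG seed for the protocol.
#' @param spec_static,spec_dynamic covariate specs for the two models.
#' @param ties_method tie handling for all Cox fits.
#' @return validated list of class `protocol_config`.
#' @export
protocol_config <- function(t0_list = c(0, 1, 2, 3), horizon = 2,
                            cv_reps = 100, cv_train_fraction = 2 / 3,
                            bootstrap_reps = 500, cv_reps_boot = 10,
                            seed = NULL,
                            spec_static = dpp_covariate_spec(),
                            spec_dynamic = dpp_covariate_spec(include_changes = TRUE),
                            ties_method = "efron") {
  if (cv_train_fraction <= 0 || cv_train_fraction >= 1) {
    stop("`cv_train_fraction` must lie in (0, 1)", call. = FALSE)
  }
  if (cv_reps < 1 || horizon <= 0 || bootstrap_reps < 0 || cv_reps_boot < 1) {
    stop("invalid protocol configuration", call. = FALSE)
  }
  structure(
    list(t0_list = t0_list, horizon = horizon, cv_reps = as.integer(cv_reps),
         cv_train_fraction = cv_train_fraction,
         bootstrap_reps = as.integer(bootstrap_reps),
         cv_reps_boot = as.integer(cv_reps_boot), seed = seed,
         spec_static = spec_static, spec_dynamic = spec_dynamic,
         ties_method = ties_method),
    class = "protocol_config"
  )
}

#' Random train/test split of subject ids
#'
#' @param ids subject identifiers (or a landmark frame, whose ids are used).
#' @param fraction training fraction; training size is `round(n * fraction)`.
#' @return list with `train` and `test` id vectors (disjoint, exhaustive).
#' @export
split_train_test <- function(ids, fraction = 2 / 3) {
  if (inherits(ids, "landmark_frame")) ids <- ids$data$id
  n <- length(ids)
  if (n < 3L) stop("need at least 3 subjects to split", call. = FALSE)
  if (fraction <= 0 || fraction >= 1) {
    stop("`fraction` must lie in (0, 1)", call. = FALSE)
  }
  n_train <- max(1L, min(n - 1L, as.integer(round(n * fraction))))
  train <- sample(ids, n_train)
  list(train = train, test = setdiff(ids, train))
}

# One CV pass at a landmark: fit static (baseline frame) and dynamic
# (landmark frame) on the training ids, predict on the test portion of the
# landmark frame. Returns predictions plus the test frame.
cv_once <- function(frame0, frame_t0, split, config) {
  train0 <- frame_subset(frame0, split$train)
  test_t0 <- frame_subset(frame_t0, split$test)
  if (nrow(test_t0$data) == 0L) stop("empty test risk set", call. = FALSE)
  static_fit <- fit_cox(train0$data, spec = config$spec_static,
                        ties_method = config$ties_method, t0 = 0)
  dyn_fit <- fit_cox(frame_subset(frame_t0, split$train)$data,
                     spec = config$spec_dynamic,
                     ties_method = config$ties_method, t0 = frame_t0$t0)
  list(
    test_frame = test_t0,
    pred_static = predict_static_at_landmark(static_fit, test_t0),
    pred_dynamic = predict_dynamic(dyn_fit, test_t0)
  )
}

# Repeated-split CV of all metrics for both models at one landmark.
# Returns per-rep rows; degenerate reps (no cases/controls in the test set,
# failed fits) are skipped with a warning.
landmark_cv <- function(cohort, t0, config, cv_reps = config$cv_reps,
                        resubstitution = FALSE) {
  frame0 <- build_landmark_frame(cohort, 0, config$horizon + t0,
                                 spec = config$spec_static)
  frame_t0 <- build_landmark_frame(cohort, t0, config$horizon,
                                   spec = config$spec_dynamic)
  ids <- frame0$data$id
  rows <- vector("list", cv_reps)
  skipped <- 0L
  for (r in seq_len(cv_reps)) {
    res <- tryCatch({
      split <- if (resubstitution) list(train = ids, test = ids) else
        split_train_test(ids, config$cv_train_fraction)
      cv <- cv_once(frame0, frame_t0, split, config)
      G <- censoring_km(cv$test_frame)
      auc_s <- auc_ipcw(cv$pred_static, cv$test_frame, G = G)$value
      auc_d <- auc_ipcw(cv$pred_dynamic, cv$test_frame, G = G)$value
      br_s <- brier_ipcw(cv$pred_static, cv$test_frame, G = G)$value
      br_d <- brier_ipcw(cv$pred_dynamic, cv$test_frame, G = G)$value
      hl_s <- hl_statistic(cv$pred_static, cv$test_frame, G = G)$value
      hl_d <- hl_statistic(cv$pred_dynamic, cv$test_frame, G = G)$value
      nri <- nri_components(cv$pred_dynamic, cv$pred_static, cv$test_frame,
                            G = G)
      data.frame(rep = r, auc_static = auc_s, auc_dynamic = auc_d,
                 brier_static = br_s, brier_dynamic = br_d,
                 hl_static = hl_s, hl_dynamic = hl_d,
                 up_event = nri$up_event, down_event = nri$down_event,
                 up_nonevent = nri$up_nonevent,
                 down_nonevent = nri$down_nonevent, nri = nri$nri)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- skipped + 1L
      next
    }
    rows[[r]] <- res
  }
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(rows) || nrow(rows) == 0L) {
    stop("all ", cv_reps, " cross-validation splits were degenerate at t0 = ",
         t0, call. = FALSE)
  }
  if (skipped > 0L) {
    warning(skipped, " of ", cv_reps, " CV splits skipped (degenerate test ",
            "set or failed fit) at t0 = ", t0)
  }
  attr(rows, "skipped") <- skipped
  attr(rows, "n_frame") <- nrow(frame_t0$data)
  attr(rows, "n_excluded") <- nrow(frame_t0$excluded)
  rows
}

#' Cross-validated accuracy metric
#'
#' For each of `cv_reps` random splits: fit both models on the training
#' subjects, predict on the test portion of the landmark risk set, and
#' compute the metric on the test set; the estimate is the mean over splits.
#' Per-rep values are attached for diagnostics.
#'
#' @param cohort a `dl_cohort`.
#' @param t0 landmark time.
#' @param model_kind `"static"` or `"dynamic"`.
#' @param metric `"auc"`, `"brier"` or `"hl"`.
#' @param config a [protocol_config()].
#' @param resubstitution debug mode: every split trains and tests on the full
#'   frame, giving the apparent metric.
#' @return an `accuracy_estimate` with attribute `per_rep`.
#' @export
cross_validated_metric <- function(cohort, t0,
                                   model_kind = c("dynamic", "static"),
                                   metric = c("auc", "brier", "hl"),
                                   config = protocol_config(),
                                   resubstitution = FALSE) {
  model_kind <- match.arg(model_kind)
  metric <- match.arg(metric)
  if (!is.null(config$seed)) set.seed(config$seed)
  reps <- landmark_cv(cohort, t0, config,
                      cv_reps = if (resubstitution) 1L else config$cv_reps,
                      resubstitution = resubstitution)
  col <- paste0(metric, "_", model_kind)
  out <- new_accuracy_estimate(metric, mean(reps[[col]]), t0,
                               t0 + config$horizon, model_kind,
                               n_eff = nrow(reps))
  attr(out, "per_rep") <- reps[[col]]
  out
}

# resample a cohort at the subject level with replacement (new ids 1..n)
resample_cohort <- function(cohort, ids = NULL) {
  sub <- cohort$subjects
  if (is.null(ids)) ids <- sample(sub$id, nrow(sub), replace = TRUE)
  new_sub <- sub[match(ids, sub$id), , drop = FALSE]
  new_sub$id <- seq_along(ids)
  labs_dt <- data.table::as.data.table(cohort$labs)
  pick <- data.table::data.table(old = ids, id_new = seq_along(ids))
  new_labs <- labs_dt[pick, on = c(id = "old"), allow.cartesian = TRUE]
  new_labs$id <- new_labs$id_new
  new_labs$id_new <- NULL
  data.table::setorderv(new_labs, c("id", "time"))
  rownames(new_sub) <- NULL
  new_cohort(subjects = new_sub, labs = as.data.frame(new_labs))
}

#' Bootstrap CI for the dynamic-minus-static metric difference
#'
#' Subject-level resampling with replacement (within the cohort, which
#' represents one arm): each resample re-runs the cross-validation procedure
#' (with `cv_reps_boot` splits) and records the dynamic-minus-static
#' difference; the CI is the 2.5/97.5 percentile interval and the two-sided
#' p-value is derived from the bootstrap distribution's position relative
#' to 0.
#'
#' @param cohort a `dl_cohort` (one arm).
#' @param t0 landmark time.
#' @param metric `"auc"` or `"brier"` (or `"nri"` for the combined NRI, in
#'   which case the "difference" is the NRI itself).
#' @param config a [protocol_config()].
#' @return list with `difference` (point estimate from the full sample),
#'   `ci` (length-2), `p_value`, and `boot` (the resample differences).
#' @export
bootstrap_difference <- function(cohort, t0, metric = c("brier", "auc", "nri"),
                                 config = protocol_config()) {
  metric <- match.arg(metric)
  if (!is.null(config$seed)) set.seed(config$seed)
  diff_of <- function(reps) {
    switch(metric,
           brier = mean(reps$brier_dynamic) - mean(reps$brier_static),
           auc = mean(reps$auc_dynamic) - mean(reps$auc_static),
           nri = combine_nri(mean(reps$up_event), mean(reps$down_event),
                             mean(reps$up_nonevent), mean(reps$down_nonevent)))
  }
  point <- diff_of(landmark_cv(cohort, t0, config))
  B <- config$bootstrap_reps
  boot <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    boot[b] <- tryCatch(
      diff_of(suppressWarnings(
        landmark_cv(resample_cohort(cohort), t0, config,
                    cv_reps = config$cv_reps_boot))),
      error = function(e) NA_real_
    )
  }
  boot <- boot[!is.na(boot)]
  if (length(boot) == 0L) stop("all bootstrap resamples failed", call. = FALSE)
  ci <- unname(stats::quantile(boot, c(0.025, 0.975)))
  p <- 2 * min(mean(boot <= 0), mean(boot >= 0))
  list(difference = point, ci = ci, p_value = min(max(p, 0), 1), boot = boot)
}

#' Run the full static-vs-dynamic study
#'
#' For each arm and each landmark time: cross-validated AUC and Brier score
#' for the static and dynamic models, the survival Hosmer-Lemeshow statistic
#' and p-value for both, and the NRI components with combined NRI; when
#' `config$bootstrap_reps > 0`, percentile bootstrap CIs and p-values for the
#' AUC and Brier differences and for the NRI. At `t0 = 0` the two models are
#' the same fit, so every metric is identical by construction.
#'
#' @param cohorts named list of `dl_cohort` objects, one per arm, or a single
#'   `dl_cohort`.
#' @param config a [protocol_config()].
#' @return object of class `study_report`: list with `metrics` (data.frame:
#'   `arm`, `t0`, `tau`, `metric`, `static`, `dynamic`, `difference`,
#'   `ci_lo`, `ci_hi`, `p_value`), `hl` (data.frame), `nri` (data.frame) and
#'   `meta`.
#' @export
run_full_study <- function(cohorts, config = protocol_config()) {
  if (inherits(cohorts, "dl_cohort")) cohorts <- list(cohort = cohorts)
  stopifnot(length(cohorts) >= 1L, !is.null(names(cohorts)))
  base_seed <- if (is.null(config$seed)) 19L else as.integer(config$seed)

  metric_rows <- list(); hl_rows <- list(); nri_rows <- list()
  n_skipped <- 0L
  for (ai in seq_along(cohorts)) {
    arm <- names(cohorts)[ai]
    cohort <- cohorts[[ai]]
    for (ti in seq_along(config$t0_list)) {
      t0 <- config$t0_list[ti]
      tau <- t0 + config$horizon
      set.seed((base_seed * 1009L + ai * 101L + ti) %% .Machine$integer.max)
      reps <- landmark_cv(cohort, t0, config)
      n_skipped <- n_skipped + attr(reps, "skipped")

      boots <- list(auc = NULL, brier = NULL, nri = NULL)
      if (config$bootstrap_reps > 0) {
        for (m in names(boots)) {
          cfg_b <- config
          cfg_b$seed <- (base_seed * 2003L + ai * 211L + ti * 17L +
                           match(m, names(boots))) %% .Machine$integer.max
          boots[[m]] <- bootstrap_difference(cohort, t0, metric = m,
                                             config = cfg_b)
        }
      }
      for (m in c("auc", "brier")) {
        s <- mean(reps[[paste0(m, "_static")]])
        d <- mean(reps[[paste0(m, "_dynamic")]])
        b <- boots[[m]]
        metric_rows[[length(metric_rows) + 1L]] <- data.frame(
          arm = arm, t0 = t0, tau = tau, metric = m,
          static = s, dynamic = d, difference = d - s,
          ci_lo = if (is.null(b)) NA_real_ else b$ci[1L],
          ci_hi = if (is.null(b)) NA_real_ else b$ci[2L],
          p_value = if (is.null(b)) NA_real_ else b$p_value,
          stringsAsFactors = FALSE
        )
      }
      hl_s <- mean(reps$hl_static)
      hl_d <- mean(reps$hl_dynamic)
      hl_rows[[length(hl_rows) + 1L]] <- data.frame(
        arm = arm, t0 = t0, tau = tau,
        hl_static = hl_s, p_static = chisq_pvalue(hl_s, 4),
        hl_dynamic = hl_d, p_dynamic = chisq_pvalue(hl_d, 4),
        stringsAsFactors = FALSE
      )
      bn <- boots$nri
      nri_rows[[length(nri_rows) + 1L]] <- data.frame(
        arm = arm, t0 = t0, tau = tau,
        up_event = mean(reps$up_event), down_event = mean(reps$down_event),
        up_nonevent = mean(reps$up_nonevent),
        down_nonevent = mean(reps$down_nonevent),
        nri = combine_nri(mean(reps$up_event), mean(reps$down_event),
                          mean(reps$up_nonevent), mean(reps$down_nonevent)),
        ci_lo = if (is.null(bn)) NA_real_ else bn$ci[1L],
        ci_hi = if (is.null(bn)) NA_real_ else bn$ci[2L],
        p_value = if (is.null(bn)) NA_real_ else bn$p_value,
        stringsAsFactors = FALSE
      )
    }
  }
  structure(
    list(
      metrics = do.call(rbind, metric_rows),
      hl = do.call(rbind, hl_rows),
      nri = do.call(rbind, nri_rows),
      meta = list(
        seed = base_seed,
        t0_list = config$t0_list, horizon = config$horizon,
        cv_reps = config$cv_reps, bootstrap_reps = config$bootstrap_reps,
        skipped_cv_reps = n_skipped,
        config_hash = config_hash(config),
        package_version = as.character(utils::packageVersion("dlpred"))
      )
    ),
    class = "study_report"
  )
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>", length(unique(x$metrics$arm)), "arm(s) x",
      length(unique(x$metrics$t0)), "landmark time(s)\n")
  print(x$metrics, digits = 3)
  invisible(x)
}
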