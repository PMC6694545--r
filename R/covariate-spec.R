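#' Covariate specification with reference-level dummy coding
#'
#' Describes the design matrix used by the Cox engine: a set of categorical
#' covariates, each with an ordered level vector whose first element is the
#' reference level, plus a set of numeric covariates used as-is. Dummy columns
#' are named `<factor>=<level>`.
#'
#' @param factors named list; each element is a character vector of levels,
#'   the first being the reference level.
#' @param numeric character vector of numeric covariate column names.
#' @return an object of class `covariate_spec`.
#' @examples
#' covariate_spec(factors = list(gender = c("male", "female")),
#'                numeric = c("glucose_b"))
#' @export
covariate_spec <- function(factors = list(), numeric = character()) {
  if (length(factors)) {
    if (is.null(names(factors)) || any(!nzchar(names(factors)))) {
      stop("all elements of `factors` must be named", call. = FALSE)
    }
    for (nm in names(factors)) {
      lv <- factors[[nm]]
      if (!is.character(lv) || length(lv) < 2L || anyDuplicated(lv)) {
        stop("factor `", nm, "` needs >= 2 distinct character levels",
             call. = FALSE)
      }
    }
  }
  numeric <- as.character(numeric)
  all_names <- c(names(factors), numeric)
  if (anyDuplicated(all_names)) {
    stop("covariate names must be unique", call. = FALSE)
  }
  structure(list(factors = factors, numeric = numeric),
            class = "covariate_spec")
}

#' Term (design-matrix column) names implied by a covariate spec
#' @param spec a [covariate_spec()].
#' @return character vector of column names in design order.
#' @export
spec_term_names <- function(spec) {
  stopifnot(inherits(spec, "covariate_spec"))
  fac <- unlist(lapply(names(spec$factors), function(nm) {
    paste0(nm, "=", spec$factors[[nm]][-1L])
  }), use.names = FALSE)
  c(fac, spec$numeric)
}

#' Build the design matrix for a covariate spec
#'
#' Rows with missing values in any required column are an error: exclusion of
#' incomplete rows is the caller's responsibility (see
#' [build_landmark_frame()]).
#'
#' @param spec a [covariate_spec()].
#' @param data data.frame holding the raw covariate columns.
#' @return numeric matrix with columns [spec_term_names()].
#' @export
build_model_matrix <- function(spec, data) {
  stopifnot(inherits(spec, "covariate_spec"), is.data.frame(data))
  need <- c(names(spec$factors), spec$numeric)
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("data is missing covariate column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(data)
  cols <- list()
  for (nm in names(spec$factors)) {
    lv <- spec$factors[[nm]]
    x <- as.character(data[[nm]])
    bad <- !is.na(x) & !(x %in% lv)
    if (any(bad)) {
      stop("covariate `", nm, "` has level(s) outside its spec: ",
           paste(unique(x[bad]), collapse = ", "), call. = FALSE)
    }
    if (anyNA(x)) stop("missing values in covariate `", nm, "`", call. = FALSE)
    for (l in lv[-1L]) cols[[paste0(nm, "=", l)]] <- as.numeric(x == l)
  }
  for (nm in spec$numeric) {
    x <- as.numeric(data[[nm]])
    if (anyNA(x)) stop("missing values in covariate `", nm, "`", call. = FALSE)
    cols[[nm]] <- x
  }
  if (length(cols) == 0L) {
    return(matrix(numeric(0), nrow = n, ncol = 0L))
  }
  m <- do.call(cbind, cols)
  rownames(m) <- NULL
  m
}

#' Default covariate specification for DPP-like cohorts
#'
#' Baseline categorical covariates (age group, gender, BMI group, smoking
#' status, race/ethnicity) with conventional reference levels (youngest age
#' group, male, lowest BMI group, non-smoker, White), baseline fasting plasma
#' glucose and HbA1c, and optionally the change-from-baseline lab covariates
#' used by the dynamic landmark model.
#'
#' @param include_changes include `glucose_chg` / `hba1c_chg` terms (the
#'   dynamic landmark parameterization).
#' @param labs_only drop the categorical block; useful for compact simulation
#'   studies where categoricals carry no signal.
#' @return a [covariate_spec()].
#' @export
dpp_covariate_spec <- function(include_changes = FALSE, labs_only = FALSE) {
  numeric <- c("glucose_b", "hba1c_b")
  if (include_changes) numeric <- c(numeric, "glucose_chg", "hba1c_chg")
  if (labs_only) {
    return(covariate_spec(numeric = numeric))
  }
  covariate_spec(
    factors = list(
      age_group = c("<40", "40-44", "45-49", "50-54", "55-59", "60-64", "65+"),
      gender    = c("male", "female"),
      bmi_group = c("<30", "30-34", "35+"),
      smoking   = c("no", "yes", "not_available"),
      race      = c("white", "black", "hispanic", "other")
    ),
    numeric = numeric
  )
}
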