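#' Right-continuous step function
#'
#' Lightweight container for right-continuous step functions such as the
#' Breslow baseline cumulative hazard or a Kaplan-Meier censoring-survival
#' curve. The function takes the value `before` strictly to the left of the
#' first knot and `values[k]` on `[knots[k], knots[k+1])`.
#'
#' @param knots strictly increasing numeric vector of jump locations.
#' @param values numeric vector, the value taken at and after each knot.
#' @param before value taken before the first knot.
#' @return an object of class `step_function`.
#' @examples
#' sf <- step_function(c(1, 2), c(0.5, 1.2), before = 0)
#' sf_eval(sf, c(0.5, 1, 1.9, 2, 3))
#' @export
step_function <- function(knots, values, before = 0) {
  knots <- as.numeric(knots)
  values <- as.numeric(values)
  if (length(knots) != length(values)) {
    stop("`knots` and `values` must have equal length", call. = FALSE)
  }
  if (length(knots) > 1L && any(diff(knots) <= 0)) {
    stop("`knots` must be strictly increasing", call. = FALSE)
  }
  structure(
    list(knots = knots, values = values, before = as.numeric(before)[1L]),
    class = "step_function"
  )
}

#' Evaluate a step function
#'
#' @param sf a [step_function()].
#' @param t numeric vector of evaluation points.
#' @return numeric vector; right-continuous evaluation.
#' @export
sf_eval <- function(sf, t) {
  stopifnot(inherits(sf, "step_function"))
  if (length(sf$knots) == 0L) return(rep(sf$before, length(t)))
  idx <- findInterval(t, sf$knots) # count of knots <= t  => right-continuous
  c(sf$before, sf$values)[idx + 1L]
}

#' @export
print.step_function <- function(x, ...) {
  cat("<step_function> ", length(x$knots), " knots; value before first knot: ",
      format(x$before), "\n", sep = "")
  if (length(x$knots)) {
    n <- min(6L, length(x$knots))
    cat("  first knots:", paste(format(x$knots[seq_len(n)], digits = 4),
                                collapse = ", "), "\n")
  }
  invisible(x)
}

# last knot (or -Inf if empty); used to flag extrapolation
sf_last_knot <- function(sf) {
  if (length(sf$knots) == 0L) -Inf else sf$knots[length(sf$knots)]
}
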