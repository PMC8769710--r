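#' Right-continuous step function
#'
#' Lightweight carrier for estimated cumulative hazards and survival
#' functions. Evaluation at `t` returns the value attached to the largest
#' knot `<= t`, or `value_before` when `t` lies before the first knot. An
#' empty knot set is allowed and represents the constant function
#' `value_before` (e.g. the Nelson-Aalen estimate with no events).
#'
#' @param knots Strictly increasing numeric vector of jump locations.
#' @param values Function value at (and after) each knot.
#' @param value_before Value before the first knot.
#' @return An object of class `step_function`.
#' @export
step_function <- function(knots, values, value_before = 0) {
  knots <- as.numeric(knots)
  values <- as.numeric(values)
  if (length(knots) != length(values)) {
    fail_validation("knots and values must have equal length")
  }
  if (length(knots) > 1 && any(diff(knots) <= 0)) {
    fail_validation("knots must be strictly increasing")
  }
  structure(list(knots = knots, values = values,
                 value_before = as.numeric(value_before)),
            class = "step_function")
}

#' Evaluate a step function
#'
#' @param sf A `step_function`.
#' @param t Numeric vector of evaluation points.
#' @param left_limit If `TRUE`, return the left limit `f(t-)`, i.e. the value
#'   attached to the largest knot strictly below `t`. Needed for the
#'   inverse-probability-of-censoring weight `1 / G(t-)`.
#' @return Numeric vector of the same length as `t`.
#' @export
eval_step <- function(sf, t, left_limit = FALSE) {
  if (length(sf$knots) == 0) {
    return(rep(sf$value_before, length(t)))
  }
  idx <- findInterval(t, sf$knots, left.open = left_limit)
  c(sf$value_before, sf$values)[idx + 1]
}

#' @export
print.step_function <- function(x, ...) {
  cat(sprintf("step_function with %d knots", length(x$knots)))
  if (length(x$knots)) {
    cat(sprintf(" on [%g, %g], value before = %g\n",
                min(x$knots), max(x$knots), x$value_before))
  } else {
    cat(sprintf(", constant at %g\n", x$value_before))
  }
  invisible(x)
}

#' Write a step function as two-column delimited text
#'
#' @param sf A `step_function`.
#' @param path Output path.
#' @param delimiter Field delimiter.
#' @export
write_step_function <- function(sf, path, delimiter = ",") {
  utils::write.table(data.frame(knot = sf$knots, value = sf$values),
                     path, sep = delimiter, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a step function written by [write_step_function()]
#'
#' @param path Input path.
#' @param value_before Value before the first knot (not stored in the file).
#' @param delimiter Field delimiter.
#' @export
read_step_function <- function(path, value_before = 0, delimiter = ",") {
  tab <- utils::read.table(path, header = TRUE, sep = delimiter)
  step_function(tab$knot, tab$value, value_before = value_before)
}
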