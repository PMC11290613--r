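#' Right-continuous step functions
#'
#' Internal representation shared by all baseline-hazard and survival-curve
#' estimators: a value before the first knot, then a new value at each knot,
#' carried forward (right-continuous).
#'
#' @param knots strictly increasing numeric vector of jump locations
#' @param values value taken at and after each knot
#' @param init value for `t` smaller than the first knot
#' @return an object of class `step_fun`
#' @keywords internal
new_step_fun <- function(knots, values, init) {
  stopifnot(length(knots) == length(values), !is.unsorted(knots, strictly = TRUE) || length(knots) <= 1)
  structure(list(knots = as.numeric(knots), values = as.numeric(values), init = init),
            class = "step_fun")
}

#' Evaluate a step function (right-continuous)
#' @param f a `step_fun`
#' @param t numeric vector of evaluation points
#' @keywords internal
eval_step <- function(f, t) {
  idx <- findInterval(t, f$knots)
  c(f$init, f$values)[idx + 1L]
}

#' Evaluate the left limit f(t-) of a step function
#' @keywords internal
eval_step_left <- function(f, t) {
  idx <- findInterval(t, f$knots, left.open = TRUE)
  c(f$init, f$values)[idx + 1L]
}

#' @export
print.step_fun <- function(x, ...) {
  cat("Step function with", length(x$knots), "knots; value", x$init, "before first knot\n")
  if (length(x$knots) > 0) {
    show <- head(data.frame(t = x$knots, value = x$values), 6)
    print(show, row.names = FALSE)
    if (length(x$knots) > 6) cat("...\n")
  }
  invisible(x)
}
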