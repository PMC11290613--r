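#' Define an external model backend
#'
#' Protocol for plugging externally fitted survival models (random survival
#' forests, deep-learning survival networks, spline hazard models, ...) into
#' the surface and rendering pipeline without reimplementing them. An
#' adapter supplies a `fit` hook and a `predict` hook returning
#' probabilities over a time grid for one covariate row; the wrapper
#' enforces the curve contract (values clipped to [0, 1], monotone in time).
#'
#' @param fit `function(dataset) -> state`; may be `NULL` for pre-fitted
#'   models (state defaults to the dataset)
#' @param predict `function(state, covariate_row, time_grid) -> numeric`
#'   where `covariate_row` is a named list with the predictor and raw
#'   adjuster values
#' @param outcome_type `"survival"` or `"cumulative_incidence"`
#' @param label short tag used in figure annotations
#' @return a `backend_adapter`
#' @seealso [wrap_backend()]
#' @export
backend_adapter <- function(fit = NULL, predict, outcome_type = c("survival", "cumulative_incidence"),
                            label = "backend") {
  outcome_type <- match.arg(outcome_type)
  stopifnot(is.function(predict))
  structure(list(fit = fit, predict = predict, outcome_type = outcome_type,
                 label = label), class = "backend_adapter")
}

#' Wrap a backend adapter as a fitted predictor
#'
#' Runs the adapter's `fit` hook on the dataset and returns an object
#' honoring the same prediction contract as the native fits, so
#' [compute_surface()] can render it. Predictions are clipped to [0, 1] and
#' monotonized (running minimum over time for survival curves, running
#' maximum for cumulative incidence); violations are reported with a
#' warning. Non-finite adapter output is an error.
#'
#' @param adapter a [backend_adapter()]
#' @param ds a `survival_dataset`
#' @return a `backend_fit`
#' @export
wrap_backend <- function(adapter, ds) {
  stopifnot(inherits(adapter, "backend_adapter"), inherits(ds, "survival_dataset"))
  state <- if (is.function(adapter$fit)) adapter$fit(ds) else ds
  structure(list(adapter = adapter, state = state, dataset = ds,
                 design = build_design(ds), outcome_type = adapter$outcome_type),
            class = "backend_fit")
}

# Evaluate a wrapped backend at one covariate row, enforcing the contract.
backend_predict_row <- function(fit, row_list, times) {
  p <- as.numeric(fit$adapter$predict(fit$state, row_list, times))
  if (length(p) != length(times))
    stop("backend adapter returned ", length(p), " values for ", length(times),
         " time points", call. = FALSE)
  if (any(!is.finite(p)))
    stop("backend adapter returned non-finite predictions", call. = FALSE)
  clipped <- pmin(pmax(p, 0), 1)
  mono <- if (fit$outcome_type == "survival") cummin(clipped) else cummax(clipped)
  if (any(abs(mono - p) > 1e-12))
    warning("backend predictions violated the ", fit$outcome_type,
            " curve contract; clipped to [0, 1] and monotonized", call. = FALSE)
  mono
}

#' Wrap a native fit as a backend adapter
#'
#' Mainly for testing the adapter contract: the resulting adapter reproduces
#' the native predictions exactly.
#'
#' @param fit a `cox_fit`, `weibull_fit` or `fine_gray_fit`
#' @return a `backend_adapter`
#' @export
as_backend_adapter <- function(fit) {
  outcome <- if (inherits(fit, "fine_gray_fit")) "cumulative_incidence" else "survival"
  backend_adapter(
    fit = function(ds) fit,
    predict = function(state, covariate_row, time_grid) {
      x_row <- design_row(state$design, covariate_row[[state$design$predictor_name]],
                          covariate_row[setdiff(names(covariate_row),
                                                state$design$predictor_name)])
      if (inherits(state, "cox_fit"))
        predict_survival_cox(state, x_row, time_grid)$estimate
      else if (inherits(state, "weibull_fit"))
        predict_survival_weibull(state, x_row, time_grid)$estimate
      else predict_cif_fine_gray(state, x_row, time_grid)$estimate
    },
    outcome_type = outcome, label = class(fit)[1]
  )
}
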