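# JSON serialization of fitted models: coefficients, covariance, and the
# baseline step-function knots/values - enough to re-render surfaces
# reproducibly without refitting (the originating dataset is not stored, so
# deserialized fits need an explicit grid and profile).

#' Serialize a fitted model to JSON
#'
#' @param fit a `cox_fit`, `weibull_fit` or `fine_gray_fit`
#' @param path optional output file; when `NULL`, returns the JSON string
#' @return `path` invisibly, or the JSON string
#' @export
model_to_json <- function(fit, path = NULL) {
  payload <- serialize_fit(fit)
  js <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

serialize_fit <- function(fit) UseMethod("serialize_fit")

design_meta_payload <- function(fit) {
  list(column_names = fit$column_names, center = fit$center,
       predictor_name = fit$design$predictor_name,
       adjuster_meta = fit$design$adjuster_meta)
}

baseline_payload <- function(b) {
  list(times = b$times, d = b$d, s0 = b$s0, xbar = b$xbar,
       increments = b$increments, cumhaz = b$cumhaz,
       cum_v1 = b$cum_v1, cum_qbar = b$cum_qbar)
}

#' @export
serialize_fit.cox_fit <- function(fit) {
  list(class = "cox_fit", beta = fit$beta, covariance = fit$covariance,
       ties = fit$ties, loglik = fit$loglik, stratified = fit$stratified,
       strata_levels = fit$strata_levels,
       baseline = lapply(fit$baseline, baseline_payload),
       design = design_meta_payload(fit))
}

#' @export
serialize_fit.weibull_fit <- function(fit) {
  list(class = "weibull_fit", shape = fit$shape, scale = fit$scale,
       gamma = fit$gamma, covariance = fit$covariance, loglik = fit$loglik,
       censoring_mode = fit$censoring_mode, design = design_meta_payload(fit))
}

#' @export
serialize_fit.fine_gray_fit <- function(fit) {
  list(class = "fine_gray_fit", beta = fit$beta, covariance = fit$covariance,
       loglik = fit$loglik, baseline = baseline_payload(fit$baseline),
       censoring_km = list(knots = fit$censoring_survival$knots,
                           values = fit$censoring_survival$values),
       design = design_meta_payload(fit))
}

#' Restore a fitted model from JSON
#'
#' The restored object predicts and renders identically to the original; it
#' does not carry the training data, so [compute_surface()] needs an explicit
#' grid and covariate profile.
#'
#' @param json JSON string or file path from [model_to_json()]
#' @return a fit object of the serialized class
#' @export
model_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  p <- length(x$design$column_names)
  design <- structure(list(
    x = NULL, column_names = as.character(x$design$column_names),
    center = setNames(as.numeric(x$design$center), x$design$column_names),
    predictor_name = x$design$predictor_name,
    adjuster_meta = lapply(x$design$adjuster_meta, function(m)
      list(type = m$type, levels = if (!is.null(m$levels)) as.character(m$levels)))
  ), class = "design_matrix")
  restore_baseline <- function(b) {
    list(times = as.numeric(b$times), d = as.numeric(b$d), s0 = as.numeric(b$s0),
         xbar = matrix(b$xbar, ncol = p), increments = as.numeric(b$increments),
         cumhaz = as.numeric(b$cumhaz), cum_v1 = as.numeric(b$cum_v1),
         cum_qbar = matrix(b$cum_qbar, ncol = p))
  }
  cov <- matrix(unlist(x$covariance), p_from_class(x, p), byrow = FALSE)
  if (x$class == "cox_fit") {
    structure(list(beta = setNames(as.numeric(x$beta), design$column_names),
                   covariance = cov, column_names = design$column_names,
                   center = design$center, ties = x$ties, loglik = x$loglik,
                   converged = TRUE, stratified = isTRUE(x$stratified),
                   strata_levels = as.character(x$strata_levels),
                   baseline = lapply(x$baseline, restore_baseline),
                   design = design, dataset = NULL),
              class = "cox_fit")
  } else if (x$class == "weibull_fit") {
    structure(list(shape = x$shape, scale = x$scale,
                   gamma = setNames(as.numeric(x$gamma), design$column_names),
                   log_shape = log(x$shape), log_scale = log(x$scale),
                   covariance = cov, loglik = x$loglik,
                   censoring_mode = x$censoring_mode,
                   column_names = design$column_names, center = design$center,
                   design = design, dataset = NULL),
              class = "weibull_fit")
  } else if (x$class == "fine_gray_fit") {
    structure(list(beta = setNames(as.numeric(x$beta), design$column_names),
                   covariance = cov, column_names = design$column_names,
                   center = design$center, loglik = x$loglik, converged = TRUE,
                   baseline = restore_baseline(x$baseline),
                   censoring_survival = new_step_fun(as.numeric(x$censoring_km$knots),
                                                     as.numeric(x$censoring_km$values),
                                                     init = 1),
                   design = design, dataset = NULL),
              class = "fine_gray_fit")
  } else stop("unknown serialized class '", x$class, "'", call. = FALSE)
}

p_from_class <- function(x, p) {
  if (x$class == "weibull_fit") p + 2L else p
}
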