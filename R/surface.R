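# The time x covariate surface of conditional predictions: the interchange
# object between estimation and rendering.

#' Build the evaluation grid for a survival surface
#'
#' @param ds a `survival_dataset`
#' @param strategy `"linear"` (equally spaced over the observed predictor
#'   range) or `"quantile"` (empirical quantiles at equally spaced
#'   probabilities, duplicates collapsed)
#' @param n_points number of covariate grid points (>= 2; default 100)
#' @param time_grid optional time grid; default is the sorted unique observed
#'   event times with 0 prepended, matching the step structure of the
#'   nonparametric baselines
#' @param trim optional length-2 probability vector (e.g. `c(0.01, 0.99)`)
#'   trimming the covariate range to those quantiles before gridding, for
#'   outlier-dominated axes
#' @return a `grid_spec` with `covariate_values` and `time_grid`
#' @export
build_grid <- function(ds, strategy = c("linear", "quantile"), n_points = 100,
                       time_grid = NULL, trim = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(ds, "survival_dataset"))
  if (n_points < 2) stop("n_points must be >= 2", call. = FALSE)
  v <- ds$predictor[is.finite(ds$predictor)]
  if (length(unique(v)) < 2)
    stop("degenerate axis: predictor has fewer than 2 distinct values", call. = FALSE)
  if (!is.null(trim)) {
    stopifnot(length(trim) == 2, trim[1] < trim[2])
    q <- stats::quantile(v, trim, names = FALSE)
    v <- v[v >= q[1] & v <= q[2]]
  }
  cov_vals <- if (strategy == "linear") {
    seq(min(v), max(v), length.out = n_points)
  } else {
    unique(stats::quantile(v, seq(0, 1, length.out = n_points), names = FALSE))
  }
  if (is.null(time_grid)) {
    tt <- if (ds$mode == "right") ds$time[ds$event >= 1L]
          else ds$right[is.finite(ds$right)]
    time_grid <- c(0, sort(unique(tt)))
  } else {
    time_grid <- sort(unique(as.numeric(time_grid)))
  }
  structure(list(covariate_values = cov_vals, time_grid = time_grid,
                 predictor_range = range(ds$predictor[is.finite(ds$predictor)])),
            class = "grid_spec")
}

#' Default covariate profile for conditioning the surface
#'
#' The displayed surface is conditional on fixed adjuster values: by default
#' the sample median for continuous adjusters and the most frequent level for
#' categorical ones (frequency ties broken by sorted level order). Individual
#' entries can be overridden by the user.
#'
#' @param ds a `survival_dataset`
#' @param design optional [build_design()] result (defaults to
#'   `build_design(ds)`)
#' @param overrides named list of user-chosen adjuster values
#' @return a `covariate_profile`: `values` (named list) and `source`
#'   (`"default"` or `"user"` per entry)
#' @export
default_profile <- function(ds, design = NULL, overrides = NULL) {
  if (is.null(design)) design <- build_design(ds)
  values <- list(); source <- character(0)
  for (nm in names(design$adjuster_meta)) {
    m <- design$adjuster_meta[[nm]]
    if (!is.null(overrides[[nm]])) {
      values[[nm]] <- overrides[[nm]]
      source[nm] <- "user"
    } else if (m$type == "continuous") {
      values[[nm]] <- stats::median(ds$adjusters[[nm]], na.rm = TRUE)
      source[nm] <- "default"
    } else {
      v <- as.character(ds$adjusters[[nm]])
      tab <- table(v)
      lv <- sort(names(tab))
      values[[nm]] <- lv[which.max(tab[lv])]
      source[nm] <- "default"
    }
  }
  extra <- setdiff(names(overrides), names(design$adjuster_meta))
  if (length(extra) > 0)
    stop("profile overrides name unknown adjuster(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  structure(list(values = values, source = source), class = "covariate_profile")
}

# One surface row: estimate + variance of log cumulative hazard at a fixed
# covariate row, dispatched on the fitted-model class.
surface_predict_row <- function(model, cov_value, profile, times, stratum = NULL) {
  UseMethod("surface_predict_row")
}

#' @export
surface_predict_row.cox_fit <- function(model, cov_value, profile, times, stratum = NULL) {
  x_row <- design_row(model$design, cov_value, profile)
  ch <- cox_cumhaz_at(model, x_row, times, stratum)
  list(estimate = exp(-ch$cumhaz), var_log_cumhaz = ch$var_log_cumhaz,
       outcome_type = "survival")
}

#' @export
surface_predict_row.weibull_fit <- function(model, cov_value, profile, times, stratum = NULL) {
  x_row <- design_row(model$design, cov_value, profile)
  ch <- weibull_cumhaz_at(model, x_row, times)
  list(estimate = exp(-ch$cumhaz), var_log_cumhaz = ch$var_log_cumhaz,
       outcome_type = "survival")
}

#' @export
surface_predict_row.fine_gray_fit <- function(model, cov_value, profile, times, stratum = NULL) {
  x_row <- design_row(model$design, cov_value, profile)
  ch <- cumhaz_table_at(model$baseline, model$beta, model$covariance, x_row, times)
  list(estimate = 1 - exp(-ch$cumhaz), var_log_cumhaz = ch$var_log_cumhaz,
       outcome_type = "cumulative_incidence")
}

#' @export
surface_predict_row.backend_fit <- function(model, cov_value, profile, times, stratum = NULL) {
  vals <- if (inherits(profile, "covariate_profile")) profile$values else profile
  row_list <- c(setNames(list(cov_value), model$design$predictor_name), vals)
  list(estimate = backend_predict_row(model, row_list, times),
       var_log_cumhaz = NULL, outcome_type = model$outcome_type)
}

#' Compute the time x covariate prediction surface
#'
#' For each covariate grid value, assembles a covariate row (predictor at the
#' grid value, adjusters at the profile) and evaluates the fitted model over
#' the time grid. The result is the matrix the contour and 3D plots render:
#' rows indexed by the covariate, columns by time. Survival surfaces are
#' non-increasing along time; cumulative-incidence surfaces (Fine-Gray)
#' non-decreasing. Delta-method bands on the log(-log) scale are attached
#' when the model supplies variances.
#'
#' A warning (not an error) is raised when the covariate grid extends beyond
#' three times the observed predictor range.
#'
#' @param model a `cox_fit`, `weibull_fit`, `fine_gray_fit` or `backend_fit`
#' @param grid a [build_grid()] result; built from the model's dataset when
#'   `NULL`
#' @param profile a [default_profile()] result; defaulted when `NULL`
#' @param ci_level confidence level for the bands (default 0.95); `NA`
#'   suppresses bands
#' @param stratum stratum label for stratified Cox fits
#' @return a `survival_surface`: `time_grid`, `covariate_values`, `values`
#'   (matrix, rows = covariate values), optional `lower`/`upper`,
#'   `outcome_type`, `ci_level`, `profile`, `model_tag`
#' @export
compute_surface <- function(model, grid = NULL, profile = NULL, ci_level = 0.95,
                            stratum = NULL) {
  if (is.null(grid)) grid <- build_grid(model$dataset)
  if (is.null(profile)) profile <- default_profile(model$dataset, model$design)
  stopifnot(inherits(grid, "grid_spec"))
  rng <- grid$predictor_range
  r <- diff(rng)
  if (r > 0 && (min(grid$covariate_values) < rng[1] - r ||
                max(grid$covariate_values) > rng[2] + r))
    warning("covariate grid extends beyond 3x the observed predictor range; ",
            "predictions there are extrapolation", call. = FALSE)

  nt <- length(grid$time_grid); nc <- length(grid$covariate_values)
  values <- matrix(NA_real_, nc, nt)
  varlog <- matrix(NA_real_, nc, nt)
  outcome <- NULL
  for (i in seq_len(nc)) {
    pr <- surface_predict_row(model, grid$covariate_values[i], profile,
                              grid$time_grid, stratum)
    values[i, ] <- pr$estimate
    if (!is.null(pr$var_log_cumhaz)) varlog[i, ] <- pr$var_log_cumhaz
    outcome <- pr$outcome_type
  }
  surf <- structure(list(
    time_grid = grid$time_grid, covariate_values = grid$covariate_values,
    values = values, lower = NULL, upper = NULL,
    outcome_type = outcome, ci_level = ci_level,
    profile = profile, model_tag = class(model)[1],
    predictor_name = model$design$predictor_name,
    stratum = stratum
  ), class = "survival_surface")
  if (!is.na(ci_level) && any(is.finite(varlog))) {
    b <- loglog_bands(as.vector(values), as.vector(varlog), ci_level,
                      if (outcome == "survival") "survival" else "incidence")
    surf$lower <- matrix(b$lower, nc, nt)
    surf$upper <- matrix(b$upper, nc, nt)
  }
  surf
}

#' Add or replace confidence bands on a surface
#'
#' `method = "delta"` recomputes the analytic bands (symmetric normal
#' interval on the log(-log) scale, back-transformed, so bands stay inside
#' (0, 1)); `method = "bootstrap"` draws `n_boot` nonparametric resamples of
#' the originating dataset, refits the model, and takes pointwise percentile
#' bands — the option to use for Fine-Gray fits, whose analytic variance is
#' approximate. Cells where the estimate is exactly 0 or 1 collapse to the
#' point value.
#'
#' @param model the fitted model that produced `surface`
#' @param surface a `survival_surface`
#' @param method `"delta"` or `"bootstrap"`
#' @param n_boot number of bootstrap refits (default 200)
#' @param seed RNG seed for the resampling
#' @return the surface with `lower`/`upper` set
#' @export
surface_ci <- function(model, surface, method = c("delta", "bootstrap"),
                       n_boot = 200, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(surface, "survival_surface"))
  if (method == "delta") {
    grid <- structure(list(covariate_values = surface$covariate_values,
                           time_grid = surface$time_grid,
                           predictor_range = range(surface$covariate_values)),
                      class = "grid_spec")
    out <- compute_surface(model, grid, surface$profile, surface$ci_level,
                           surface$stratum)
    if (is.null(out$lower))
      stop("model does not supply variances; use method = 'bootstrap'", call. = FALSE)
    surface$lower <- out$lower; surface$upper <- out$upper
    return(surface)
  }
  ds <- model$dataset
  if (is.null(ds)) stop("bootstrap bands need the originating dataset", call. = FALSE)
  nc <- length(surface$covariate_values); nt <- length(surface$time_grid)
  draws <- array(NA_real_, c(n_boot, nc, nt))
  ok <- 0L
  with_local_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(ds$n, replace = TRUE)
      bs <- tryCatch(as_survival_dataset(ds$data[idx, , drop = FALSE], ds$roles),
                     error = function(e) NULL)
      refit <- if (is.null(bs)) NULL else
        tryCatch(suppressWarnings(refit_model(model, bs)), error = function(e) NULL)
      if (is.null(refit)) next
      s <- tryCatch(suppressWarnings(
        compute_surface(refit,
                        structure(list(covariate_values = surface$covariate_values,
                                       time_grid = surface$time_grid,
                                       predictor_range = range(surface$covariate_values)),
                                  class = "grid_spec"),
                        surface$profile, ci_level = NA, stratum = surface$stratum)),
        error = function(e) NULL)
      if (is.null(s)) next
      draws[b, , ] <- s$values
      ok <- ok + 1L
    }
  })
  if (ok < n_boot / 2)
    stop("bootstrap failed: only ", ok, " of ", n_boot, " resamples refit", call. = FALSE)
  alpha <- 1 - surface$ci_level
  qs <- apply(draws, c(2, 3), stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), na.rm = TRUE)
  surface$lower <- qs[1, , ]; surface$upper <- qs[2, , ]
  deg <- surface$values %in% c(0, 1)
  surface$lower[deg] <- surface$values[deg]; surface$upper[deg] <- surface$values[deg]
  surface
}

refit_model <- function(model, ds) UseMethod("refit_model")
#' @export
refit_model.cox_fit <- function(model, ds) {
  if (model$stratified && is.null(ds$strata))
    stop("cannot bootstrap a fit stratified on labels outside the dataset roles",
         call. = FALSE)
  if (model$stratified) fit_stratified_cox(ds, ties = model$ties)
  else fit_cox(ds, ties = model$ties)
}
#' @export
refit_model.weibull_fit <- function(model, ds) fit_weibull(ds, mode = model$censoring_mode)
#' @export
refit_model.fine_gray_fit <- function(model, ds) fit_fine_gray(ds)
#' @export
refit_model.backend_fit <- function(model, ds) wrap_backend(model$adapter, ds)

#' Read a prediction off the surface
#'
#' The lookup behind interactive hover: step lookup in time (the value at the
#' last grid time at or before `t`, matching the estimators' step functions)
#' and linear interpolation in the covariate between adjacent grid rows.
#'
#' @param surface a `survival_surface`
#' @param t time in `[0, max(time_grid)]`
#' @param x covariate value within the grid range
#' @return list with `estimate`, `lower`, `upper` (bands `NA` when absent)
#' @export
value_at <- function(surface, t, x) {
  stopifnot(inherits(surface, "survival_surface"))
  tg <- surface$time_grid; cv <- surface$covariate_values
  if (t < 0 || t > max(tg))
    stop("t = ", t, " outside the surface time span [0, ", max(tg), "]", call. = FALSE)
  if (x < min(cv) || x > max(cv))
    stop("x = ", x, " outside the covariate grid [", min(cv), ", ", max(cv), "]",
         call. = FALSE)
  ti <- findInterval(t, tg)
  init <- if (surface$outcome_type == "survival") 1 else 0
  pick <- function(m) {
    if (is.null(m)) return(NA_real_)
    col <- if (ti == 0L) rep(init, length(cv)) else m[, ti]
    j <- findInterval(x, cv)
    if (j >= length(cv)) return(col[length(cv)])
    w <- (x - cv[j]) / (cv[j + 1] - cv[j])
    (1 - w) * col[j] + w * col[j + 1]
  }
  list(estimate = pick(surface$values), lower = pick(surface$lower),
       upper = pick(surface$upper))
}

#' Serialize a surface to JSON
#'
#' Schema: `{times[], covariate[], values[][], lower[][]?, upper[][]?,
#' outcome_type, ci_level, profile{}}` — the contract between fitting and
#' rendering (and the payload embedded in interactive HTML exports).
#' Numbers are written at full precision, so the round trip through
#' [surface_from_json()] is exact.
#'
#' @param surface a `survival_surface`
#' @param path optional file path; when `NULL` the JSON string is returned
#' @return `path` (invisibly) or a JSON string
#' @export
surface_to_json <- function(surface, path = NULL) {
  payload <- list(
    times = surface$time_grid,
    covariate = surface$covariate_values,
    values = surface$values,
    outcome_type = surface$outcome_type,
    ci_level = surface$ci_level,
    profile = if (length(surface$profile$values) > 0) surface$profile$values
              else stats::setNames(list(), character(0)),
    predictor_name = surface$predictor_name,
    model_tag = surface$model_tag
  )
  if (!is.null(surface$lower)) { payload$lower <- surface$lower; payload$upper <- surface$upper }
  js <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Deserialize a surface from JSON
#'
#' @param json a JSON string or file path produced by [surface_to_json()]
#' @return a `survival_surface`
#' @export
surface_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  prof <- structure(list(values = as.list(x$profile),
                         source = setNames(rep("user", length(x$profile)),
                                           names(x$profile))),
                    class = "covariate_profile")
  structure(list(
    time_grid = as.numeric(x$times), covariate_values = as.numeric(x$covariate),
    values = matrix(x$values, nrow = length(x$covariate)),
    lower = if (!is.null(x$lower)) matrix(x$lower, nrow = length(x$covariate)) else NULL,
    upper = if (!is.null(x$upper)) matrix(x$upper, nrow = length(x$covariate)) else NULL,
    outcome_type = x$outcome_type, ci_level = x$ci_level,
    profile = prof, model_tag = x$model_tag,
    predictor_name = x$predictor_name, stratum = NULL
  ), class = "survival_surface")
}

#' @export
print.survival_surface <- function(x, ...) {
  cat("<survival_surface>", x$outcome_type, "from", x$model_tag, "\n")
  cat(" ", length(x$covariate_values), "covariate values x",
      length(x$time_grid), "time points;",
      if (is.null(x$lower)) "no bands" else paste0(100 * x$ci_level, "% bands"), "\n")
  invisible(x)
}
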