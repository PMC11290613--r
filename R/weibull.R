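# Parametric Weibull survival regression in the accelerated-failure-time
# parameterization: S(t | x) = exp(-(t / (lambda * exp(x gamma)))^k).
# Supports right-censored and interval-censored likelihoods. The PH mapping
# is beta_PH = -k * gamma.

# theta = (log k, log lambda, gamma...); returns the NEGATIVE log-likelihood.
# Interval mode: rows with left == right contribute the density (exact times),
# right == Inf contribute S(left), left == 0 contributes 1 - S(right).
weibull_neg_loglik <- function(theta, x, mode, time = NULL, status = NULL,
                               left = NULL, right = NULL) {
  k <- exp(theta[1]); loglam <- theta[2]
  gamma <- theta[-(1:2)]
  mu <- rep(loglam, nrow(x)) + if (length(gamma) > 0) drop(x %*% gamma) else 0
  if (mode == "right") {
    z <- k * (log(time) - mu)          # log cumulative hazard
    ll <- sum(status * (theta[1] - log(time) + z)) - sum(exp(z))
  } else {
    ll <- 0
    exact <- is.finite(right) & left == right & left > 0
    if (any(exact)) {
      z <- k * (log(left[exact]) - mu[exact])
      ll <- ll + sum(theta[1] - log(left[exact]) + z - exp(z))
    }
    iv <- !exact
    if (any(iv)) {
      # log S(L) and log S(R); S(0) = 1, S(Inf) = 0
      lsl <- ifelse(left[iv] > 0, -exp(k * (log(pmax(left[iv], 1e-300)) - mu[iv])), 0)
      lsr <- ifelse(is.finite(right[iv]),
                    -exp(k * (log(right[iv]) - mu[iv])), -Inf)
      # log(exp(lsl) - exp(lsr)) with lsl > lsr
      diffl <- lsl + log1p(-exp(pmin(lsr - lsl, -1e-16)))
      ll <- ll + sum(diffl)
    }
  }
  if (!is.finite(ll)) ll <- -1e10
  -ll
}

numeric_hessian <- function(fn, theta, eps = 1e-5) {
  p <- length(theta)
  H <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in i:p) {
    ei <- ej <- numeric(p); ei[i] <- eps; ej[j] <- eps
    H[i, j] <- H[j, i] <-
      (fn(theta + ei + ej) - fn(theta + ei - ej) -
         fn(theta - ei + ej) + fn(theta - ei - ej)) / (4 * eps^2)
  }
  H
}

#' Fit a Weibull survival regression model
#'
#' Maximum likelihood in the accelerated-failure-time (AFT)
#' parameterization \eqn{S(t|x) = \exp\{-(t/(\lambda e^{x\gamma}))^k\}},
#' optimized over \eqn{(\log k, \log\lambda, \gamma)} by quasi-Newton (BFGS)
#' with the covariance taken from the inverse numerical Hessian. Supports
#' right-censored data (events contribute the density, censored subjects the
#' survival function) and interval-censored data (each subject contributes
#' \eqn{S(L_i|x) - S(R_i|x)}, with \eqn{S(\infty) = 0} and exact times
#' contributing the density).
#'
#' Under proportional hazards the AFT coefficients map to log hazard ratios
#' as \eqn{\beta_{PH} = -k\gamma}.
#'
#' @param ds a `survival_dataset` (right or interval mode, matching `mode`)
#' @param design optional [build_design()] result
#' @param mode `"right"` or `"interval"`; defaults to the dataset's mode
#' @param fix_shape optional fixed value for the shape k (excluded from
#'   optimization); used mainly for exponential fits (k = 1)
#' @param covariates if `FALSE`, fit the marginal (intercept-only) model,
#'   ignoring predictor and adjusters
#' @return a `weibull_fit` with `shape`, `scale`, `gamma`, `covariance`
#'   (order: log k, log lambda, gamma), `loglik`, `censoring_mode`
#' @examples
#' ds <- gen_ph_weibull(sim_spec(n = 150, beta = 0.5, seed = 3))
#' fit <- fit_weibull(ds)
#' c(shape = fit$shape, scale = fit$scale)
#' @export
fit_weibull <- function(ds, design = NULL, mode = NULL, fix_shape = NULL,
                        covariates = TRUE) {
  stopifnot(inherits(ds, "survival_dataset"))
  if (is.null(mode)) mode <- ds$mode
  if (mode != ds$mode)
    stop("dataset mode is '", ds$mode, "' but mode = '", mode, "' requested", call. = FALSE)
  if (!covariates) {
    design <- structure(list(x = matrix(numeric(0), nrow = ds$n, ncol = 0),
                             column_names = character(0), center = numeric(0),
                             predictor_name = ds$predictor_name,
                             adjuster_meta = list()),
                        class = "design_matrix")
  }
  if (is.null(design)) design <- build_design(ds)
  xc <- sweep(design$x, 2, design$center)
  p <- ncol(xc)

  if (mode == "right") {
    status <- as.integer(ds$event == 1L)
    if (any(ds$event >= 2L))
      warning("competing-event codes (>= 2) treated as censored", call. = FALSE)
    if (sum(status) < 1L)
      stop("unidentifiable: all observations are right-censored", call. = FALSE)
    tpos <- pmax(ds$time, .Machine$double.eps)
    loglam0 <- log(mean(tpos))
    args <- list(x = xc, mode = "right", time = tpos, status = status)
  } else {
    finite_info <- is.finite(ds$right) | (ds$left > 0)
    if (!any(is.finite(ds$right)))
      stop("unidentifiable: every interval is right-open (no finite right bound)",
           call. = FALSE)
    mid <- ifelse(is.finite(ds$right), (ds$left + ds$right) / 2, ds$left)
    loglam0 <- log(mean(pmax(mid, .Machine$double.eps)))
    args <- list(x = xc, mode = "interval", left = ds$left, right = ds$right)
  }

  if (is.null(fix_shape)) {
    theta0 <- c(0, loglam0, numeric(p))
    fn <- function(th) do.call(weibull_neg_loglik, c(list(theta = th), args))
    free <- seq_along(theta0)
  } else {
    stopifnot(fix_shape > 0)
    theta0 <- c(loglam0, numeric(p))
    fn <- function(th) do.call(weibull_neg_loglik,
                               c(list(theta = c(log(fix_shape), th)), args))
    free <- NULL
  }
  opt <- stats::optim(theta0, fn, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  if (opt$convergence != 0)
    stop("Weibull fit did not converge (optim code ", opt$convergence,
         ", ", opt$counts[1], " evaluations)", call. = FALSE)

  if (is.null(fix_shape)) {
    theta_c <- opt$par
  } else {
    theta_c <- c(log(fix_shape), opt$par)
  }
  H <- numeric_hessian(function(th) do.call(weibull_neg_loglik, c(list(theta = th), args)),
                       theta_c)
  full_names <- c("log_shape", "log_scale", design$column_names)
  if (is.null(fix_shape)) {
    cov_c <- tryCatch(solve(H), error = function(e) matrix(NA_real_, p + 2, p + 2))
  } else {
    cov_c <- matrix(0, p + 2, p + 2)
    cov_c[-1, -1] <- tryCatch(solve(H[-1, -1, drop = FALSE]),
                              error = function(e) matrix(NA_real_, p + 1, p + 1))
  }

  # un-center: log lambda = log lambda_c - center . gamma  (k, gamma unchanged)
  gamma <- theta_c[-(1:2)]
  loglam <- theta_c[2] - sum(design$center * gamma)
  A <- diag(p + 2)
  if (p > 0) A[2, 3:(p + 2)] <- -design$center
  covariance <- A %*% cov_c %*% t(A)
  dimnames(covariance) <- list(full_names, full_names)

  structure(list(
    shape = exp(theta_c[1]), scale = exp(loglam),
    gamma = setNames(gamma, design$column_names),
    log_shape = theta_c[1], log_scale = loglam,
    covariance = covariance, loglik = -opt$value,
    censoring_mode = mode, fixed_shape = !is.null(fix_shape),
    column_names = design$column_names, center = design$center,
    design = design, dataset = ds, n = ds$n
  ), class = "weibull_fit")
}

# log Lambda(t|x) = k (log t - mu), mu = log lambda + x gamma, with the
# delta-method variance from the (log k, log lambda, gamma) covariance:
# gradient (log Lambda, -k, -k x).
weibull_cumhaz_at <- function(fit, x_row, times) {
  if (any(times < 0)) stop("prediction times must be >= 0", call. = FALSE)
  k <- fit$shape
  mu <- fit$log_scale + sum(x_row * fit$gamma)
  loglam_t <- ifelse(times > 0, k * (log(times) - mu), -Inf)
  p <- length(fit$gamma)
  var_log <- rep(NA_real_, length(times))
  ok <- is.finite(loglam_t)
  if (any(ok) && all(is.finite(fit$covariance))) {
    g <- cbind(loglam_t[ok], rep(-k, sum(ok)))
    if (p > 0) g <- cbind(g, matrix(rep(-k * x_row, each = sum(ok)), ncol = p))
    var_log[ok] <- rowSums((g %*% fit$covariance) * g)
  }
  list(cumhaz = exp(loglam_t), var_log_cumhaz = var_log)
}

#' Predict conditional survival from a Weibull fit
#'
#' @inheritParams predict_survival_cox
#' @param fit a `weibull_fit`
#' @return a tibble with `time`, `estimate`, `var_log_cumhaz` and optional
#'   `lower`, `upper` (log(-log) scale delta bands)
#' @export
predict_survival_weibull <- function(fit, covariate_row, times, ci_level = NULL) {
  stopifnot(inherits(fit, "weibull_fit"))
  x_row <- align_covariate_row(covariate_row, fit$column_names)
  ch <- weibull_cumhaz_at(fit, x_row, times)
  out <- tibble::tibble(time = times, estimate = exp(-ch$cumhaz),
                        var_log_cumhaz = ch$var_log_cumhaz)
  if (!is.null(ci_level)) {
    bands <- loglog_bands(out$estimate, ch$var_log_cumhaz, ci_level, "survival")
    out$lower <- bands$lower; out$upper <- bands$upper
  }
  out
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat("<weibull_fit>", x$censoring_mode, "censoring | n =", x$n, "\n")
  cat("  shape k =", format(x$shape), " scale lambda =", format(x$scale), "\n")
  if (length(x$gamma) > 0) {
    cat("  AFT coefficients (log-time scale); beta_PH = -k * gamma:\n")
    print(data.frame(gamma = x$gamma, beta_PH = -x$shape * x$gamma))
  }
  cat("log likelihood:", format(x$loglik), "\n")
  invisible(x)
}
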