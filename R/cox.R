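# Native Cox proportional-hazards machinery: Newton-Raphson on the partial
# likelihood (Efron or Breslow ties), Breslow baseline cumulative hazard,
# and conditional survival prediction with the standard asymptotic variance.

# Pre-group a stratum's sorted data for fast repeated likelihood evaluation.
# idx: subject indices sorted by increasing time within the stratum.
cox_stratum_groups <- function(time, status, idx) {
  t_s <- time[idx]
  evt_times <- sort(unique(t_s[status[idx] == 1L]))
  groups <- lapply(evt_times, function(tt) {
    j0 <- match(TRUE, t_s >= tt)  # first sorted position in the risk set
    D <- which(t_s == tt & status[idx] == 1L)
    list(time = tt, j0 = j0, D = D, d = length(D))
  })
  list(idx = idx, groups = groups)
}

rev_cumsum <- function(m) {
  if (is.null(dim(m))) rev(cumsum(rev(m)))
  else apply(m, 2, function(col) rev(cumsum(rev(col))))
}

# Log partial likelihood, score and information for centered design xc.
# strata_pre: list of cox_stratum_groups results.
cox_loglik <- function(beta, xc, strata_pre, ties) {
  p <- ncol(xc)
  pairs <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)  # p(p+1)/2
  eta_all <- drop(xc %*% beta)
  ll <- 0; g <- numeric(p); H <- matrix(0, p, p)
  for (st in strata_pre) {
    idx <- st$idx
    if (length(st$groups) == 0L) next
    x_s <- xc[idx, , drop = FALSE]
    eta <- eta_all[idx]
    w <- exp(eta)
    wx <- x_s * w
    wxx <- matrix(0, length(idx), nrow(pairs))
    for (k in seq_len(nrow(pairs)))
      wxx[, k] <- w * x_s[, pairs[k, 1]] * x_s[, pairs[k, 2]]
    S0suf <- rev_cumsum(w)
    S1suf <- matrix(rev_cumsum(wx), ncol = p)
    S2suf <- matrix(rev_cumsum(wxx), ncol = nrow(pairs))
    unpack <- function(v) {
      m <- matrix(0, p, p)
      m[cbind(pairs[, 1], pairs[, 2])] <- v
      m[cbind(pairs[, 2], pairs[, 1])] <- v
      m
    }
    for (gr in st$groups) {
      S0R <- S0suf[gr$j0]
      S1R <- S1suf[gr$j0, ]
      S2R <- unpack(S2suf[gr$j0, ])
      D <- gr$D; d <- gr$d
      ll <- ll + sum(eta[D])
      g <- g + colSums(x_s[D, , drop = FALSE])
      if (ties == "breslow" || d == 1L) {
        m1 <- S1R / S0R
        ll <- ll - d * log(S0R)
        g <- g - d * m1
        H <- H - d * (S2R / S0R - tcrossprod(m1))
      } else {
        S0D <- sum(w[D])
        S1D <- colSums(wx[D, , drop = FALSE])
        S2D <- unpack(colSums(wxx[D, , drop = FALSE]))
        for (l in seq_len(d) - 1L) {
          f <- l / d
          S0l <- S0R - f * S0D
          m1 <- (S1R - f * S1D) / S0l
          ll <- ll - log(S0l)
          g <- g - m1
          H <- H - ((S2R - f * S2D) / S0l - tcrossprod(m1))
        }
      }
    }
  }
  list(loglik = ll, score = g, hessian = H)
}

cox_newton_raphson <- function(xc, strata_pre, ties, max_iter = 50,
                               rel_tol = 1e-12, beta_cap = 10) {
  p <- ncol(xc)
  beta <- numeric(p)
  cur <- cox_loglik(beta, xc, strata_pre, ties)
  loglik_null <- cur$loglik
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    info <- -cur$hessian
    step <- tryCatch(solve(info, cur$score), error = function(e)
      stop("degenerate design: the partial-likelihood information matrix is singular ",
           "(no within-stratum comparisons or collinear covariates)", call. = FALSE))
    halved <- 0L
    repeat {
      beta_new <- beta + step
      nxt <- cox_loglik(beta_new, xc, strata_pre, ties)
      if (is.finite(nxt$loglik) && nxt$loglik >= cur$loglik - 1e-12) break
      step <- step / 2
      halved <- halved + 1L
      if (halved > 30L)
        stop("Cox partial-likelihood maximization failed: step-halving exhausted at ",
             "iteration ", iter, call. = FALSE)
    }
    done <- abs(nxt$loglik - cur$loglik) < rel_tol * (abs(cur$loglik) + 1e-8)
    beta <- beta_new
    cur <- nxt
    settled <- done && max(abs(cur$score)) < 1e-6
    # monotone likelihood: the coefficient keeps drifting past the cap while
    # the maximizer is still moving (the score itself may vanish exponentially)
    if (any(abs(beta) > beta_cap) && !settled)
      stop("monotone partial likelihood: a coefficient diverged (|beta| > ", beta_cap,
           " with the maximizer still unsettled). The risk ordering is perfectly ",
           "separated by a covariate; remove or coarsen it.", call. = FALSE)
    if (settled) { converged <- TRUE; break }
  }
  list(beta = beta, loglik = cur$loglik, loglik_null = loglik_null,
       score = cur$score, information = -cur$hessian,
       n_iter = iter, converged = converged)
}

#' Fit a Cox proportional hazards model
#'
#' Newton-Raphson maximization of the partial likelihood on a numerically
#' centered design, with the Breslow baseline cumulative hazard
#' \eqn{\hat\Lambda_0(t) = \sum_{t_j \le t} d_j / \sum_{i \in R(t_j)} e^{x_i\hat\beta}}
#' computed per stratum. Ties are handled by the Efron (default) or Breslow
#' approximation.
#'
#' Competing-event codes (>= 2) are treated as censoring at their time (the
#' cause-specific hazard convention) with a warning; use [fit_fine_gray()]
#' to model the cumulative incidence directly.
#'
#' @param ds a `survival_dataset` (right-censored mode)
#' @param design a [build_design()] result; built from `ds` when `NULL`
#' @param ties `"efron"` or `"breslow"`
#' @param strata optional factor of stratum labels (length n); defaults to the
#'   dataset's stratum column in [fit_stratified_cox()]
#' @return a `cox_fit` with elements `beta`, `covariance` (inverse observed
#'   information), `baseline` (per-stratum Breslow step functions plus the
#'   risk-set quantities needed for prediction variances), `loglik`,
#'   `n_iter`, `converged`
#' @seealso [predict_survival_cox()], [breslow_baseline()], [fit_stratified_cox()]
#' @examples
#' ds <- gen_ph_weibull(sim_spec(n = 120, beta = 0.6, seed = 7))
#' fit <- fit_cox(ds)
#' exp(fit$beta)  # hazard ratio per unit of the predictor
#' @export
fit_cox <- function(ds, design = NULL, ties = c("efron", "breslow"), strata = NULL) {
  ties <- match.arg(ties)
  stopifnot(inherits(ds, "survival_dataset"))
  if (ds$mode != "right")
    stop("fit_cox needs right-censored data; use fit_weibull(mode = 'interval') ",
         "for interval censoring", call. = FALSE)
  if (is.null(design)) design <- build_design(ds)
  status <- as.integer(ds$event == 1L)
  if (any(ds$event >= 2L))
    warning("competing-event codes (>= 2) treated as censored at their time ",
            "(cause-specific hazard convention); consider fit_fine_gray()",
            call. = FALSE)
  if (sum(status) < 1L)
    stop("fit_cox needs at least one event of interest", call. = FALSE)

  time <- ds$time
  strata_f <- if (is.null(strata)) factor(rep("all", ds$n)) else factor(strata)
  levs <- levels(strata_f)
  zero_evt <- vapply(levs, function(l) sum(status[strata_f == l]) == 0L, logical(1))
  if (any(zero_evt))
    warning("stratum/strata with zero events contribute no partial-likelihood terms: ",
            paste(levs[zero_evt], collapse = ", "), call. = FALSE)

  xc <- sweep(design$x, 2, design$center)
  strata_pre <- lapply(levs, function(l) {
    sub <- which(strata_f == l)
    cox_stratum_groups(time, status, sub[order(time[sub])])
  })
  nr <- cox_newton_raphson(xc, strata_pre, ties)
  covariance <- solve(nr$information)
  dimnames(covariance) <- list(design$column_names, design$column_names)
  beta <- setNames(nr$beta, design$column_names)

  baseline <- cox_baseline_tables(beta, design, time, status, strata_f, levs)

  structure(list(
    beta = beta, covariance = covariance,
    column_names = design$column_names, center = design$center,
    ties = ties, loglik = nr$loglik, loglik_null = nr$loglik_null,
    n_iter = nr$n_iter, converged = nr$converged,
    baseline = baseline, strata_levels = levs,
    stratified = !is.null(strata),
    design = design, dataset = ds, strata = if (is.null(strata)) NULL else strata_f,
    n = ds$n, n_event = sum(status)
  ), class = "cox_fit")
}

# Per-stratum Breslow tables on the uncentered covariate scale (reference
# x = 0): jump times, d_j, S0_j, risk-weighted covariate mean, increments,
# and the cumulative pieces the prediction variance needs.
cox_baseline_tables <- function(beta, design, time, status, strata_f, levs) {
  x <- design$x
  eta <- drop(x %*% beta)
  w <- exp(eta)
  out <- list()
  for (l in levs) {
    sub <- which(strata_f == l)
    tt <- sort(unique(time[sub][status[sub] == 1L]))
    J <- length(tt)
    d <- s0 <- inc <- numeric(J)
    xbar <- matrix(0, J, ncol(x))
    for (j in seq_len(J)) {
      risk <- sub[time[sub] >= tt[j]]
      d[j] <- sum(time[sub] == tt[j] & status[sub] == 1L)
      s0[j] <- sum(w[risk])
      xbar[j, ] <- colSums(x[risk, , drop = FALSE] * w[risk]) / s0[j]
      inc[j] <- d[j] / s0[j]
    }
    cum_qbar <- matrix(0, J, ncol(x))
    if (J > 0L) for (k in seq_len(ncol(x))) cum_qbar[, k] <- cumsum(xbar[, k] * inc)
    out[[l]] <- list(times = tt, d = d, s0 = s0, xbar = xbar,
                     increments = inc, cumhaz = cumsum(inc),
                     cum_v1 = cumsum(d / s0^2), cum_qbar = cum_qbar)
  }
  out
}

#' Breslow baseline cumulative hazard
#'
#' The estimated baseline cumulative hazard of a fitted Cox model as a
#' right-continuous step function (reference covariate value x = 0).
#' With all coefficients equal to zero it reduces exactly to the
#' Nelson-Aalen estimator.
#'
#' @param fit a `cox_fit`
#' @param stratum stratum label; defaults to the single stratum of an
#'   unstratified fit
#' @return a `step_fun` with `Lambda(0) = 0`
#' @export
breslow_baseline <- function(fit, stratum = NULL) {
  stopifnot(inherits(fit, "cox_fit"))
  b <- cox_pick_stratum(fit, stratum)
  new_step_fun(b$times, b$cumhaz, init = 0)
}

cox_pick_stratum <- function(fit, stratum) {
  if (is.null(stratum)) {
    if (length(fit$baseline) > 1L)
      stop("stratified fit: specify `stratum` (one of ",
           paste(fit$strata_levels, collapse = ", "), ")", call. = FALSE)
    fit$baseline[[1L]]
  } else {
    if (!as.character(stratum) %in% names(fit$baseline))
      stop("unknown stratum '", stratum, "'", call. = FALSE)
    fit$baseline[[as.character(stratum)]]
  }
}

# Cumulative hazard and variance of log Lambda-hat(t | x) at a covariate row.
# Standard asymptotic variance combining the Breslow-increment term and the
# delta-method term in beta-hat:
#   Var(Lambda-hat(t|x)) = e^{2 x beta} [ sum_j d_j/S0_j^2 + q(t)' V q(t) ],
#   q(t) = sum_j (d_j/S0_j) (x - xbar_j).
cox_cumhaz_at <- function(fit, x_row, times, stratum = NULL) {
  if (any(times < 0)) stop("prediction times must be >= 0", call. = FALSE)
  cumhaz_table_at(cox_pick_stratum(fit, stratum), fit$beta, fit$covariance,
                  x_row, times)
}

# Shared by the Cox and Fine-Gray predictors: step lookup of the baseline
# table plus the asymptotic variance of log Lambda-hat(t | x).
cumhaz_table_at <- function(b, beta, covariance, x_row, times) {
  eta <- sum(x_row * beta)
  idx <- findInterval(times, b$times)
  lam0 <- c(0, b$cumhaz)[idx + 1L]
  v1 <- c(0, b$cum_v1)[idx + 1L]
  qbar <- rbind(0, b$cum_qbar)[idx + 1L, , drop = FALSE]
  var_log <- rep(NA_real_, length(times))
  pos <- lam0 > 0
  if (any(pos)) {
    q <- lam0[pos] %o% x_row - qbar[pos, , drop = FALSE]
    quad <- rowSums((q %*% covariance) * q)
    var_log[pos] <- (v1[pos] + quad) / lam0[pos]^2
  }
  list(cumhaz = lam0 * exp(eta), var_log_cumhaz = var_log)
}

#' Predict conditional survival from a Cox fit
#'
#' Evaluates \eqn{\hat S(t | x) = \exp(-\hat\Lambda_0(t) e^{x\hat\beta})} by
#' step lookup, with the variance of \eqn{\log\hat\Lambda(t|x)} from the
#' standard asymptotic formula (Breslow-increment variance plus the
#' delta-method term in \eqn{\hat\beta}). Confidence limits are symmetric on
#' the \eqn{\log(-\log S)} scale, hence always inside (0, 1).
#'
#' @param fit a `cox_fit`
#' @param covariate_row named numeric vector matching the design columns
#'   (see [design_row()])
#' @param times non-negative prediction times
#' @param stratum stratum label for stratified fits
#' @param ci_level confidence level, or `NULL` for no bands
#' @return a tibble with `time`, `estimate`, `var_log_cumhaz` and, when
#'   `ci_level` is given, `lower`, `upper`
#' @export
predict_survival_cox <- function(fit, covariate_row, times, stratum = NULL,
                                 ci_level = NULL) {
  stopifnot(inherits(fit, "cox_fit"))
  x_row <- align_covariate_row(covariate_row, fit$column_names)
  ch <- cox_cumhaz_at(fit, x_row, times, stratum)
  out <- tibble::tibble(time = times, estimate = exp(-ch$cumhaz),
                        var_log_cumhaz = ch$var_log_cumhaz)
  if (!is.null(ci_level)) {
    bands <- loglog_bands(out$estimate, ch$var_log_cumhaz, ci_level,
                          outcome = "survival")
    out$lower <- bands$lower; out$upper <- bands$upper
  }
  out
}

align_covariate_row <- function(covariate_row, column_names) {
  if (!is.null(names(covariate_row))) {
    missing <- setdiff(column_names, names(covariate_row))
    if (length(missing) > 0)
      stop("covariate row is missing column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    covariate_row <- covariate_row[column_names]
  } else if (length(covariate_row) != length(column_names)) {
    stop("covariate row has length ", length(covariate_row), "; design has ",
         length(column_names), " column(s)", call. = FALSE)
  }
  as.numeric(covariate_row)
}

# Symmetric normal interval on the log(-log) scale, back-transformed.
# For survival S: log(-log S) +/- z se;  for incidence F the same transform
# is applied to 1 - F. Degenerate cells (S in {0,1}) collapse to the point.
loglog_bands <- function(est, var_log_cumhaz, ci_level, outcome) {
  s <- if (outcome == "survival") est else 1 - est
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  lower <- upper <- s
  ok <- is.finite(var_log_cumhaz) & var_log_cumhaz >= 0 & s > 0 & s < 1
  se <- sqrt(var_log_cumhaz[ok])
  loglam <- log(-log(s[ok]))
  s_lo <- exp(-exp(loglam + z * se))  # lower survival
  s_hi <- exp(-exp(loglam - z * se))
  lower[ok] <- s_lo; upper[ok] <- s_hi
  if (outcome == "survival") list(lower = lower, upper = upper)
  else list(lower = 1 - upper, upper = 1 - lower)
}

#' Fit a stratified Cox model
#'
#' Shared coefficients across strata, separate Breslow baseline hazards per
#' stratum: the partial likelihood is the product of the within-stratum
#' partial likelihoods, so the baseline hazard is free to differ across
#' levels of the stratum variable.
#'
#' @param ds a `survival_dataset` with a stratum role (or pass `stratum`)
#' @param design optional [build_design()] result
#' @param stratum optional vector of stratum labels overriding the dataset's
#' @param ties `"efron"` or `"breslow"`
#' @return a `cox_fit` with one baseline per stratum
#' @export
fit_stratified_cox <- function(ds, design = NULL, stratum = NULL,
                               ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  strata_f <- if (!is.null(stratum)) factor(stratum) else ds$strata
  if (is.null(strata_f))
    stop("fit_stratified_cox needs a stratum column (roles) or `stratum` labels",
         call. = FALSE)
  if (nlevels(droplevels(strata_f)) < 2L)
    stop("fit_stratified_cox needs >= 2 strata", call. = FALSE)
  fit_cox(ds, design = design, ties = ties, strata = droplevels(strata_f))
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("<cox_fit>", if (x$stratified) "stratified," else "",
      "ties =", x$ties, "| n =", x$n, "| events =", x$n_event, "\n")
  se <- sqrt(diag(x$covariance))
  print(data.frame(coef = x$beta, `exp(coef)` = exp(x$beta), se = se,
                   z = x$beta / se, check.names = FALSE))
  cat("log partial likelihood:", format(x$loglik), "(", x$n_iter, "iterations )\n")
  invisible(x)
}
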