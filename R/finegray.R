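# Fine-Gray subdistribution-hazard regression for competing risks.
#
# Subjects who fail from a competing cause remain in the subdistribution
# risk set after their failure, down-weighted by the inverse probability of
# censoring: w_i(t) = G(t-) / G(T_i-), where G is the Kaplan-Meier estimate
# of the censoring distribution (left-continuous, the standard convention).
# Estimation is a weighted Cox-type Newton-Raphson (Breslow ties); the
# baseline subdistribution cumulative hazard uses the weighted Breslow
# formula. The covariance is the inverse weighted observed information,
# which is approximate for Fine-Gray (bootstrap bands are available through
# surface_ci()).

fg_weight_matrix <- function(time, event, evt_times, G) {
  n <- length(time); J <- length(evt_times)
  W <- matrix(0, n, J)
  g_at <- eval_step_left(G, evt_times)           # G(t_j -)
  g_own <- eval_step_left(G, time)               # G(T_i -)
  for (j in seq_len(J)) {
    at_risk <- time >= evt_times[j]
    W[at_risk, j] <- 1
    past_comp <- !at_risk & event >= 2L & g_own > 0
    W[past_comp, j] <- g_at[j] / g_own[past_comp]
  }
  W
}

fg_loglik <- function(beta, xc, eta_fixed = NULL, W, d1_idx, tie_group, d) {
  # d1_idx: indices of cause-1 events; tie_group: their event-time group;
  # d: events per group (Breslow ties)
  eta <- drop(xc %*% beta)
  w_exp <- exp(eta)
  p <- ncol(xc)
  pairs <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  S0 <- drop(crossprod(W, w_exp))
  S1 <- crossprod(W, xc * w_exp)
  wxx <- matrix(0, nrow(xc), nrow(pairs))
  for (k in seq_len(nrow(pairs)))
    wxx[, k] <- w_exp * xc[, pairs[k, 1]] * xc[, pairs[k, 2]]
  S2 <- crossprod(W, wxx)
  ll <- sum(eta[d1_idx]) - sum(d * log(S0))
  m1 <- S1 / S0
  g <- colSums(xc[d1_idx, , drop = FALSE]) - colSums(m1 * d)
  H <- matrix(0, p, p)
  for (j in seq_along(d)) {
    S2j <- matrix(0, p, p)
    S2j[cbind(pairs[, 1], pairs[, 2])] <- S2[j, ]
    S2j[cbind(pairs[, 2], pairs[, 1])] <- S2[j, ]
    H <- H - d[j] * (S2j / S0[j] - tcrossprod(m1[j, ]))
  }
  list(loglik = ll, score = g, hessian = H, S0 = S0, S1 = S1)
}

#' Fit a Fine-Gray subdistribution-hazard model
#'
#' Models the cumulative incidence of the event of interest (cause 1) in the
#' presence of competing causes (event codes >= 2). The subdistribution risk
#' set keeps subjects who failed from a competing cause, weighted by
#' \eqn{\hat G(t-)/\hat G(T_i-)} (IPCW with the censoring Kaplan-Meier);
#' coefficients maximize the weighted partial likelihood (Breslow ties) by
#' Newton-Raphson under the same convergence and divergence rules as
#' [fit_cox()]. The predicted cumulative incidence is
#' \eqn{\hat F_1(t|x) = 1 - \exp\{-\hat\Lambda_{10}(t) e^{x\hat\beta}\}}.
#'
#' With zero competing events all weights are 1 and the fit coincides with
#' a Breslow-ties Cox fit.
#'
#' @param ds a `survival_dataset`; usually flagged `competing_risks`
#' @param design optional [build_design()] result
#' @return a `fine_gray_fit` with `beta`, `covariance` (inverse weighted
#'   observed information; approximate), `baseline` (weighted Breslow
#'   subdistribution cumulative hazard), `censoring_survival` (the censoring
#'   Kaplan-Meier \eqn{\hat G})
#' @examples
#' ds <- gen_competing(sim_spec(n = 300, beta = 0.5, seed = 11,
#'                              competing = list(p = 0.4)))
#' fit <- fit_fine_gray(ds)
#' fit$beta
#' @export
fit_fine_gray <- function(ds, design = NULL) {
  stopifnot(inherits(ds, "survival_dataset"))
  if (ds$mode != "right")
    stop("fit_fine_gray needs right-censored (not interval) data", call. = FALSE)
  if (is.null(design)) design <- build_design(ds)
  time <- ds$time; event <- ds$event
  if (sum(event == 1L) < 1L)
    stop("fit_fine_gray needs at least one event of interest (code 1)", call. = FALSE)

  G <- censoring_km(time, event)
  evt_times <- sort(unique(time[event == 1L]))
  W <- fg_weight_matrix(time, event, evt_times, G)
  d1_idx <- which(event == 1L)
  tie_group <- match(time[d1_idx], evt_times)
  d <- as.numeric(tabulate(tie_group, nbins = length(evt_times)))

  xc <- sweep(design$x, 2, design$center)
  p <- ncol(xc)
  beta <- numeric(p)
  cur <- fg_loglik(beta, xc, W = W, d1_idx = d1_idx, tie_group = tie_group, d = d)
  loglik_null <- cur$loglik
  converged <- FALSE
  for (iter in seq_len(50L)) {
    info <- -cur$hessian
    step <- tryCatch(solve(info, cur$score), error = function(e)
      stop("degenerate design: singular weighted information matrix", call. = FALSE))
    halved <- 0L
    repeat {
      beta_new <- beta + step
      nxt <- fg_loglik(beta_new, xc, W = W, d1_idx = d1_idx, tie_group = tie_group, d = d)
      if (is.finite(nxt$loglik) && nxt$loglik >= cur$loglik - 1e-12) break
      step <- step / 2; halved <- halved + 1L
      if (halved > 30L)
        stop("Fine-Gray maximization failed: step-halving exhausted", call. = FALSE)
    }
    done <- abs(nxt$loglik - cur$loglik) < 1e-12 * (abs(cur$loglik) + 1e-8)
    beta <- beta_new; cur <- nxt
    if (any(abs(beta) > 10) && max(abs(cur$score)) > 1e-3)
      stop("monotone weighted partial likelihood: a coefficient diverged", call. = FALSE)
    if (done && max(abs(cur$score)) < 1e-6) { converged <- TRUE; break }
  }
  covariance <- solve(-cur$hessian)
  dimnames(covariance) <- list(design$column_names, design$column_names)
  beta <- setNames(beta, design$column_names)

  # weighted Breslow baseline on the uncentered scale (reference x = 0)
  shift <- exp(sum(design$center * beta))
  s0_unc <- cur$S0 * shift
  xbar <- sweep(cur$S1 / cur$S0, 2, design$center, `+`)
  inc <- d / s0_unc
  cum_qbar <- matrix(0, length(evt_times), p)
  for (k in seq_len(p)) cum_qbar[, k] <- cumsum(xbar[, k] * inc)
  baseline <- list(times = evt_times, d = d, s0 = s0_unc, xbar = xbar,
                   increments = inc, cumhaz = cumsum(inc),
                   cum_v1 = cumsum(d / s0_unc^2), cum_qbar = cum_qbar)

  structure(list(
    beta = beta, covariance = covariance,
    column_names = design$column_names, center = design$center,
    loglik = cur$loglik, loglik_null = loglik_null,
    n_iter = iter, converged = converged,
    baseline = baseline, censoring_survival = G,
    design = design, dataset = ds, n = ds$n,
    n_event = sum(event == 1L), n_competing = sum(event >= 2L)
  ), class = "fine_gray_fit")
}

#' Predict cumulative incidence from a Fine-Gray fit
#'
#' \eqn{\hat F_1(t|x) = 1 - \exp\{-\hat\Lambda_{10}(t) e^{x\hat\beta}\}},
#' non-decreasing in t and inside [0, 1). Delta-method bands are symmetric
#' on the \eqn{\log(-\log(1 - \hat F_1))} scale.
#'
#' @inheritParams predict_survival_cox
#' @param fit a `fine_gray_fit`
#' @return a tibble with `time`, `estimate` (cumulative incidence),
#'   `var_log_cumhaz` and optional `lower`, `upper`
#' @export
predict_cif_fine_gray <- function(fit, covariate_row, times, ci_level = NULL) {
  stopifnot(inherits(fit, "fine_gray_fit"))
  if (any(times < 0)) stop("prediction times must be >= 0", call. = FALSE)
  x_row <- align_covariate_row(covariate_row, fit$column_names)
  ch <- cumhaz_table_at(fit$baseline, fit$beta, fit$covariance, x_row, times)
  out <- tibble::tibble(time = times, estimate = 1 - exp(-ch$cumhaz),
                        var_log_cumhaz = ch$var_log_cumhaz)
  if (!is.null(ci_level)) {
    bands <- loglog_bands(out$estimate, ch$var_log_cumhaz, ci_level, "incidence")
    out$lower <- bands$lower; out$upper <- bands$upper
  }
  out
}

#' @export
print.fine_gray_fit <- function(x, ...) {
  cat("<fine_gray_fit> n =", x$n, "| cause-1 events =", x$n_event,
      "| competing =", x$n_competing, "\n")
  se <- sqrt(diag(x$covariance))
  print(data.frame(coef = x$beta, `exp(coef)` = exp(x$beta), se = se,
                   z = x$beta / se, check.names = FALSE))
  invisible(x)
}
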