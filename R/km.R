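#' Kaplan-Meier product-limit estimator
#'
#' Nonparametric estimate of the survival function with Greenwood variance.
#' Used directly as the nonparametric baseline and internally as the
#' censoring-distribution estimate for inverse-probability-of-censoring
#' weighting (Fine-Gray risk sets, integrated Brier score).
#'
#' @param times non-negative observation times
#' @param event_flags 1 = event observed, 0 = censored (logical accepted)
#' @return an object of class `km_fit`: a [step function][new_step_fun] over
#'   the distinct event times with fields `surv`, `var` (Greenwood variance of
#'   S-hat at each knot), `n_risk`, `n_event` and the sample size `n`.
#'   `S(0) = 1`; the curve is right-continuous.
#' @examples
#' km <- kaplan_meier(c(1, 2, 3), c(1, 0, 1))
#' km_survival(km, c(1, 3))  # 2/3, 1/3
#' @export
kaplan_meier <- function(times, event_flags) {
  times <- as.numeric(times)
  event_flags <- as.integer(as.logical(event_flags))
  if (length(times) < 1) stop("kaplan_meier: need at least one observation", call. = FALSE)
  if (any(!is.finite(times)) || any(times < 0))
    stop("kaplan_meier: times must be finite and non-negative", call. = FALSE)
  if (length(event_flags) != length(times))
    stop("kaplan_meier: times and event_flags lengths differ", call. = FALSE)

  evt <- sort(unique(times[event_flags == 1L]))
  if (length(evt) == 0L) {
    f <- new_step_fun(numeric(0), numeric(0), init = 1)
    f$surv <- numeric(0); f$var <- numeric(0)
    f$n_risk <- integer(0); f$n_event <- integer(0); f$n <- length(times)
    class(f) <- c("km_fit", class(f))
    return(f)
  }
  n_risk <- vapply(evt, function(t) sum(times >= t), numeric(1))
  d <- vapply(evt, function(t) sum(times == t & event_flags == 1L), numeric(1))
  surv <- cumprod(1 - d / n_risk)
  # Greenwood: Var(S) = S^2 * sum d / (n (n - d)); term is 0 where S hits 0
  gw <- ifelse(n_risk > d, d / (n_risk * (n_risk - d)), 0)
  var <- surv^2 * cumsum(gw)
  f <- new_step_fun(evt, surv, init = 1)
  f$surv <- surv; f$var <- var
  f$n_risk <- as.integer(n_risk); f$n_event <- as.integer(d); f$n <- length(times)
  class(f) <- c("km_fit", class(f))
  f
}

#' Evaluate a Kaplan-Meier curve
#' @param fit a `km_fit`
#' @param t evaluation times
#' @param left if `TRUE`, return the left limit S(t-) instead of S(t)
#' @return survival probabilities
#' @export
km_survival <- function(fit, t, left = FALSE) {
  if (left) eval_step_left(fit, t) else eval_step(fit, t)
}

#' Kaplan-Meier estimate of the censoring distribution
#'
#' Flips the event coding (censoring becomes the "event") and applies the
#' product-limit estimator, yielding the censoring survival function G-hat
#' used for IPCW. Any event code >= 1 counts as a true event, i.e. not
#' censoring.
#'
#' @param times observation times
#' @param events event codes (0 censored, >= 1 an event of any cause)
#' @return a `km_fit` for G-hat with G(0) = 1, non-increasing
#' @export
censoring_km <- function(times, events) {
  kaplan_meier(times, as.integer(events) == 0L)
}
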