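# Model-selection guidance and model-fit metrics. The recommendation logic
# reconstructs the guided decision flow: competing-risks and
# interval-censoring gates first, then the model-family preference, then
# stratification.

#' Describe a study for model selection
#'
#' @param competing_risks can the event of interest be precluded by another
#'   event (e.g. death before progression)?
#' @param interval_censored are event times only known to fall between
#'   scheduled visits?
#' @param family preference for the survival-model family:
#'   `"parametric"`, `"nonparametric"`, `"semiparametric"` or `"unsure"`
#' @param needs_strata should the baseline hazard differ across levels of a
#'   covariate?
#' @return a `study_answers` object
#' @export
study_answers <- function(competing_risks = FALSE, interval_censored = FALSE,
                          family = c("unsure", "parametric", "nonparametric",
                                     "semiparametric"),
                          needs_strata = FALSE) {
  family <- match.arg(family)
  structure(list(competing_risks = isTRUE(competing_risks),
                 interval_censored = isTRUE(interval_censored),
                 family = family, needs_strata = isTRUE(needs_strata)),
            class = "study_answers")
}

#' Recommend a survival model for a study design
#'
#' Competing risks route to the Fine-Gray model; interval censoring to the
#' parametric Weibull likelihood; otherwise the family preference decides:
#' parametric = Weibull, nonparametric = spline-based hazard (available only
#' through a [backend adapter][backend_adapter]), semiparametric or unsure =
#' Cox, refined to the stratified Cox when the baseline hazard should differ
#' across strata. Competing risks combined with interval censoring is not a
#' supported combination.
#'
#' @param answers a [study_answers()] object
#' @return list with `model` (one of `fine_gray`, `weibull_interval`,
#'   `weibull`, `spline_backend`, `cox`, `stratified_cox`), a one-line
#'   `rationale`, and `backend_required`
#' @examples
#' recommend_model(study_answers(competing_risks = TRUE))$model
#' @export
recommend_model <- function(answers) {
  stopifnot(inherits(answers, "study_answers"))
  if (answers$competing_risks && answers$interval_censored)
    stop("unsupported combination: competing risks together with interval ",
         "censoring is not covered by the available models", call. = FALSE)
  if (answers$competing_risks)
    return(list(model = "fine_gray", backend_required = FALSE,
                rationale = "competing events preclude the event of interest; model the cumulative incidence directly"))
  if (answers$interval_censored)
    return(list(model = "weibull_interval", backend_required = FALSE,
                rationale = "event times known only within visit windows; parametric interval-censored likelihood"))
  base <- switch(answers$family,
    parametric = list(model = "weibull", backend_required = FALSE,
                      rationale = "parametric fit favors out-of-sample prediction"),
    nonparametric = list(model = "spline_backend", backend_required = TRUE,
                         rationale = "flexible hazard shape via a spline-based model (external backend required)"),
    list(model = "cox", backend_required = FALSE,
         rationale = "semiparametric Cox model avoids baseline-hazard assumptions"))
  if (answers$needs_strata && base$model == "cox") {
    base$model <- "stratified_cox"
    base$rationale <- "Cox model with per-stratum baselines: the baseline hazard differs across strata"
  }
  base
}

#' Harrell's concordance index
#'
#' The fraction of comparable subject pairs in which the higher risk score
#' belongs to the subject with the earlier observed event. A pair is
#' comparable when one subject has an observed event strictly before the
#' other subject's observation time; score ties count 1/2. Pairs rendered
#' incomparable by censoring (or by tied times) are excluded.
#'
#' @param times observation times
#' @param event_flags 1 = event, 0 = censored
#' @param risk_scores higher = higher risk (earlier expected event)
#' @return concordance in [0, 1]
#' @examples
#' concordance_index(c(1, 2, 3), c(1, 1, 1), c(3, 2, 1))  # 1
#' @export
concordance_index <- function(times, event_flags, risk_scores) {
  n <- length(times)
  stopifnot(n >= 2, length(event_flags) == n, length(risk_scores) == n)
  event_flags <- as.integer(as.logical(event_flags))
  num <- den <- 0
  for (i in which(event_flags == 1L)) {
    later <- times > times[i]
    if (!any(later)) next
    den <- den + sum(later)
    num <- num + sum(risk_scores[i] > risk_scores[later]) +
      0.5 * sum(risk_scores[i] == risk_scores[later])
  }
  if (den == 0)
    stop("concordance undefined: no comparable pairs (all times tied or censored)",
         call. = FALSE)
  num / den
}

#' Integrated Brier score with IPCW
#'
#' Time-dependent Brier score
#' \eqn{BS(t) = n^{-1}\sum_i \hat S(t|x_i)^2 1\{T_i \le t, \delta_i = 1\}/\hat G(T_i^-)
#'   + (1-\hat S(t|x_i))^2 1\{T_i > t\}/\hat G(t)},
#' with \eqn{\hat G} the censoring Kaplan-Meier from [censoring_km()],
#' averaged over the window by the trapezoidal rule. Lower is better; a
#' constant prediction of 1/2 scores 0.25 on uncensored data.
#'
#' @param surv_prob n x m matrix of predicted survival probabilities
#'   \eqn{\hat S(t_g | x_i)}, columns matching `eval_times`
#' @param eval_times increasing evaluation times covering the window
#' @param times,event_flags observed follow-up and event indicator (1/0)
#' @param window integration window `c(a, b)`; default spans `eval_times`.
#'   If \eqn{\hat G} hits zero inside the window the window is truncated
#'   with a warning.
#' @return list with `ibs`, and `brier` (tibble of BS(t) over the grid used)
#' @export
integrated_brier <- function(surv_prob, eval_times, times, event_flags,
                             window = NULL) {
  surv_prob <- as.matrix(surv_prob)
  n <- length(times)
  stopifnot(nrow(surv_prob) == n, ncol(surv_prob) == length(eval_times),
            !is.unsorted(eval_times))
  event_flags <- as.integer(event_flags)
  if (is.null(window)) window <- range(eval_times)
  G <- censoring_km(times, event_flags)
  keep <- eval_times >= window[1] & eval_times <= window[2]
  tg <- eval_times[keep]
  g_at <- km_survival(G, tg)
  if (any(g_at <= 0)) {
    cut <- min(tg[g_at <= 0])
    warning("censoring survival reaches 0 at t = ", cut,
            "; integration window truncated", call. = FALSE)
    keep2 <- tg < cut
    tg <- tg[keep2]; g_at <- g_at[keep2]
  }
  if (length(tg) < 2)
    stop("integration window too narrow after truncation", call. = FALSE)
  sp <- surv_prob[, keep, drop = FALSE][, seq_along(tg), drop = FALSE]
  g_own <- km_survival(G, times, left = TRUE)  # G(T_i -)
  bs <- vapply(seq_along(tg), function(k) {
    t <- tg[k]
    died <- times <= t & event_flags == 1L
    alive <- times > t
    w_died <- ifelse(died & g_own > 0, 1 / g_own, 0)
    contrib <- sp[, k]^2 * died * w_died +
      (1 - sp[, k])^2 * alive / g_at[k]
    mean(contrib)
  }, numeric(1))
  width <- diff(range(tg))
  ibs <- sum(diff(tg) * (head(bs, -1) + tail(bs, -1)) / 2) / width
  list(ibs = ibs, brier = tibble::tibble(time = tg, brier = bs))
}

#' Predicted survival matrix for a fitted model
#'
#' Convenience for [integrated_brier()] and [concordance_index()]: evaluates
#' subject-level predictions \eqn{\hat S(t | x_i)} over a time grid from any
#' of the native fits.
#'
#' @param model a `cox_fit` or `weibull_fit`
#' @param eval_times evaluation time grid
#' @return n x length(eval_times) matrix
#' @export
predict_survival_matrix <- function(model, eval_times) {
  x <- model$design$x
  t(vapply(seq_len(nrow(x)), function(i) {
    row <- setNames(as.numeric(x[i, ]), colnames(x))
    if (inherits(model, "cox_fit")) {
      st <- if (model$stratified) as.character(model$strata[i]) else NULL
      predict_survival_cox(model, row, eval_times, stratum = st)$estimate
    } else {
      predict_survival_weibull(model, row, eval_times)$estimate
    }
  }, numeric(length(eval_times))))
}
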