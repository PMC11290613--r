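# Brute-force oracle: the Breslow-ties log partial likelihood written out
# directly from risk sets, maximized by grid + golden-section search. Kept
# deliberately independent of the package's internals.
brute_cox_loglik <- function(beta, time, status, x) {
  ll <- 0
  for (tt in sort(unique(time[status == 1]))) {
    D <- which(time == tt & status == 1)
    R <- which(time >= tt)
    ll <- ll + sum(x[D] * beta) - length(D) * log(sum(exp(x[R] * beta)))
  }
  ll
}

test_that("balanced binary covariate gives beta-hat = 0 by symmetry", {
  ds <- make_ds(time = c(1, 1, 2, 2), event = rep(1L, 4), x = c(0, 1, 0, 1))
  for (ties in c("efron", "breslow")) {
    fit <- fit_cox(ds, ties = ties)
    expect_equal(unname(fit$beta), 0, tolerance = 1e-10)
    expect_true(fit$converged)
  }
})

test_that("beta-hat maximizes the written-out partial likelihood (1-D scan)", {
  time <- c(1, 2, 3, 4); status <- c(1, 1, 1, 0); x <- c(1, 0, 1, 0)
  ds <- make_ds(time = time, event = status, x = x)
  fit <- fit_cox(ds, ties = "breslow")
  grid <- seq(-5, 5, by = 0.01)
  ll <- vapply(grid, brute_cox_loglik, numeric(1), time, status, x)
  peak <- grid[which.max(ll)]
  refined <- stats::optimize(brute_cox_loglik, c(peak - 0.02, peak + 0.02),
                             time = time, status = status, x = x, maximum = TRUE,
                             tol = 1e-9)
  expect_lt(abs(unname(fit$beta) - refined$maximum), 1e-3)
  expect_equal(fit$loglik, refined$objective, tolerance = 1e-6)
})

test_that("perfectly separated risk ordering raises a divergence error", {
  ds <- make_ds(time = c(1, 2), event = c(1, 1), x = c(1, 0))
  expect_error(fit_cox(ds), "monotone")
})

test_that("constant covariate raises a degenerate-design error", {
  df <- data.frame(time = 1:4, event = c(1, 1, 0, 1), x = c(1, 2, 3, 4), z = 1)
  ds <- as_survival_dataset(df, simple_roles(adjusters = "z"),
                            adjuster_types = c(z = "continuous"))
  expect_error(build_design(ds), "degenerate design")
})

test_that("competing codes are censored under plain Cox, with a warning", {
  ds <- make_ds(time = c(1, 2, 3, 4, 5), event = c(1L, 2L, 1L, 0L, 1L),
                x = c(0.5, 1, 0, 1.5, 0.2))
  expect_warning(fit <- fit_cox(ds), "competing")
  ds2 <- make_ds(time = c(1, 2, 3, 4, 5), event = c(1L, 0L, 1L, 0L, 1L),
                 x = c(0.5, 1, 0, 1.5, 0.2))
  expect_equal(fit$beta, fit_cox(ds2)$beta, tolerance = 1e-12)
})

test_that("coefficients, likelihood and baseline match coxph on random data", {
  set.seed(99)
  reps <- 0
  while (reps < 12) {
    n <- sample(12:30, 1)
    df <- data.frame(time = round(rexp(n), 2) + 0.1, event = rbinom(n, 1, 0.7),
                     x = rnorm(n), z1 = rnorm(n))
    if (sum(df$event) < 3) next
    ds <- as_survival_dataset(df, simple_roles(adjusters = "z1"),
                              adjuster_types = c(z1 = "continuous"))
    fit <- tryCatch(fit_cox(ds), error = function(e) NULL)
    orc <- survival::coxph(survival::Surv(time, event) ~ x + z1, data = df,
                           ties = "efron",
                           control = survival::coxph.control(eps = 1e-11, iter.max = 100))
    if (is.null(fit) || any(abs(coef(orc)) > 8)) next
    reps <- reps + 1
    expect_equal(unname(fit$beta), unname(coef(orc)), tolerance = 1e-6)
    expect_equal(fit$loglik, orc$loglik[2], tolerance = 1e-6)
    sf <- survival::survfit(orc, newdata = data.frame(x = 0, z1 = 0), ctype = 1)
    expect_equal(eval_step(breslow_baseline(fit), sf$time), sf$cumhaz,
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("Breslow baseline reduces exactly to Nelson-Aalen at beta = 0", {
  fit <- fit_cox(symmetric_ds(), ties = "breslow")
  expect_identical(unname(fit$beta), 0)
  b <- fit$baseline[[1]]
  expect_identical(b$increments, c(2 / 6, 2 / 4, 2 / 2))  # = 1/3, 1/2, 1
  na_hand <- cumsum(c(1 / 3, 1 / 2, 1))
  expect_equal(eval_step(breslow_baseline(fit), c(1, 2, 3)), na_hand, tolerance = 1e-15)
  # a single event whose covariate sits at the risk-set mean: beta-hat = 0,
  # and the hazard accrues nothing after the last event
  ds0 <- make_ds(time = 1:3, event = c(1L, 0L, 0L), x = c(0.6, 0.3, 0.9))
  f0 <- fit_cox(ds0)
  expect_equal(eval_step(breslow_baseline(f0), 2.5), eval_step(breslow_baseline(f0), 1))
})

test_that("shifting the covariate rescales the baseline by exp(-c beta)", {
  set.seed(5)
  df <- data.frame(time = round(rexp(30), 2) + 0.1, event = rbinom(30, 1, 0.8),
                   x = rnorm(30))
  ds <- as_survival_dataset(df, simple_roles())
  fit <- fit_cox(ds)
  df2 <- df; df2$x <- df$x + 2
  fit2 <- fit_cox(as_survival_dataset(df2, simple_roles()))
  expect_equal(fit2$beta, fit$beta, tolerance = 1e-8)
  # every exp(x_i beta) multiplied by exp(2 beta) => increments divided by it
  expect_equal(fit2$baseline[[1]]$increments * exp(2 * unname(fit$beta)),
               fit$baseline[[1]]$increments, tolerance = 1e-8)
})

test_that("survival prediction is exp(-Lambda0 exp(x beta)) with S(0) = 1", {
  ds <- gen_ph_weibull(sim_spec(n = 120, beta = c(0.6, -0.3), seed = 31))
  fit <- fit_cox(ds)
  bl <- breslow_baseline(fit)
  tq <- c(0, 1.3, 2.9, 8)
  row <- c(x = 0.7, z1 = -0.4)
  pred <- predict_survival_cox(fit, row, tq)
  expect_equal(pred$estimate,
               exp(-eval_step(bl, tq) * exp(sum(row * fit$beta))), tolerance = 1e-12)
  expect_identical(pred$estimate[1], 1)
  expect_error(predict_survival_cox(fit, row, -1), ">= 0")
  expect_error(predict_survival_cox(fit, c(x = 1), tq), "missing column")
})

test_that("analytic curve variance tracks the bootstrap at the covariate mean", {
  ds <- gen_ph_weibull(sim_spec(n = 200, beta = 0.5, seed = 77,
                                censoring = list(type = "exponential", rate = 0.08)))
  fit <- fit_cox(ds)
  xbar <- c(x = mean(ds$predictor))
  tq <- unname(quantile(ds$time[ds$event == 1], c(0.3, 0.6)))
  pred <- predict_survival_cox(fit, xbar, tq)
  var_s_analytic <- (pred$estimate * log(pred$estimate))^2 * pred$var_log_cumhaz

  boots <- matrix(NA_real_, 500, length(tq))
  set.seed(123)
  for (b in seq_len(nrow(boots))) {
    idx <- sample.int(ds$n, replace = TRUE)
    bs <- as_survival_dataset(ds$data[idx, ], ds$roles)
    bfit <- tryCatch(fit_cox(bs), error = function(e) NULL)
    if (is.null(bfit)) next
    boots[b, ] <- predict_survival_cox(bfit, xbar, tq)$estimate
  }
  var_boot <- apply(boots, 2, var, na.rm = TRUE)
  expect_lt(max(abs(var_s_analytic / var_boot - 1)), 0.25)
})

test_that("stratified fit: replication identity and degenerate strata", {
  set.seed(9)
  df <- data.frame(time = round(rexp(25), 2) + 0.1, event = rbinom(25, 1, 0.75),
                   x = rnorm(25))
  df2 <- rbind(df, df)
  df2$s <- rep(c("a", "b"), each = 25)
  ds1 <- as_survival_dataset(df, simple_roles())
  ds2 <- as_survival_dataset(df2, simple_roles(stratum = "s"))
  fit1 <- fit_cox(ds1)
  fit2 <- fit_stratified_cox(ds2)
  expect_equal(fit2$beta, fit1$beta, tolerance = 1e-9)
  expect_length(fit2$baseline, 2)

  dfu <- df; dfu$s <- paste0("id", seq_len(nrow(dfu)))
  dsu <- as_survival_dataset(dfu, simple_roles(stratum = "s"))
  expect_error(suppressWarnings(fit_stratified_cox(dsu)), "degenerate|singular")
})

test_that("stratified fit recovers the shared coefficient across baselines", {
  # two strata with different Weibull baselines, common beta = 0.7
  set.seed(55)
  n <- 500
  x <- rnorm(n)
  s <- rep(c("a", "b"), length.out = n)
  shape <- ifelse(s == "a", 1, 2); scale <- ifelse(s == "a", 3, 8)
  u <- runif(n)
  t <- scale * (-log(u) * exp(-0.7 * x))^(1 / shape)
  cens <- rexp(n, 0.05)
  df <- data.frame(time = pmin(t, cens), event = as.integer(t <= cens), x = x, s = s)
  ds <- as_survival_dataset(df, simple_roles(stratum = "s"))
  fit <- fit_stratified_cox(ds)
  se <- sqrt(diag(fit$covariance))[1]
  expect_lt(abs(unname(fit$beta["x"]) - 0.7), 3 * se)
})
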