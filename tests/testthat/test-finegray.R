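# Independent oracle: the weighted subdistribution partial likelihood written
# out from first principles (risk sets retaining prior competing failures,
# IPCW weights from the censoring KM left limit), scanned over beta.
brute_fg_loglik <- function(beta, time, cause, x) {
  cens_t <- sort(unique(time[cause == 0]))
  G <- function(t) {  # censoring KM, right-continuous
    s <- 1
    for (ct in cens_t) {
      if (ct > t) break
      n_risk <- sum(time >= ct)
      s <- s * (1 - sum(time == ct & cause == 0) / n_risk)
    }
    s
  }
  Gm <- function(t) {  # left limit G(t-)
    s <- 1
    for (ct in cens_t) {
      if (ct >= t) break
      s <- s * (1 - sum(time == ct & cause == 0) / sum(time >= ct))
    }
    s
  }
  ll <- 0
  for (j in which(cause == 1)) {
    tj <- time[j]
    denom <- 0
    for (i in seq_along(time)) {
      w <- if (time[i] >= tj) 1
           else if (cause[i] >= 2 && Gm(time[i]) > 0) Gm(tj) / Gm(time[i])
           else 0
      denom <- denom + w * exp(x[i] * beta)
    }
    ll <- ll + x[j] * beta - log(denom)
  }
  ll
}

test_that("six-subject worked example matches the brute-force scan", {
  time <- 1:6
  cause <- c(1L, 2L, 1L, 0L, 2L, 1L)
  x <- c(0, 1, 1, 0, 1, 0)
  ds <- make_ds(time = time, event = cause, x = x)
  fit <- fit_fine_gray(ds)
  grid <- seq(-5, 5, by = 0.01)
  ll <- vapply(grid, brute_fg_loglik, numeric(1), time, cause, x)
  peak <- grid[which.max(ll)]
  refined <- stats::optimize(brute_fg_loglik, c(peak - 0.02, peak + 0.02),
                             time = time, cause = cause, x = x,
                             maximum = TRUE, tol = 1e-9)
  expect_lt(abs(unname(fit$beta) - refined$maximum), 1e-3)
})

test_that("with zero competing events the fit reduces to Breslow-ties Cox", {
  set.seed(12)
  for (r in 1:5) {
    ds <- gen_ph_weibull(sim_spec(n = 60, beta = 0.5, seed = 200 + r,
                                  censoring = list(type = "exponential", rate = 0.15)))
    fg <- fit_fine_gray(ds)
    cx <- fit_cox(ds, ties = "breslow")
    expect_lt(max(abs(fg$beta - cx$beta)), 1e-8)
  }
})

test_that("coefficients match cmprsk::crr on competing-risks data", {
  for (r in 1:3) {
    ds <- gen_competing(sim_spec(n = 150, beta = c(0.5, -0.3), seed = 300 + r,
                                 competing = list(p = 0.4),
                                 censoring = list(type = "exponential", rate = 0.3)))
    fit <- fit_fine_gray(ds)
    orc <- cmprsk::crr(ds$time, ds$event, cbind(x = ds$predictor, z1 = ds$adjusters$z1),
                       failcode = 1, cencode = 0, gtol = 1e-10)
    expect_equal(unname(fit$beta), unname(orc$coef), tolerance = 1e-6)
  }
})

test_that("predicted incidence follows 1 - exp(-Lambda exp(x beta))", {
  ds <- gen_competing(sim_spec(n = 200, beta = 0.5, seed = 6,
                               competing = list(p = 0.4)))
  fit <- fit_fine_gray(ds)
  # closed-form spot check: at x with x beta = 0 and Lambda10(t) = L,
  # F1 = 1 - exp(-L)
  t1 <- fit$baseline$times[10]
  L <- fit$baseline$cumhaz[10]
  pred <- predict_cif_fine_gray(fit, c(x = 0), t1)
  expect_equal(pred$estimate, 1 - exp(-L), tolerance = 1e-12)

  tq <- seq(0, max(ds$time), length.out = 50)
  ci <- predict_cif_fine_gray(fit, c(x = 0.8), tq, ci_level = 0.95)
  expect_identical(ci$estimate[1], 0)  # F(0) = 0
  expect_true(all(diff(ci$estimate) >= -1e-12))
  expect_true(all(ci$estimate >= 0 & ci$estimate < 1))
  expect_true(all(ci$lower[-1] <= ci$estimate[-1] + 1e-12))
  expect_true(all(ci$upper[-1] >= ci$estimate[-1] - 1e-12))
})

test_that("cumulative-incidence arithmetic: Lambda = 0.2 at x beta = 0", {
  ds <- gen_competing(sim_spec(n = 120, beta = 0.5, seed = 44,
                               competing = list(p = 0.35)))
  fit <- fit_fine_gray(ds)
  # any time where the baseline reaches some L: prediction at x = 0 is 1 - e^-L
  idx <- which.min(abs(fit$baseline$cumhaz - 0.2))
  L <- fit$baseline$cumhaz[idx]
  expect_equal(predict_cif_fine_gray(fit, c(x = 0), fit$baseline$times[idx])$estimate,
               1 - exp(-L), tolerance = 1e-12)
})
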