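test_that("grid construction: linear spacing, quantile collapse, errors", {
  ds <- make_ds(time = c(1, 2, 3, 4), event = c(1, 1, 0, 1), x = c(0, 1, 0.5, 0.25))
  g <- build_grid(ds, "linear", n_points = 5)
  expect_equal(g$covariate_values, c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(g$time_grid, c(0, 1, 2, 4))  # unique event times, 0 prepended

  dsq <- make_ds(time = 1:4, event = rep(1L, 4), x = c(1, 1, 1, 2))
  gq <- build_grid(dsq, "quantile", n_points = 3)
  expect_equal(gq$covariate_values, c(1, 2))  # duplicates collapsed

  expect_error(build_grid(ds, n_points = 1), ">= 2")
  dsc <- make_ds(time = 1:3, event = rep(1L, 3), x = rep(1, 3))
  expect_error(build_grid(dsc), "degenerate axis")
})

test_that("default profile: median, mode, sorted-order tiebreak, overrides", {
  df <- data.frame(time = 1:6, event = rep(1L, 6), x = rnorm(6),
                   age = c(1, 2, 3, 1, 2, 3), sex = c("F", "F", "M", "F", "M", "F"),
                   g = c("b", "a", "b", "a", "b", "a"))
  ds <- as_survival_dataset(df, simple_roles(adjusters = c("age", "sex", "g")),
                            adjuster_types = c(age = "continuous"))
  prof <- default_profile(ds)
  expect_equal(prof$values$age, 2)
  expect_equal(prof$values$sex, "F")
  expect_equal(prof$values$g, "a")  # 3-3 tie -> sorted level order
  expect_equal(unname(prof$source["age"]), "default")

  prof2 <- default_profile(ds, overrides = list(age = 10))
  expect_equal(prof2$values$age, 10)
  expect_equal(unname(prof2$source["age"]), "user")
  expect_error(default_profile(ds, overrides = list(nope = 1)), "unknown adjuster")
})

test_that("a zero-coefficient fit yields identical surface rows", {
  fit <- fit_cox(symmetric_ds())
  surf <- compute_surface(fit, build_grid(fit$dataset, n_points = 7))
  expect_identical(unname(fit$beta), 0)
  for (i in 2:7) expect_equal(surf$values[i, ], surf$values[1, ], tolerance = 1e-12)
})

test_that("surface rows honor the monotone curve contracts", {
  set.seed(42)
  for (r in 1:10) {
    ds <- gen_ph_weibull(sim_spec(n = 80, beta = runif(1, -1, 1), seed = 400 + r,
                                  censoring = list(type = "exponential", rate = 0.1)))
    fit <- fit_cox(ds)
    surf <- compute_surface(fit, build_grid(ds, n_points = 9))
    expect_true(all(surf$values >= 0 & surf$values <= 1))
    expect_true(all(apply(surf$values, 1, function(r) all(diff(r) <= 1e-12))))
    expect_true(all(surf$values[, 1] == 1))  # S(0) = 1
    if (unname(fit$beta["x"]) > 0) {
      # higher predictor -> pointwise lower survival
      expect_true(all(diff(surf$values[, ncol(surf$values)]) <= 1e-12))
    }
    expect_true(all(surf$lower <= surf$values + 1e-12))
    expect_true(all(surf$upper >= surf$values - 1e-12))
  }
})

test_that("Weibull surface cell matches the closed form", {
  fit <- manual_weibull_fit(shape = 1, scale = 1, gamma = c(x = log(2)))
  fit$dataset <- NULL
  grid <- structure(list(covariate_values = c(0, 1), time_grid = c(0, 1),
                         predictor_range = c(0, 1)), class = "grid_spec")
  surf <- compute_surface(fit, grid, profile = list(), ci_level = NA)
  expect_equal(surf$values[2, 2], exp(-0.5), tolerance = 1e-12)
  expect_equal(surf$values[, 1], c(1, 1))
})

test_that("extrapolated covariate grids warn but do not error", {
  ds <- gen_ph_weibull(sim_spec(n = 60, beta = 0.5, seed = 2))
  fit <- fit_cox(ds)
  rng <- range(ds$predictor)
  far <- structure(list(covariate_values = seq(rng[1] - 2 * diff(rng),
                                               rng[2] + 2 * diff(rng), length.out = 5),
                        time_grid = c(0, sort(ds$time[ds$event == 1])),
                        predictor_range = rng), class = "grid_spec")
  expect_warning(compute_surface(fit, far), "extrapolation")
})

test_that("value_at: node lookup, interpolation, boundary and range errors", {
  surf <- manual_surface(values = rbind(c(1, 0.4), c(1, 0.6)),
                         time_grid = c(0, 2), covariate_values = c(0, 1))
  expect_identical(value_at(surf, 2, 0)$estimate, 0.4)   # exact node
  expect_identical(value_at(surf, 2, 1)$estimate, 0.6)
  expect_equal(value_at(surf, 2, 0.5)$estimate, 0.5)     # linear in x
  expect_equal(value_at(surf, 1.99, 0.5)$estimate, 1)    # step in t: before knot
  surf2 <- manual_surface(values = rbind(c(0.9, 0.4), c(0.8, 0.6)),
                          time_grid = c(1, 2), covariate_values = c(0, 1))
  expect_equal(value_at(surf2, 0.5, 0.3)$estimate, 1)    # before first event time
  expect_error(value_at(surf, 3, 0.5), "time span")
  expect_error(value_at(surf, 1, 2), "covariate grid")
})

test_that("delta bands: zero variance collapses, S = 1 stays a point", {
  fit <- manual_weibull_fit(shape = 1.2, scale = 2, gamma = c(x = 0.3))
  grid <- structure(list(covariate_values = c(0, 0.5, 1), time_grid = c(0, 1, 2),
                         predictor_range = c(0, 1)), class = "grid_spec")
  surf <- compute_surface(fit, grid, profile = list(), ci_level = 0.95)
  expect_equal(surf$lower, surf$values)  # zero covariance -> bands collapse
  expect_equal(surf$upper, surf$values)
  expect_equal(surf$lower[, 1], c(1, 1, 1))  # S(0) = 1 -> band (1, 1)
})

test_that("bootstrap and delta bands agree in median width on simulated data", {
  ds <- gen_ph_weibull(sim_spec(n = 500, beta = 0.5, seed = 13,
                                censoring = list(type = "exponential", rate = 0.05)))
  fit <- fit_cox(ds)
  tq <- unname(quantile(ds$time[ds$event == 1], c(0.2, 0.4, 0.6, 0.8)))
  grid <- structure(list(covariate_values = quantile(ds$predictor, c(0.25, 0.5, 0.75),
                                                     names = FALSE),
                         time_grid = tq, predictor_range = range(ds$predictor)),
                    class = "grid_spec")
  surf_d <- compute_surface(fit, grid, ci_level = 0.95)
  surf_b <- surface_ci(fit, compute_surface(fit, grid, ci_level = 0.95),
                       method = "bootstrap", n_boot = 200, seed = 7)
  wd <- median(surf_d$upper - surf_d$lower)
  wb <- median(surf_b$upper - surf_b$lower)
  expect_lt(abs(wb / wd - 1), 0.30)
})

test_that("surface JSON serialization round-trips exactly", {
  ds <- gen_ph_weibull(sim_spec(n = 60, beta = 0.5, seed = 3))
  surf <- compute_surface(fit_cox(ds), build_grid(ds, n_points = 6))
  s2 <- surface_from_json(surface_to_json(surf))
  expect_identical(s2$values, surf$values)
  expect_identical(s2$lower, surf$lower)
  expect_identical(s2$upper, surf$upper)
  expect_identical(s2$time_grid, surf$time_grid)
  expect_identical(s2$covariate_values, surf$covariate_values)
  expect_identical(s2$outcome_type, surf$outcome_type)
})
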