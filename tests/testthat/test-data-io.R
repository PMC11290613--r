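test_that("CSV parsing honors roles and drops incomplete rows with a count", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,e,x", "1,1,0.5", "2,0,1.5", "3,1,2.5"), path)
  ds <- read_dataset(path, column_roles(time = "t", event = "e", predictor = "x"))
  expect_s3_class(ds, "survival_dataset")
  expect_equal(ds$n, 3)
  expect_equal(ds$time, c(1, 2, 3))
  expect_equal(ds$predictor, c(0.5, 1.5, 2.5))

  # missing predictor value: complete-case drop, logged count
  writeLines(c("t,e,x", "1,1,0.5", "2,0,", "3,1,2.5"), path)
  expect_message(
    ds2 <- read_dataset(path, column_roles(time = "t", event = "e", predictor = "x")),
    "dropped 1 row")
  expect_equal(ds2$n, 2)
  expect_equal(ds2$n_dropped, 1)
})

test_that("role errors name the offending column; bad values are located", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,e,x", "1,1,0.5"), path)
  expect_error(
    read_dataset(path, column_roles(time = "t", event = "e", predictor = "foo")),
    "foo")
  writeLines(c("t,e,x", "abc,1,0.5"), path)
  expect_error(
    read_dataset(path, column_roles(time = "t", event = "e", predictor = "x")),
    "non-numeric time.*row 1")
  writeLines(c("t,e,x", ",1,", ",0,"), path)
  expect_error(
    suppressMessages(
      read_dataset(path, column_roles(time = "t", event = "e", predictor = "x"))),
    "no usable rows")
  expect_error(column_roles(event = "e", predictor = "x"), "exactly one")
  expect_error(column_roles(time = "t", event = "e", predictor = "x",
                            adjusters = c("x", "z")), "must not also be an adjuster")
})

test_that("interval mode maps empty or 'Inf' right bounds to +infinity", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("l,r,e,x", "1,2,1,0.1", "3,,0,0.2", "2,Inf,0,0.3"), path)
  roles <- column_roles(interval_left = "l", interval_right = "r",
                        event = "e", predictor = "x")
  ds <- read_dataset(path, roles)
  expect_equal(ds$n, 3)
  expect_equal(ds$left, c(1, 3, 2))
  expect_equal(ds$right, c(2, Inf, Inf))
  expect_equal(ds$mode, "interval")
})

test_that("validate_dataset reports violations with row indices, not errors", {
  ds <- make_ds(time = c(1, 2, 3, 4, -1), event = c(1, 0, 1, 1, 1),
                x = c(0.1, 0.4, 0.2, 0.9, 0.5))
  rep <- validate_dataset(ds)
  expect_equal(rep$check, "negative_time")
  expect_true(5L %in% rep$rows[[1]])

  df <- data.frame(l = c(1, 2), r = c(2, 1), e = c(1, 1), x = c(0.3, 0.7))
  dsi <- as_survival_dataset(df, column_roles(interval_left = "l", interval_right = "r",
                                              event = "e", predictor = "x"))
  expect_true("interval_order" %in% validate_dataset(dsi)$check)

  ok <- make_ds(time = 1:4, event = c(1, 0, 1, 1), x = c(0.1, 0.2, 0.3, 0.4))
  expect_equal(nrow(validate_dataset(ok)), 0)

  const <- make_ds(time = 1:3, event = c(1, 1, 0), x = rep(2, 3))
  expect_true("degenerate_predictor" %in% validate_dataset(const)$check)
})

test_that("competing-risks flag follows the 0/1/>=2 event coding", {
  ds <- make_ds(time = 1:4, event = c(1, 0, 2, 1), x = c(0.1, 0.2, 0.3, 0.4))
  expect_true(ds$competing_risks)
  expect_false(make_ds(time = 1:3, event = c(1, 0, 1), x = 1:3)$competing_risks)
})

test_that("covariate summaries: bins, median, mode, degenerate input", {
  ds <- make_ds(time = 1:3, event = rep(1L, 3), x = c(1, 2, 3))
  s <- summarize_covariate(ds, "x", n_bins = 2)
  expect_equal(s$histogram$count, c(1, 2))  # [1,2): {1}; [2,3]: {2,3}
  expect_equal(s$histogram$bin_left, c(1, 2))
  expect_equal(s$median, 2)

  dsc <- make_ds(time = 1:3, event = rep(1L, 3), x = c(5, 5, 5) + c(0, 0, 1e-9))
  # truly constant column: summary must degrade to a single bin
  dsc$data$x <- c(5, 5, 5)
  sc <- summarize_covariate(dsc, "x", n_bins = 4)
  expect_equal(nrow(sc$histogram), 1)
  expect_equal(sc$histogram$count, 3)
  expect_equal(sc$median, 5)

  dsa <- make_ds(time = 1:3, event = rep(1L, 3), x = c(1, 2, 3), g = c("a", "a", "b"))
  sa <- summarize_covariate(dsa, "g")
  expect_equal(sa$mode, "a")
  # frequency tie broken by sorted level order
  dsb <- make_ds(time = 1:4, event = rep(1L, 4), x = 1:4, g = c("b", "a", "b", "a"))
  expect_equal(summarize_covariate(dsb, "g")$mode, "a")
})

test_that("histogram counts sum to the non-missing count for any n_bins", {
  set.seed(11)
  ds <- make_ds(time = rexp(40) + 0.1, event = rbinom(40, 1, 0.6), x = rnorm(40))
  for (nb in c(1, 2, 5, 13)) {
    s <- summarize_covariate(ds, "x", n_bins = nb)
    expect_equal(sum(s$histogram$count), 40 - s$n_missing)
  }
})

test_that("write/read round-trip reproduces every dataset field", {
  set.seed(3)
  df <- data.frame(time = round(rexp(25), 3) + 0.05, event = rbinom(25, 1, 0.7),
                   x = round(rnorm(25), 4), z = round(rnorm(25), 4),
                   g = sample(c("u", "v"), 25, TRUE))
  ds <- as_survival_dataset(df, simple_roles(adjusters = c("z", "g")))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, path)
  ds2 <- read_dataset(path, ds$roles)
  expect_equal(ds2$time, ds$time)
  expect_equal(ds2$event, ds$event)
  expect_equal(ds2$predictor, ds$predictor)
  expect_equal(ds2$adjusters, ds$adjusters, ignore_attr = TRUE)
  expect_equal(ds2$adjuster_types, ds$adjuster_types)

  # interval mode incl. the Inf sentinel
  dsi <- gen_interval(sim_spec(n = 30, beta = 0.4, seed = 8,
                               interval = list(spacing = 1, n_visits = 6)))
  write_dataset(dsi, path)
  dsi2 <- read_dataset(path, dsi$roles)
  expect_equal(dsi2$left, dsi$left)
  expect_equal(dsi2$right, dsi$right)
})
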