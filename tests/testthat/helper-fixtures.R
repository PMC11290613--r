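# Shared fixtures: all test data is built in code.

simple_roles <- function(adjusters = character(0), stratum = NULL) {
  column_roles(time = "time", event = "event", predictor = "x",
               adjusters = adjusters, stratum = stratum)
}

make_ds <- function(time, event, x, ...) {
  extra <- list(...)
  df <- data.frame(time = time, event = event, x = x)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  as_survival_dataset(df, simple_roles(adjusters = names(extra)))
}

# Six subjects with a perfectly balanced binary covariate at every event
# time: the partial-likelihood score at beta = 0 vanishes by symmetry, so
# the fit sits exactly at beta-hat = 0 and the Breslow baseline reduces to
# Nelson-Aalen with increments 2/6, 2/4, 2/2 = 1/3, 1/2, 1.
symmetric_ds <- function() {
  make_ds(time = c(1, 1, 2, 2, 3, 3), event = rep(1L, 6), x = rep(c(0, 1), 3))
}

# Hand-built Weibull fit (k, lambda, single AFT coefficient on x) with a
# given covariance, for closed-form prediction checks.
manual_weibull_fit <- function(shape, scale, gamma, covariance = NULL) {
  p <- length(gamma)
  if (is.null(covariance)) covariance <- matrix(0, p + 2, p + 2)
  design <- structure(list(x = NULL, column_names = names(gamma),
                           center = setNames(numeric(p), names(gamma)),
                           predictor_name = names(gamma)[1],
                           adjuster_meta = list()),
                      class = "design_matrix")
  structure(list(shape = shape, scale = scale, gamma = gamma,
                 log_shape = log(shape), log_scale = log(scale),
                 covariance = covariance, loglik = NA_real_,
                 censoring_mode = "right", column_names = names(gamma),
                 center = design$center, design = design, dataset = NULL),
            class = "weibull_fit")
}

# Hand-built surface for value_at / rendering checks.
manual_surface <- function(values, time_grid, covariate_values,
                           outcome_type = "survival", lower = NULL, upper = NULL) {
  structure(list(time_grid = time_grid, covariate_values = covariate_values,
                 values = values, lower = lower, upper = upper,
                 outcome_type = outcome_type, ci_level = 0.95,
                 profile = structure(list(values = list(), source = character(0)),
                                     class = "covariate_profile"),
                 model_tag = "manual", predictor_name = "x", stratum = NULL),
            class = "survival_surface")
}

# Extract the JSON payload embedded in an interactive HTML export.
read_html_payload <- function(path) {
  lines <- readLines(path, warn = FALSE)
  open <- grep("application/json", lines)[1]
  close <- open + which(grepl("</script>", lines[(open + 1):length(lines)]))[1]
  jsonlite::fromJSON(paste(lines[(open + 1):(close - 1)], collapse = "\n"))
}
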