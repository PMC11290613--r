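#' Designate column roles for a survival table
#'
#' Maps columns of a rectangular table onto the roles the models need:
#' the follow-up time (or the two interval bounds for interval-censored
#' data), the event indicator, the continuous predictor displayed on the
#' contour axis, optional adjuster covariates, and an optional stratum.
#'
#' Event coding convention: 0 = censored, 1 = event of interest,
#' integers >= 2 = competing causes.
#'
#' @param time name of the time column (right-censored mode); mutually
#'   exclusive with `interval_left`/`interval_right`
#' @param event name of the event/censoring indicator column
#' @param predictor name of the continuous covariate of interest
#' @param adjusters character vector of adjuster column names (may be empty)
#' @param stratum optional stratum column name
#' @param interval_left,interval_right interval-censored mode: columns with
#'   the interval bounds. An empty cell or the token `"Inf"` in
#'   `interval_right` means right-censored at the left bound.
#' @return a `column_roles` object
#' @examples
#' column_roles(time = "t", event = "e", predictor = "x", adjusters = "age")
#' @export
column_roles <- function(time = NULL, event, predictor, adjusters = character(),
                         stratum = NULL, interval_left = NULL, interval_right = NULL) {
  interval_mode <- !is.null(interval_left) || !is.null(interval_right)
  if (interval_mode && (is.null(interval_left) || is.null(interval_right)))
    stop("column_roles: interval mode needs both interval_left and interval_right", call. = FALSE)
  if (is.null(time) == !interval_mode)
    stop("column_roles: set exactly one of `time` or the interval_left/interval_right pair",
         call. = FALSE)
  adjusters <- as.character(adjusters)
  if (predictor %in% adjusters)
    stop("column_roles: predictor '", predictor, "' must not also be an adjuster", call. = FALSE)
  structure(list(time = time, interval_left = interval_left,
                 interval_right = interval_right, event = event,
                 predictor = predictor, adjusters = adjusters, stratum = stratum,
                 mode = if (interval_mode) "interval" else "right"),
            class = "column_roles")
}

role_columns <- function(roles) {
  c(roles$time, roles$interval_left, roles$interval_right, roles$event,
    roles$predictor, roles$adjusters, roles$stratum)
}

#' Build a survival dataset from a data frame
#'
#' Validates and packages subject-level data into the container used by all
#' fitting, surface, and histogram code. Rows with missing values in any role
#' column are dropped (complete-case on role columns only) and the dropped
#' count is reported via a message.
#'
#' Adjusters are auto-detected as categorical when non-numeric or when they
#' take at most `max_levels` distinct values; override per column through
#' `adjuster_types`.
#'
#' @param df a data frame with the role columns
#' @param roles a [column_roles()] object
#' @param max_levels distinct-value threshold below which a numeric adjuster
#'   is treated as categorical (default 10)
#' @param adjuster_types optional named character vector
#'   (`"continuous"`/`"categorical"`) overriding auto-detection
#' @return a `survival_dataset`
#' @export
as_survival_dataset <- function(df, roles, max_levels = 10, adjuster_types = NULL) {
  stopifnot(inherits(roles, "column_roles"))
  df <- as.data.frame(df)
  missing_cols <- setdiff(role_columns(roles), names(df))
  if (length(missing_cols) > 0)
    stop("role column(s) not found in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)

  interval_mode <- roles$mode == "interval"
  if (interval_mode) {
    # right-censoring sentinel: empty cell or "Inf" -> +infinity
    r <- df[[roles$interval_right]]
    if (is.character(r)) {
      r[!is.na(r) & trimws(r) == ""] <- "Inf"
      rn <- suppressWarnings(as.numeric(r))
      bad <- which(!is.na(r) & is.na(rn) & !trimws(r) %in% c("", "NA"))
      if (length(bad) > 0)
        stop("non-numeric interval_right value at row ", bad[1], call. = FALSE)
      r <- rn
    }
    df[[roles$interval_right]] <- r
    check_numeric_col(df, roles$interval_left, "interval_left")
  } else {
    check_numeric_col(df, roles$time, "time")
  }
  check_numeric_col(df, roles$event, "event")
  check_numeric_col(df, roles$predictor, "predictor")

  keep <- complete.cases(df[, role_columns(roles), drop = FALSE])
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message("dropped ", n_dropped, " row(s) with missing values in role columns")
  df <- df[keep, role_columns(roles), drop = FALSE]
  if (nrow(df) == 0)
    stop("no usable rows after removing missing values", call. = FALSE)

  event <- as.integer(df[[roles$event]])
  adjusters <- df[, roles$adjusters, drop = FALSE]
  types <- detect_adjuster_types(adjusters, max_levels, adjuster_types)

  ds <- structure(list(
    n = nrow(df),
    mode = roles$mode,
    time = if (!interval_mode) as.numeric(df[[roles$time]]) else NULL,
    left = if (interval_mode) as.numeric(df[[roles$interval_left]]) else NULL,
    right = if (interval_mode) as.numeric(df[[roles$interval_right]]) else NULL,
    event = event,
    predictor = as.numeric(df[[roles$predictor]]),
    predictor_name = roles$predictor,
    adjusters = adjusters,
    adjuster_types = types,
    strata = if (!is.null(roles$stratum)) factor(df[[roles$stratum]]) else NULL,
    stratum_name = roles$stratum,
    competing_risks = any(event >= 2L),
    roles = roles,
    n_dropped = n_dropped,
    data = df
  ), class = "survival_dataset")
  ds
}

check_numeric_col <- function(df, col, label) {
  v <- df[[col]]
  if (is.numeric(v)) return(invisible(TRUE))
  vn <- suppressWarnings(as.numeric(as.character(v)))
  bad <- which(!is.na(v) & is.na(vn))
  if (length(bad) > 0)
    stop("non-numeric ", label, " value in column '", col, "' at row ", bad[1], call. = FALSE)
  invisible(TRUE)
}

detect_adjuster_types <- function(adjusters, max_levels, override) {
  types <- vapply(names(adjusters), function(nm) {
    v <- adjusters[[nm]]
    if (!is.numeric(v)) "categorical"
    else if (length(unique(v)) <= max_levels) "categorical"
    else "continuous"
  }, character(1))
  if (!is.null(override)) {
    bad <- setdiff(names(override), names(adjusters))
    if (length(bad) > 0)
      stop("adjuster_types names not among adjusters: ", paste(bad, collapse = ", "),
           call. = FALSE)
    types[names(override)] <- override
  }
  types
}

#' Read a survival dataset from a delimited text file
#'
#' Reads a CSV/TSV file with a header row, applies [column_roles()] and
#' returns a validated [`survival_dataset`][as_survival_dataset]. The
#' delimiter is taken from the file extension (`.tsv`/`.txt` = tab,
#' otherwise comma) unless given explicitly.
#'
#' @inheritParams as_survival_dataset
#' @param path file path
#' @param delim field delimiter; `NULL` = auto-detect from extension
#' @return a `survival_dataset`
#' @export
read_dataset <- function(path, roles, delim = NULL, max_levels = 10,
                         adjuster_types = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    ext <- tolower(tools::file_ext(path))
    delim <- if (ext %in% c("tsv", "txt")) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  # preserve "" vs NA distinction only where the interval sentinel needs it
  if (roles$mode == "interval") {
    raw <- utils::read.table(path, header = TRUE, sep = delim, colClasses = "character",
                             stringsAsFactors = FALSE)
    if (roles$interval_right %in% names(raw)) df[[roles$interval_right]] <- raw[[roles$interval_right]]
  }
  as_survival_dataset(df, roles, max_levels = max_levels, adjuster_types = adjuster_types)
}

#' Write a survival dataset back to CSV
#'
#' Writes the role columns of a dataset to a delimited file such that
#' [read_dataset()] with the same roles reproduces the dataset (the
#' round-trip identity). Infinite interval bounds are written as `Inf`.
#'
#' @param ds a `survival_dataset`
#' @param path output file path
#' @param delim field delimiter (default comma)
#' @return `path`, invisibly
#' @export
write_dataset <- function(ds, path, delim = ",") {
  utils::write.table(ds$data, path, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a survival dataset
#'
#' Checks every container invariant and returns the violations as data, not
#' exceptions: an empty report means the dataset is valid.
#'
#' @param ds a `survival_dataset`
#' @return a tibble with columns `check`, `rows` (list-column of offending row
#'   indices) and `message`; zero rows when all invariants hold
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "survival_dataset"))
  v <- list()
  add <- function(check, rows, msg) {
    v[[length(v) + 1L]] <<- tibble::tibble(check = check, rows = list(as.integer(rows)),
                                           message = msg)
  }
  if (ds$mode == "right") {
    bad <- which(!is.finite(ds$time) | ds$time < 0)
    if (length(bad) > 0)
      add("negative_time", bad, paste0("time must be finite and >= 0 (rows ",
                                       paste(head(bad, 5), collapse = ", "), ")"))
  } else {
    bad <- which(!is.finite(ds$left) | ds$left < 0)
    if (length(bad) > 0)
      add("negative_time", bad, "interval left bound must be finite and >= 0")
    bad <- which(ds$left > ds$right)
    if (length(bad) > 0)
      add("interval_order", bad, paste0("interval left bound exceeds right bound (rows ",
                                        paste(head(bad, 5), collapse = ", "), ")"))
  }
  bad <- which(ds$event < 0 | ds$event != floor(ds$event))
  if (length(bad) > 0)
    add("event_code", bad, "event codes must be non-negative integers")
  finite_pred <- ds$predictor[is.finite(ds$predictor)]
  if (length(unique(finite_pred)) < 2)
    add("degenerate_predictor", integer(0),
        "predictor needs >= 2 distinct finite values for a contour axis")
  if (length(v) == 0)
    tibble::tibble(check = character(0), rows = list(), message = character(0))
  else do.call(rbind, v)
}

#' Summarize a covariate for profiling and the marginal histogram
#'
#' Computes the median (continuous) or most frequent level (categorical),
#' an equal-width histogram over the observed range, and the missing count.
#' Bins are half-open `[left, right)` except the last, which is closed, so
#' counts always sum to the number of non-missing values.
#'
#' @param ds a `survival_dataset`
#' @param column a role column name (defaults to the predictor)
#' @param n_bins number of histogram bins (>= 1)
#' @return a `covariate_summary`: list with `column`, `median`, `mode`,
#'   `histogram` (tibble `bin_left`, `bin_right`, `count`), `n_missing`
#' @export
summarize_covariate <- function(ds, column = ds$predictor_name, n_bins = 20) {
  stopifnot(inherits(ds, "survival_dataset"), n_bins >= 1)
  if (!column %in% names(ds$data))
    stop("column '", column, "' is not a role column of this dataset", call. = FALSE)
  v <- ds$data[[column]]
  n_missing <- sum(is.na(v))
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("all values missing in column '", column, "'", call. = FALSE)

  if (is.numeric(v)) {
    med <- stats::median(v)
    rng <- range(v)
    if (rng[1] == rng[2]) {
      hist <- tibble::tibble(bin_left = rng[1], bin_right = rng[2], count = length(v))
    } else {
      breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
      idx <- pmin(findInterval(v, breaks), n_bins)  # last bin closed
      cnt <- tabulate(idx, nbins = n_bins)
      hist <- tibble::tibble(bin_left = breaks[-length(breaks)],
                             bin_right = breaks[-1], count = cnt)
    }
    mode_val <- NULL
  } else {
    tab <- table(v)
    lv <- sort(names(tab))
    mode_val <- lv[which.max(tab[lv])]  # ties broken by sorted level order
    med <- NA_real_
    hist <- tibble::tibble(bin_left = NA_real_, bin_right = NA_real_,
                           count = as.integer(tab[lv]))
    hist$level <- lv
  }
  structure(list(column = column, median = med, mode = mode_val,
                 histogram = hist, n_missing = n_missing, n = length(v)),
            class = "covariate_summary")
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat("<survival_dataset> n =", x$n, "| mode:", x$mode,
      if (x$competing_risks) "| competing risks" else "", "\n")
  cat("  predictor:", x$predictor_name)
  if (length(x$adjuster_types) > 0)
    cat(" | adjusters:", paste(names(x$adjuster_types), paste0("(", x$adjuster_types, ")"),
                               collapse = ", "))
  if (!is.null(x$stratum_name)) cat(" | stratum:", x$stratum_name)
  cat("\n  events:", sum(x$event == 1L), "of interest,",
      sum(x$event >= 2L), "competing,", sum(x$event == 0L), "censored\n")
  invisible(x)
}
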