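#' Build the model design matrix from a survival dataset
#'
#' Columns are ordered deterministically: the continuous predictor first,
#' then adjusters in role order; categorical adjusters are expanded to
#' one-hot indicator columns in sorted level order with the first (sorted)
#' level as the dropped reference. Per-column means are stored so fitting
#' can run on a numerically centered copy.
#'
#' @param ds a `survival_dataset`
#' @return a `design_matrix`: list with `x` (n x p numeric matrix),
#'   `column_names`, `center` (column means), and the adjuster metadata
#'   needed to assemble prediction rows from a covariate profile
#' @export
build_design <- function(ds) {
  stopifnot(inherits(ds, "survival_dataset"))
  cols <- list()
  cols[[ds$predictor_name]] <- ds$predictor
  meta <- list()
  for (nm in names(ds$adjuster_types)) {
    v <- ds$adjusters[[nm]]
    if (ds$adjuster_types[[nm]] == "continuous") {
      cols[[nm]] <- as.numeric(v)
      meta[[nm]] <- list(type = "continuous")
    } else {
      lev <- sort(unique(as.character(v)))
      meta[[nm]] <- list(type = "categorical", levels = lev)
      for (l in lev[-1]) cols[[paste0(nm, l)]] <- as.numeric(as.character(v) == l)
    }
  }
  x <- do.call(cbind, cols)
  colnames(x) <- names(cols)
  const <- apply(x, 2, function(col) length(unique(col)) < 2)
  if (any(const))
    stop("degenerate design: constant column(s) ", paste(names(cols)[const], collapse = ", "),
         call. = FALSE)
  structure(list(x = x, column_names = colnames(x), center = colMeans(x),
                 predictor_name = ds$predictor_name, adjuster_meta = meta),
            class = "design_matrix")
}

#' Assemble a single covariate row for prediction
#'
#' Combines a predictor value with a [covariate profile][default_profile]
#' into a numeric row matching the design-matrix column layout (categorical
#' profile levels are one-hot expanded).
#'
#' @param design a `design_matrix`
#' @param predictor_value value for the continuous predictor
#' @param profile a `covariate_profile` (or named list of adjuster values);
#'   may be `NULL` when the design has no adjusters
#' @return named numeric vector of length `ncol(design$x)`
#' @export
design_row <- function(design, predictor_value, profile = NULL) {
  vals <- if (inherits(profile, "covariate_profile")) profile$values else profile
  row <- setNames(numeric(length(design$column_names)), design$column_names)
  row[design$predictor_name] <- predictor_value
  for (nm in names(design$adjuster_meta)) {
    m <- design$adjuster_meta[[nm]]
    if (is.null(vals) || is.null(vals[[nm]]))
      stop("covariate profile is missing adjuster '", nm, "'", call. = FALSE)
    if (m$type == "continuous") {
      row[nm] <- as.numeric(vals[[nm]])
    } else {
      l <- as.character(vals[[nm]])
      if (!l %in% m$levels)
        stop("profile level '", l, "' not among levels of adjuster '", nm, "'", call. = FALSE)
      for (ll in m$levels[-1]) row[paste0(nm, ll)] <- as.numeric(l == ll)
    }
  }
  row
}
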