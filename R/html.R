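# Self-contained interactive HTML export. The figure's data (surface grid,
# values, bands, histogram, palette) is embedded as a JSON payload in a
# <script type="application/json"> block and rendered client-side on a
# canvas by embedded JavaScript: no external scripts, stylesheets or fonts,
# so the file works offline and can be archived with a manuscript.
#
# The 2D view reports value_at() lookups on hover (step in time, linear in
# the covariate, probability as a percentage with one decimal); the 3D view
# supports drag rotation, with confidence bands as semitransparent layers.

html_payload <- function(figure) {
  surface <- figure$surface
  pal <- surface_palette(surface$outcome_type, 256, figure$options$palette)
  payload <- list(
    kind = figure$kind,
    times = surface$time_grid,
    covariate = surface$covariate_values,
    values = surface$values,
    outcome_type = surface$outcome_type,
    ci_level = surface$ci_level,
    profile = if (length(surface$profile$values) > 0) surface$profile$values
              else stats::setNames(list(), character(0)),
    predictor_name = surface$predictor_name,
    model_tag = surface$model_tag,
    time_label = figure$options$time_label,
    covariate_label = figure$options$covariate_label,
    level_step = figure$options$level_step,
    band_opacity = figure$options$band_opacity,
    colors = pal,
    hist_fill = figure$options$hist_fill
  )
  if (!is.null(surface$lower)) {
    payload$lower <- surface$lower
    payload$upper <- surface$upper
  }
  if (!is.null(figure$summary)) {
    payload$histogram <- list(
      bin_left = figure$summary$histogram$bin_left,
      bin_right = figure$summary$histogram$bin_right,
      count = figure$summary$histogram$count
    )
  }
  jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE, null = "null")
}

write_interactive_html <- function(figure, path) {
  payload <- html_payload(figure)
  title <- if (figure$kind == "contour2d") "Survival contour" else "Survival surface (3D)"
  html <- paste0(
    "<!DOCTYPE html>\n<html>\n<head>\n<meta charset=\"utf-8\">\n",
    "<title>", title, "</title>\n",
    "<style>\n", html_css(), "\n</style>\n</head>\n<body>\n",
    "<div id=\"wrap\"><canvas id=\"plot\" width=\"960\" height=\"640\"></canvas>",
    "<div id=\"tip\"></div></div>\n",
    "<script id=\"survsurf-data\" type=\"application/json\">\n", payload,
    "\n</script>\n",
    "<script>\n", html_js(), "\n</script>\n</body>\n</html>\n"
  )
  writeLines(html, path, useBytes = TRUE)
  invisible(path)
}

html_css <- function() {
  paste(
    "body { font-family: sans-serif; margin: 12px; }",
    "#wrap { position: relative; display: inline-block; }",
    "#tip { position: absolute; display: none; pointer-events: none;",
    "  background: rgba(0,0,0,0.75); color: #fff; padding: 4px 7px;",
    "  border-radius: 4px; font-size: 12px; white-space: pre; }",
    sep = "\n")
}

# The renderer. Shared helpers + a 2D contour/histogram branch and a 3D
# rotating-surface branch, selected by payload.kind.
html_js <- function() {
  paste(readLines(system.file("js", "renderer.js", package = "survsurf"),
                  warn = FALSE), collapse = "\n")
}
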