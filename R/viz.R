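# Rendering of survival surfaces: 2D filled contour with a marginal
# covariate histogram, and a 3D surface with confidence bands as
# semitransparent layers. Static output goes through ggplot2 / base
# graphics; interactive output is a self-contained HTML document (see
# html.R).

# Color contract: darker always means worse outcome. The palette maps the
# plotted probability p in [0,1] to a color; for survival, low p is dark;
# for cumulative incidence the scale is reversed so high incidence is dark.
surface_palette <- function(outcome_type, n = 256, name = "Viridis") {
  cols <- grDevices::hcl.colors(n, name)  # dark -> light
  if (outcome_type == "cumulative_incidence") rev(cols) else cols
}

default_viz_options <- function(options = list()) {
  utils::modifyList(list(
    level_step = 0.05,        # probability band width of the filled contour
    palette = "Viridis",
    hist_fill = "orange",
    time_label = "Time",
    covariate_label = NULL,   # default: predictor name
    band_opacity = 0.35,      # 3D CI layer opacity
    title = NULL
  ), options)
}

check_surface_summary <- function(surface, summary) {
  if (!is.null(summary)) {
    stopifnot(inherits(summary, "covariate_summary"))
    if (!is.null(surface$predictor_name) && summary$column != surface$predictor_name)
      stop("surface predictor '", surface$predictor_name,
           "' does not match summary column '", summary$column, "'", call. = FALSE)
    if (!is.numeric(summary$histogram$bin_left) || anyNA(summary$histogram$bin_left))
      stop("contour histogram needs a numeric covariate summary", call. = FALSE)
  }
}

# Cell boundaries for step-in-time rendering: column j of the surface holds
# the value on [t_j, t_{j+1}); the covariate axis uses midpoint boundaries.
surface_cells <- function(surface) {
  tg <- surface$time_grid; cv <- surface$covariate_values
  nt <- length(tg); nc <- length(cv)
  tb <- tg  # nt boundaries -> nt - 1 cells
  cb <- c(cv[1], (cv[-nc] + cv[-1]) / 2, cv[nc])
  cells <- expand.grid(j = seq_len(nt - 1L), i = seq_len(nc))
  data.frame(
    xmin = tb[cells$j], xmax = tb[cells$j + 1L],
    ymin = cb[cells$i], ymax = cb[cells$i + 1L],
    value = surface$values[cbind(cells$i, cells$j)]
  )
}

#' Render the 2D contour plot with a marginal histogram
#'
#' The signature figure: x = time, y = the continuous predictor, color = the
#' predicted probability in bands of `level_step` (default 0.05), with the
#' covariate histogram aligned on the shared y axis at the right. Darker
#' colors always mean worse predicted outcome. Export with
#' [export_figure()]; the interactive HTML export reports [value_at()]
#' estimates on hover (probability as a percentage with one decimal).
#'
#' @param surface a `survival_surface`
#' @param summary a [summarize_covariate()] result for the predictor
#' @param options list of rendering options: `level_step`, `palette`,
#'   `hist_fill` (default orange), `time_label`, `covariate_label`, `title`
#' @return a `figure_artifact` (kind `"contour2d"`)
#' @export
render_contour2d <- function(surface, summary, options = list()) {
  stopifnot(inherits(surface, "survival_surface"))
  check_surface_summary(surface, summary)
  opt <- default_viz_options(options)
  if (is.null(opt$covariate_label)) opt$covariate_label <- surface$predictor_name

  step <- opt$level_step
  breaks <- seq(0, 1, by = step)
  if (max(breaks) < 1) breaks <- c(breaks, 1)
  nlev <- length(breaks) - 1L
  pal <- surface_palette(surface$outcome_type, nlev, opt$palette)
  cells <- surface_cells(surface)
  cells$band <- cut(cells$value, breaks, include.lowest = TRUE, right = FALSE)
  lev <- levels(cells$band)

  prob_lab <- if (surface$outcome_type == "survival") "survival probability"
              else "cumulative incidence"
  p_main <- ggplot2::ggplot(cells) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = .data$ymin, ymax = .data$ymax,
                                    fill = .data$band)) +
    ggplot2::scale_fill_manual(values = setNames(pal, lev), drop = FALSE,
                               name = prob_lab) +
    ggplot2::labs(x = opt$time_label, y = opt$covariate_label, title = opt$title) +
    ggplot2::theme_minimal()

  h <- summary$histogram
  ylim <- range(c(surface$covariate_values, h$bin_left, h$bin_right))
  p_hist <- ggplot2::ggplot(h) +
    ggplot2::geom_rect(ggplot2::aes(ymin = .data$bin_left, ymax = .data$bin_right,
                                    xmin = 0, xmax = .data$count),
                       fill = opt$hist_fill, color = "white") +
    ggplot2::labs(x = "count", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  p_main <- p_main + ggplot2::coord_cartesian(ylim = ylim)
  p_hist <- p_hist + ggplot2::coord_cartesian(ylim = ylim)
  combined <- patchwork::wrap_plots(p_main, p_hist, widths = c(4, 1))

  structure(list(kind = "contour2d", plot = combined, surface = surface,
                 summary = summary, options = opt,
                 color_scale = list(name = opt$palette, darker_is_worse = TRUE),
                 n_layers = 1L),
            class = "figure_artifact")
}

#' Render the 3D survival surface
#'
#' z = predicted probability over (time, predictor). When the surface has
#' confidence bands, the lower and upper band surfaces are drawn as
#' semitransparent layers around the opaque estimate (3 layers total). The
#' interactive HTML export supports drag rotation; static export uses a
#' fixed perspective.
#'
#' @param surface a `survival_surface`
#' @param options rendering options: `band_opacity` (default 0.35),
#'   `palette`, `time_label`, `covariate_label`, `title`
#' @return a `figure_artifact` (kind `"surface3d"`)
#' @export
render_surface3d <- function(surface, options = list()) {
  stopifnot(inherits(surface, "survival_surface"))
  opt <- default_viz_options(options)
  if (is.null(opt$covariate_label)) opt$covariate_label <- surface$predictor_name
  has_bands <- !is.null(surface$lower)
  draw <- function() draw_surface3d_static(surface, opt)
  structure(list(kind = "surface3d", plot = NULL, draw = draw, surface = surface,
                 summary = NULL, options = opt,
                 color_scale = list(name = opt$palette, darker_is_worse = TRUE),
                 n_layers = if (has_bands) 3L else 1L,
                 layer_opacity = if (has_bands) c(opt$band_opacity, 1, opt$band_opacity) else 1),
            class = "figure_artifact")
}

draw_surface3d_static <- function(surface, opt) {
  tg <- surface$time_grid; cv <- surface$covariate_values
  z <- t(surface$values)  # persp wants x = rows
  pal <- surface_palette(surface$outcome_type, 64, opt$palette)
  zf <- (z[-1, -1] + z[-nrow(z), -1] + z[-1, -ncol(z)] + z[-nrow(z), -ncol(z)]) / 4
  facet_col <- pal[pmax(1L, pmin(64L, 1L + floor(zf * 63.999)))]
  pm <- graphics::persp(tg, cv, z, zlim = c(0, 1), col = facet_col, border = NA,
                        theta = 35, phi = 25, expand = 0.7,
                        xlab = opt$time_label, ylab = opt$covariate_label,
                        zlab = if (surface$outcome_type == "survival") "S(t|x)" else "F1(t|x)",
                        ticktype = "detailed", main = opt$title)
  if (!is.null(surface$lower)) {
    for (m in list(surface$lower, surface$upper)) {
      col <- grDevices::adjustcolor("grey40", alpha.f = opt$band_opacity)
      for (i in seq_len(length(cv) - 1L)) for (j in seq_len(length(tg) - 1L)) {
        quad <- grDevices::trans3d(c(tg[j], tg[j + 1], tg[j + 1], tg[j]),
                                   c(cv[i], cv[i], cv[i + 1], cv[i + 1]),
                                   c(m[i, j], m[i, j + 1], m[i + 1, j + 1], m[i + 1, j]),
                                   pm)
        graphics::polygon(quad, col = col, border = NA)
      }
    }
  }
  invisible(pm)
}

#' Export a rendered figure
#'
#' Writes a `figure_artifact` to disk. HTML exports are interactive and
#' self-contained (all data and code embedded, no network access); PNG and
#' SVG are static. The format must match the file extension.
#'
#' @param figure a `figure_artifact`
#' @param path output path
#' @param format `"html"`, `"png"` or `"svg"`; default from the extension
#' @param dpi resolution for PNG output (default 150)
#' @param width,height device size in inches
#' @return `path`, invisibly
#' @export
export_figure <- function(figure, path, format = NULL, dpi = 150,
                          width = 9, height = 6) {
  stopifnot(inherits(figure, "figure_artifact"))
  ext <- tolower(tools::file_ext(path))
  if (is.null(format)) format <- ext
  format <- tolower(format)
  if (!format %in% c("html", "png", "svg"))
    stop("unsupported format '", format, "' (use html, png or svg)", call. = FALSE)
  if (nzchar(ext) && ext != format)
    stop("format '", format, "' does not match file extension '.", ext, "'",
         call. = FALSE)
  if (format == "html") {
    write_interactive_html(figure, path)
  } else {
    if (format == "png")
      grDevices::png(path, width = width * dpi, height = height * dpi, res = dpi)
    else grDevices::svg(path, width = width, height = height)
    on.exit(grDevices::dev.off(), add = TRUE)
    if (figure$kind == "contour2d") print(figure$plot) else figure$draw()
  }
  invisible(path)
}

#' @export
print.figure_artifact <- function(x, ...) {
  cat("<figure_artifact>", x$kind, "|", x$n_layers, "layer(s) | palette:",
      x$color_scale$name, "\n")
  invisible(x)
}
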