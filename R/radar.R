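#' Equally spaced axis tick labels
#'
#' Builds the ring labels for a radar chart: `segments + 1` equally spaced
#' values from `lo` to `hi`, rounded to 2 decimals. This reproduces the
#' usual manual-axis construction `round(seq(min, max, by = (max - min) /
#' segments), 2)` used to label per-site IBRv2 charts.
#'
#' @param lo,hi Axis range (`lo <= hi`).
#' @param segments Number of concentric rings (>= 1).
#' @return Numeric vector of `segments + 1` tick values.
#' @examples
#' axis_ticks(0, 8, 4)        # 0 2 4 6 8
#' axis_ticks(-1.5, 2.5, 4)   # -1.5 -0.5 0.5 1.5 2.5
#' @export
axis_ticks <- function(lo, hi, segments = 4) {
  if (!is.finite(lo) || !is.finite(hi) || lo > hi) {
    stop("need finite `lo` <= `hi`", call. = FALSE)
  }
  if (segments < 1L || segments != as.integer(segments)) {
    stop("`segments` must be a positive integer", call. = FALSE)
  }
  round(seq(lo, hi, length.out = segments + 1L), 2)
}

# ---- internal chart geometry -------------------------------------------

# default qualitative palette (colorblind-safe Okabe-Ito subset)
.radar_palette <- c("#E69F00", "#56B4E9", "#009E73", "#D55E00",
                    "#CC79A7", "#0072B2", "#F0E442", "#999999")

# axis angles: first biomarker at 12 o'clock, proceeding clockwise
radar_angles <- function(k) pi / 2 - 2 * pi * (seq_len(k) - 1L) / k

# map scores on [lo, hi] to unit radii; degenerate lo == hi maps to 0
radar_radii <- function(values, lo, hi) {
  if (hi > lo) pmin(pmax((values - lo) / (hi - lo), 0), 1)
  else rep(0, length(values))
}

# a chart spec: labels, series (list of list(name, values, color, dashed,
# points)), lo < hi, segments, ticks
make_chart_spec <- function(labels, series, lo, hi, segments, ticks = NULL) {
  if (lo >= hi) stop("axis range must satisfy lo < hi", call. = FALSE)
  if (segments < 1L) stop("`segments` must be >= 1", call. = FALSE)
  for (s in series) {
    if (length(s$values) != length(labels)) {
      stop("series '", s$name, "' length differs from axis count", call. = FALSE)
    }
  }
  if (is.null(ticks)) ticks <- axis_ticks(lo, hi, segments)
  list(labels = labels, series = series, lo = lo, hi = hi,
       segments = as.integer(segments), ticks = ticks)
}

num2 <- function(x) sprintf("%.2f", x)

# ---- SVG renderer -------------------------------------------------------

# Writes the radar chart as plain SVG markup. Output is a pure function of
# the chart-spec object (fixed canvas, fonts and number formatting; no
# timestamps), so
# identical inputs give byte-identical files, and the structure is
# parseable: site polygons carry class "series", the dashed reference
# polygon class "baseline", axis labels class "axis-label" and ring labels
# class "tick-label".
radar_svg <- function(spec, path, width = 480, height = 480) {
  cx <- width / 2
  cy <- height / 2
  r_max <- min(width, height) / 2 - 60
  k <- length(spec$labels)
  ang <- radar_angles(k)
  pt <- function(radii) {
    paste(num2(cx + r_max * radii * cos(ang)),
          num2(cy - r_max * radii * sin(ang)), sep = ",", collapse = " ")
  }
  ln <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
    width, height, width, height),
    '<rect width="100%" height="100%" fill="white"/>',
    sprintf('<g font-family="sans-serif" font-size="12" fill="black">'))
  # concentric rings
  for (i in seq_len(spec$segments)) {
    f <- i / spec$segments
    ln <- c(ln, sprintf(
      '<polygon class="ring" points="%s" fill="none" stroke="#CCCCCC" stroke-width="0.8"/>',
      pt(rep(f, k))))
  }
  # radial axes
  for (i in seq_len(k)) {
    ln <- c(ln, sprintf(
      '<line class="axis" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#CCCCCC" stroke-width="0.8"/>',
      num2(cx), num2(cy),
      num2(cx + r_max * cos(ang[i])), num2(cy - r_max * sin(ang[i]))))
  }
  # axis (biomarker) labels, pushed slightly beyond the outer ring
  for (i in seq_len(k)) {
    ln <- c(ln, sprintf(
      '<text class="axis-label" x="%s" y="%s" text-anchor="middle">%s</text>',
      num2(cx + (r_max + 18) * cos(ang[i])),
      num2(cy - (r_max + 18) * sin(ang[i]) + 4),
      xml_escape(spec$labels[i])))
  }
  # ring tick labels along the first (12 o'clock) axis
  for (i in seq_along(spec$ticks)) {
    f <- (i - 1L) / spec$segments
    ln <- c(ln, sprintf(
      '<text class="tick-label" x="%s" y="%s" font-size="9" fill="#555555">%s</text>',
      num2(cx + 4), num2(cy - r_max * f - 2), num2(spec$ticks[i])))
  }
  # series polygons (closed by the polygon element itself)
  for (s in spec$series) {
    radii <- radar_radii(s$values, spec$lo, spec$hi)
    cls <- if (isTRUE(s$dashed)) "baseline" else "series"
    dash <- if (isTRUE(s$dashed)) ' stroke-dasharray="6,4"' else ""
    ln <- c(ln, sprintf(
      '<polygon class="%s" points="%s" fill="none" stroke="%s" stroke-width="2"%s/>',
      cls, pt(radii), s$color, dash))
    if (isTRUE(s$points)) {
      for (i in seq_len(k)) {
        ln <- c(ln, sprintf(
          '<circle class="marker" cx="%s" cy="%s" r="3" fill="%s"/>',
          num2(cx + r_max * radii[i] * cos(ang[i])),
          num2(cy - r_max * radii[i] * sin(ang[i])), s$color))
      }
    }
  }
  # legend, top-left
  for (i in seq_along(spec$series)) {
    s <- spec$series[[i]]
    y <- 16 + 16 * (i - 1L)
    ln <- c(ln, sprintf(
      '<line x1="8" y1="%s" x2="28" y2="%s" stroke="%s" stroke-width="2"%s/>',
      num2(y), num2(y), s$color,
      if (isTRUE(s$dashed)) ' stroke-dasharray="6,4"' else ""),
      sprintf('<text class="legend-label" x="34" y="%s">%s</text>',
              num2(y + 4), xml_escape(s$name)))
  }
  ln <- c(ln, "</g>", "</svg>")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(ln, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# ---- base-graphics renderer (PNG / PDF) ---------------------------------

radar_draw <- function(spec) {
  k <- length(spec$labels)
  ang <- radar_angles(k)
  op <- graphics::par(mar = c(1, 1, 1, 1), xpd = NA)
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(xlim = c(-1.45, 1.45), ylim = c(-1.45, 1.45),
                        asp = 1)
  for (i in seq_len(spec$segments)) {
    f <- i / spec$segments
    graphics::polygon(f * cos(ang), f * sin(ang), border = "grey70")
  }
  graphics::segments(0, 0, cos(ang), sin(ang), col = "grey70")
  graphics::text(1.18 * cos(ang), 1.18 * sin(ang), spec$labels, cex = 0.9)
  graphics::text(rep(0.04, spec$segments + 1L),
                 seq(0, 1, length.out = spec$segments + 1L),
                 num2(spec$ticks), cex = 0.6, adj = 0, col = "grey40")
  for (s in spec$series) {
    r <- radar_radii(s$values, spec$lo, spec$hi)
    graphics::polygon(r * cos(ang), r * sin(ang), border = s$color,
                      lwd = 2, lty = if (isTRUE(s$dashed)) 2 else 1)
    if (isTRUE(s$points)) {
      graphics::points(r * cos(ang), r * sin(ang), pch = 16, col = s$color)
    }
  }
  graphics::legend("topleft", bty = "n", lwd = 2, cex = 0.8,
                   legend = vapply(spec$series, `[[`, "", "name"),
                   col = vapply(spec$series, `[[`, "", "color"),
                   lty = vapply(spec$series,
                                function(s) if (isTRUE(s$dashed)) 2L else 1L,
                                0L))
}

chart_format <- function(file, format = NULL) {
  if (!is.null(format)) format <- tolower(format)
  else format <- tolower(tools::file_ext(file))
  if (!format %in% c("svg", "png", "pdf")) {
    stop("unsupported chart format '", format,
         "' (use svg, png or pdf)", call. = FALSE)
  }
  format
}

render_chart <- function(spec, file, format = NULL, width = 480, height = 480) {
  fmt <- chart_format(file, format)
  if (fmt == "svg") {
    radar_svg(spec, file, width = width, height = height)
  } else {
    if (fmt == "png") grDevices::png(file, width = width, height = height)
    else grDevices::pdf(file, width = width / 96, height = height / 96)
    on.exit(grDevices::dev.off())
    radar_draw(spec)
  }
  invisible(file)
}

# ---- user-facing charts -------------------------------------------------

#' Radar chart of standardized IBR scores
#'
#' Draws one closed polygon per site over the k biomarker axes, using the
#' shifted scores S from [ibr_std()]. The enclosed area of each polygon is
#' what the IBR index measures. Axis minimum is 0; the maximum defaults to
#' the largest S score.
#'
#' @param std An `ibr_std` object.
#' @param file Output path; the extension selects the format.
#' @param format Optional `"svg"`, `"png"` or `"pdf"` override.
#' @param segments Number of concentric rings.
#' @param colors Optional vector of per-site colors.
#' @param max_score Optional axis maximum (default `max(S)`).
#' @param ticks Optional explicit ring labels (length `segments + 1`).
#' @return `file`, invisibly.
#' @export
ibr_chart <- function(std, file, format = NULL, segments = 4, colors = NULL,
                      max_score = NULL, ticks = NULL) {
  if (!inherits(std, "ibr_std")) stop("`std` must be an ibr_std object",
                                      call. = FALSE)
  hi <- if (is.null(max_score)) max(std$S) else max_score
  if (hi <= 0) hi <- 1  # all-zero scores: keep a valid axis
  if (is.null(colors)) {
    colors <- rep_len(.radar_palette, length(std$sites))
  }
  series <- lapply(seq_along(std$sites), function(i) {
    list(name = std$sites[i], values = std$S[i, ], color = colors[i],
         dashed = FALSE, points = FALSE)
  })
  spec <- make_chart_spec(std$biomarkers, series, 0, hi, segments, ticks)
  render_chart(spec, file, format)
}

#' Radar chart of IBRv2 A parameters for one site
#'
#' Draws the site's biomarker deviation indexes (A parameters) as a solid
#' polygon with point markers, overlaid on the reference's zero line drawn
#' as a dashed black polygon with point markers. Vertices above the dashed
#' baseline are upregulated relative to the reference, vertices below are
#' downregulated. The axis range defaults to `[min(A, 0), max(A, 0)]` for
#' the plotted site, with `segments` rings.
#'
#' @param bdi An `ibrv2_bdi` object.
#' @param site Site label to plot. Requesting the reference site itself
#'   warns and renders the baseline only.
#' @param file Output path; the extension selects the format.
#' @param format Optional `"svg"`, `"png"` or `"pdf"` override.
#' @param segments Number of concentric rings.
#' @param range Optional axis range `c(lo, hi)` override.
#' @param ticks Optional explicit ring labels, e.g. from [axis_ticks()].
#' @param color Polygon color for the site.
#' @return `file`, invisibly.
#' @export
ibrv2_chart <- function(bdi, site, file, format = NULL, segments = 4,
                        range = NULL, ticks = NULL, color = "#D55E00") {
  if (!inherits(bdi, "ibrv2_bdi")) stop("`bdi` must be an ibrv2_bdi object",
                                        call. = FALSE)
  if (!site %in% bdi$sites) stop("unknown site '", site, "'", call. = FALSE)
  baseline_only <- site == bdi$reference
  if (baseline_only) {
    warning("site '", site, "' is the reference site; rendering the ",
            "zero baseline only")
  }
  a <- bdi$A[site, ]
  if (is.null(range)) {
    lo <- min(a, 0)
    hi <- max(a, 0)
    if (lo == hi) { lo <- -1; hi <- 1 }  # all-zero deviations
  } else {
    lo <- range[1L]; hi <- range[2L]
  }
  series <- list(list(name = bdi$reference, values = rep(0, length(a)),
                      color = "black", dashed = TRUE, points = TRUE))
  if (!baseline_only) {
    series <- c(series, list(list(name = site, values = a, color = color,
                                  dashed = FALSE, points = TRUE)))
  }
  spec <- make_chart_spec(bdi$biomarkers, series, lo, hi, segments, ticks)
  render_chart(spec, file, format)
}
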