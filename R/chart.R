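#' Build a value-for-money chart specification
#'
#' Lays out the chart's data: the plotted points, the Pareto frontier, the
#' quadrant guide thresholds (defaulting to the midpoint of the plotted
#' cost and benefit ranges, since any division into "good value" and
#' "poor value" quadrants is a display convention, not a property of the
#' data), the evidence-to-bubble-area mapping (areas in ratio 1 : 2 : 3
#' for poor : medium : high) and the X-factor highlight.
#'
#' @param points A non-empty `vfm_points` data frame
#'   (see [build_vfm_points()]).
#' @param cost_threshold,benefit_threshold Quadrant guide positions;
#'   `NULL` means midrange of the data.
#' @param title Chart title.
#' @param width,height Canvas size in pixels.
#' @param max_bubble_radius Radius (px) of a highest-evidence bubble.
#' @param x_factor_fill,neutral_fill Bubble fill colors for flagged /
#'   unflagged technologies.
#' @param hatch_x_factors Use a grayscale-safe hatch pattern instead of a
#'   fill color for X-factor bubbles.
#' @param config Style defaults, see [vfm_config()]; explicit arguments
#'   win over the config.
#' @return An object of class `vfm_chart_spec`.
#' @export
make_chart_spec <- function(points,
                            cost_threshold = config$cost_threshold,
                            benefit_threshold = config$benefit_threshold,
                            title = "Value for Money Chart",
                            width = 720, height = 520,
                            max_bubble_radius = config$max_bubble_radius,
                            x_factor_fill = config$x_factor_fill,
                            neutral_fill = config$neutral_fill,
                            hatch_x_factors = config$hatch_x_factors,
                            config = vfm_config()) {
  if (is.null(points) || nrow(points) == 0L)
    stop("cannot build a chart from an empty portfolio")
  grades <- c("poor", "medium", "high")
  ev <- match(normalize_label(points$evidence), grades)
  if (anyNA(ev))
    stop(sprintf("unknown evidence grade '%s'", points$evidence[which(is.na(ev))[1L]]))
  spec <- list(
    points = points,
    frontier = pareto_frontier(points),
    cost_threshold = if (is.null(cost_threshold))
      mean(range(points$cost)) else cost_threshold,
    benefit_threshold = if (is.null(benefit_threshold))
      mean(range(points$benefit)) else benefit_threshold,
    evidence_rank = ev,
    evidence_areas = config$evidence_areas,
    title = title, width = width, height = height,
    max_bubble_radius = max_bubble_radius,
    x_factor_fill = x_factor_fill, neutral_fill = neutral_fill,
    hatch_x_factors = hatch_x_factors
  )
  class(spec) <- "vfm_chart_spec"
  spec
}

## linear screen scale with degenerate-range guard
make_scale <- function(lo, hi, from, to) {
  if (hi - lo < 1e-12) { lo <- lo - 1; hi <- hi + 1 }
  function(x) from + (x - lo) / (hi - lo) * (to - from)
}

#' Render a chart specification to SVG
#'
#' Produces an SVG 1.1 document whose structure is machine-checkable: one
#' `circle.bubble` per technology (area proportional to evidence grade,
#' fill marking X-factors), a `polyline.frontier` through the Pareto
#' frontier, two `line.quadrant-guide` rules, axis titles "Benefits" and
#' "Total Cost", and one `text.bubble-label` per bubble carrying the
#' technology id.  Benefit is on the vertical axis, cost on the
#' horizontal, origin at (0, 0).
#'
#' @param spec A [make_chart_spec()] object.
#' @param path Optional file to write the SVG to.
#' @return The SVG document as a character string, invisibly if `path`
#'   is given.
#' @export
render_svg <- function(spec, path = NULL) {
  pts <- spec$points
  mar <- c(left = 70, right = 25, top = 45, bottom = 55)
  xr <- c(0, max(pts$cost) * 1.06)
  yr <- c(0, max(pts$benefit) * 1.12)
  sx <- make_scale(xr[1], xr[2], mar[["left"]], spec$width - mar[["right"]])
  sy <- make_scale(yr[1], yr[2], spec$height - mar[["bottom"]], mar[["top"]])

  doc <- xml2::xml_new_root(
    "svg", xmlns = "http://www.w3.org/2000/svg", version = "1.1",
    width = as.character(spec$width), height = as.character(spec$height),
    viewBox = sprintf("0 0 %d %d", spec$width, spec$height))
  add <- function(parent, name, ...) xml2::xml_add_child(parent, name, ...)

  if (spec$hatch_x_factors) {
    defs <- add(doc, "defs")
    pat <- add(defs, "pattern", id = "xfhatch", width = "6", height = "6",
               patternUnits = "userSpaceOnUse", patternTransform = "rotate(45)")
    add(pat, "rect", width = "6", height = "6", fill = "#e8e8e8")
    add(pat, "line", x1 = "0", y1 = "0", x2 = "0", y2 = "6",
        stroke = "#555555", "stroke-width" = "2")
  }

  add(doc, "title", spec$title)
  add(doc, "text", spec$title, x = as.character(spec$width / 2), y = "24",
      "text-anchor" = "middle", "font-size" = "16", class = "chart-title")

  # axes
  x0 <- sx(0); y0 <- sy(0)
  add(doc, "line", x1 = as.character(x0), y1 = as.character(sy(yr[2])),
      x2 = as.character(x0), y2 = as.character(y0),
      stroke = "black", class = "axis")
  add(doc, "line", x1 = as.character(x0), y1 = as.character(y0),
      x2 = as.character(sx(xr[2])), y2 = as.character(y0),
      stroke = "black", class = "axis")
  add(doc, "text", "Benefits", x = "18", y = as.character(spec$height / 2),
      transform = sprintf("rotate(-90 18 %d)", round(spec$height / 2)),
      "text-anchor" = "middle", "font-size" = "13", class = "axis-label")
  add(doc, "text", "Total Cost", x = as.character((x0 + sx(xr[2])) / 2),
      y = as.character(spec$height - 14),
      "text-anchor" = "middle", "font-size" = "13", class = "axis-label")

  # quadrant guides
  add(doc, "line", class = "quadrant-guide",
      x1 = as.character(sx(spec$cost_threshold)), y1 = as.character(sy(yr[2])),
      x2 = as.character(sx(spec$cost_threshold)), y2 = as.character(y0),
      stroke = "#999999", "stroke-dasharray" = "5,4")
  add(doc, "line", class = "quadrant-guide",
      x1 = as.character(x0), y1 = as.character(sy(spec$benefit_threshold)),
      x2 = as.character(sx(xr[2])), y2 = as.character(sy(spec$benefit_threshold)),
      stroke = "#999999", "stroke-dasharray" = "5,4")

  # frontier polyline (a single marker degenerates to a one-vertex polyline)
  fidx <- match(spec$frontier, pts$tech_id)
  fx <- sx(pts$cost[fidx]); fy <- sy(pts$benefit[fidx])
  add(doc, "polyline", class = "frontier",
      points = paste(sprintf("%.2f,%.2f", fx, fy), collapse = " "),
      fill = "none", stroke = "#2a2a2a", "stroke-width" = "1.5")

  # bubbles: area proportional to evidence grade => radius ~ sqrt(area)
  areas <- spec$evidence_areas[spec$evidence_rank]
  r <- spec$max_bubble_radius * sqrt(areas / max(spec$evidence_areas))
  fill <- ifelse(pts$x_flag,
                 if (spec$hatch_x_factors) "url(#xfhatch)" else spec$x_factor_fill,
                 spec$neutral_fill)
  for (i in seq_len(nrow(pts))) {
    add(doc, "circle", class = "bubble",
        cx = sprintf("%.2f", sx(pts$cost[i])), cy = sprintf("%.2f", sy(pts$benefit[i])),
        r = sprintf("%.4f", r[i]), fill = fill[i],
        "fill-opacity" = "0.75", stroke = "#333333",
        "data-tech" = pts$tech_id[i],
        "data-evidence" = pts$evidence[i],
        "data-x-factor" = tolower(as.character(pts$x_flag[i])))
    add(doc, "text", pts$tech_id[i], class = "bubble-label",
        x = sprintf("%.2f", sx(pts$cost[i]) + r[i] + 2),
        y = sprintf("%.2f", sy(pts$benefit[i]) - 2), "font-size" = "10")
  }

  out <- as.character(doc)
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
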