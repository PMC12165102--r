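#' @name rmt
#' @title Right-angled mixture triangle surfaces
#' @description
#' The three-component macronutrient simplex is projected onto a
#' right-angled mixture triangle (RMT): protein percent on the x-axis,
#' fat percent on the y-axis, carbohydrate implicit on the hypotenuse as
#' `100 - x - y`. A fitted Scheffe mixture model is evaluated on a grid
#' restricted to the observed design window, isolines of the predicted
#' response are extracted, and the surface is rendered red (high) to blue
#' (low) with labelled isolines.
NULL

#' Project diet compositions onto the right-angled mixture triangle
#'
#' @param diet A `diet_design` or data frame with `protein`, `carb`,
#'   `fat` fractions.
#' @return Data frame with `x` (protein %) and `y` (fat %); carbohydrate
#'   percent is recoverable as `100 - x - y`.
#' @export
#' @examples
#' project_rmt(make_apex_diets())
project_rmt <- function(diet) {
  diet <- as.data.frame(diet)
  chk <- diet
  if (!"label" %in% names(chk)) chk$label <- as.character(seq_len(nrow(chk)))
  if (!"energy_density" %in% names(chk)) chk$energy_density <- 14.5
  validate_diet_design(chk, require_shared_density = FALSE)
  data.frame(x = 100 * diet$protein, y = 100 * diet$fat)
}

#' Invert the RMT projection back to compositions
#'
#' @param x,y Protein and fat percentages; `x + y <= 100` required.
#' @param energy_density Energy density assigned to the reconstructed
#'   diets.
#' @param labels Optional labels.
#' @return A `diet_design`.
#' @export
unproject_rmt <- function(x, y, energy_density = 14.5, labels = NULL) {
  if (any(x < -1e-9 | y < -1e-9 | x + y > 100 + 1e-9))
    stop("(x, y) must satisfy x >= 0, y >= 0, x + y <= 100")
  if (is.null(labels)) labels <- sprintf("pt%03d", seq_along(x))
  d <- data.frame(label = labels, protein = x / 100,
                  carb = (100 - x - y) / 100, fat = y / 100,
                  energy_density = energy_density,
                  stringsAsFactors = FALSE)
  class(d) <- c("diet_design", "data.frame")
  validate_diet_design(d, require_shared_density = FALSE)
  d
}

# Is an RMT point (percent coordinates) inside the design window?
rmt_inside <- function(x, y, bounds, tol = 1e-9) {
  carb <- 100 - x - y
  x >= bounds$protein[1] - tol & x <= bounds$protein[2] + tol &
    y >= bounds$fat[1] - tol & y <= bounds$fat[2] + tol &
    carb >= bounds$carb[1] - tol & carb <= bounds$carb[2] + tol
}

#' Evaluate a mixture-model response surface on the RMT
#'
#' Predicts the fitted Scheffe model on a regular (protein %, fat %) grid
#' restricted to the observed design window; the model is never
#' extrapolated outside the window (values there are `NA`).
#'
#' @param fit A `mixture_fit`.
#' @param bounds Design window as a list with `protein`, `carb`, `fat`
#'   percent ranges; default the 5--60 / 20--75 / 20--75 array window.
#' @param resolution Grid step in percent (default 1).
#' @param mask `"box"` masks to the axis-aligned window; `"hull"` masks
#'   to the convex hull of `design` projections.
#' @param design The `diet_design` used (required for `mask = "hull"`,
#'   also overplotted by [render_rmt()]).
#' @return An `rmt_surface` list: `x`, `y`, `values` (matrix, `NA`
#'   outside the mask), `mask`, `fit`, `bounds`, `resolution`, `design`.
#' @export
evaluate_surface <- function(fit, bounds = design_bounds(), resolution = 1,
                             mask = c("box", "hull"), design = NULL) {
  mask <- match.arg(mask)
  if (!is.numeric(resolution) || resolution <= 0 || resolution >= 100)
    stop("resolution must be a grid step in (0, 100) percent")
  if (any(unlist(bounds) < -1e-9) || any(unlist(bounds) > 100 + 1e-9))
    stop("bounds must lie within the percent triangle")
  x <- seq(bounds$protein[1], bounds$protein[2], by = resolution)
  y <- seq(bounds$fat[1], bounds$fat[2], by = resolution)
  g <- expand.grid(x = x, y = y)
  inside <- rmt_inside(g$x, g$y, bounds)
  if (mask == "hull") {
    if (is.null(design)) stop("mask = \"hull\" needs the diet design")
    pr <- project_rmt(design)
    hull <- grDevices::chull(pr$x, pr$y)
    inside <- inside & in_convex_hull(g$x, g$y, pr$x[hull], pr$y[hull])
  }
  if (!any(inside)) stop("empty masked region for the requested bounds")
  vals <- rep(NA_real_, nrow(g))
  vals[inside] <- predict(fit, unproject_rmt(g$x[inside], g$y[inside]))
  structure(list(x = x, y = y,
                 values = matrix(vals, length(x), length(y)),
                 mask = matrix(inside, length(x), length(y)),
                 fit = fit, bounds = bounds, resolution = resolution,
                 mask_type = mask, design = design),
            class = "rmt_surface")
}

#' Extract response isolines from an RMT surface
#'
#' Marching-squares contour extraction of the fitted polynomial at the
#' requested response levels, clipped to the surface mask. Levels outside
#' the observed value range are skipped with a warning.
#'
#' @param surface An `rmt_surface`.
#' @param levels Response levels; default a pretty 6-level ladder over the
#'   observed range.
#' @return Data frame `level,x,y,segment_id` of polyline vertices, one
#'   `segment_id` per connected polyline.
#' @export
contour_isolines <- function(surface, levels = NULL) {
  vr <- range(surface$values, na.rm = TRUE)
  auto <- is.null(levels)
  if (auto) levels <- pretty(vr, 6)
  keep <- levels > vr[1] & levels < vr[2]
  if (any(!keep) && !auto)
    warning("skipping isoline level(s) outside the observed response range: ",
            paste(levels[!keep], collapse = ", "))
  levels <- sort(levels[keep])
  if (!length(levels))
    return(data.frame(level = numeric(0), x = numeric(0), y = numeric(0),
                      segment_id = integer(0)))
  # Contour the polynomial on the full rectangle (it is defined
  # everywhere), then clip the polylines to the mask so no isoline
  # crosses the mask boundary.
  g <- expand.grid(x = surface$x, y = surface$y)
  tri <- g$x + g$y <= 100 + 1e-9
  full <- rep(NA_real_, nrow(g))
  full[tri] <- predict(surface$fit, unproject_rmt(g$x[tri], g$y[tri]))
  zfull <- matrix(full, length(surface$x), length(surface$y))
  cl <- grDevices::contourLines(surface$x, surface$y, zfull, levels = levels)
  out <- list(); seg <- 0L
  for (p in cl) {
    ok <- rmt_inside(p$x, p$y, surface$bounds) & is.finite(p$x)
    if (surface$mask_type == "hull" && !is.null(surface$design)) {
      pr <- project_rmt(surface$design)
      hull <- grDevices::chull(pr$x, pr$y)
      ok <- ok & in_convex_hull(p$x, p$y, pr$x[hull], pr$y[hull])
    }
    if (!any(ok)) next
    runs <- rle(ok)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in which(runs$values)) {
      seg <- seg + 1L
      i <- starts[r]:ends[r]
      out[[seg]] <- data.frame(level = p$level, x = p$x[i], y = p$y[i],
                               segment_id = seg)
    }
  }
  if (!length(out))
    return(data.frame(level = numeric(0), x = numeric(0), y = numeric(0),
                      segment_id = integer(0)))
  do.call(rbind, out)
}

#' Write isoline polylines to CSV
#'
#' @param isolines Result of [contour_isolines()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_isolines <- function(isolines, path) {
  utils::write.csv(isolines[, c("level", "x", "y", "segment_id")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Render an RMT response surface to PNG
#'
#' Filled surface (red = high response, blue = low), labelled isolines,
#' and the design diets overplotted. Rendering is deterministic for a
#' fixed surface (fixed style, no timestamps).
#'
#' @param surface An `rmt_surface`.
#' @param path Output PNG path.
#' @param levels Isoline levels (default as in [contour_isolines()]).
#' @param palette `"blue-red"` (blue low to red high) or `"green-red"`.
#' @param width,height Image size in pixels.
#' @return `path`, invisibly.
#' @export
render_rmt <- function(surface, path, levels = NULL,
                       palette = c("blue-red", "green-red"),
                       width = 800, height = 800) {
  palette <- match.arg(palette)
  if (all(is.na(surface$values)))
    stop("empty masked region: nothing to render")
  cols <- switch(palette,
    "blue-red" = grDevices::colorRampPalette(
      c("navy", "steelblue", "white", "indianred", "red"))(100),
    "green-red" = grDevices::colorRampPalette(
      c("darkgreen", "yellowgreen", "gold", "orange", "red"))(100))
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  graphics::image(surface$x, surface$y, surface$values, col = cols,
                  xlim = c(0, 100), ylim = c(0, 100),
                  xlab = "protein (% of energy)", ylab = "fat (% of energy)",
                  main = "predicted response on the right-angled mixture triangle")
  graphics::segments(0, 100, 100, 0, col = "grey40")  # hypotenuse (carb axis)
  graphics::contour(surface$x, surface$y, surface$values, add = TRUE,
                    levels = if (is.null(levels))
                      pretty(range(surface$values, na.rm = TRUE), 6) else levels,
                    labcex = 0.9)
  if (!is.null(surface$design)) {
    pr <- project_rmt(surface$design)
    graphics::points(pr$x, pr$y, pch = 21, bg = "white", cex = 1.4)
  }
  invisible(path)
}
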