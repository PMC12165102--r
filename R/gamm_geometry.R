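#' @name supply_geometry
#' @title Nutrient-supply space geometry and prediction surfaces
#' @description
#' Fitted panel GAMMs are visualized in the 2D (fat, carbohydrate) supply
#' plane with protein held at a quantile of global supply. Two geometric
#' overlays aid interpretation: the isocaloric line, which holds total
#' macronutrient energy constant while the carbohydrate:fat ratio varies
#' (slope -1), and radials from the origin, along which the
#' carbohydrate:fat ratio is constant while total energy grows.
NULL

# Point-in-convex-polygon by uniform cross-product sign (tol on scale).
in_convex_hull <- function(px, py, hx, hy) {
  nh <- length(hx)
  scale <- max(diff(range(hx)), diff(range(hy)))
  tol <- 1e-9 * scale^2
  inside <- rep(TRUE, length(px))
  sgn <- NULL
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    cr <- (hx[j] - hx[i]) * (py - hy[i]) - (hy[j] - hy[i]) * (px - hx[i])
    if (is.null(sgn)) {
      s <- sign(sum(sign(cr[abs(cr) > tol])))
      sgn <- if (s == 0) 1 else s
    }
    inside <- inside & (sgn * cr >= -tol)
  }
  inside
}

#' Predict a (fat, carbohydrate) nutrient surface from a panel GAMM
#'
#' Evaluates the population-level prediction (country random intercept set
#' to 0) on a grid of fat and carbohydrate supplies, with protein supply
#' held at a quantile of the training panel's protein supply and GDP and
#' year fixed. Grid points outside the convex hull of the observed
#' (fat, carb) supply pairs are masked.
#'
#' @param fit A `gamm_fit`.
#' @param fat_grid,carb_grid Supply grids in kcal/capita/day; default 41
#'   points over the observed range.
#' @param protein_quantile Quantile in (0, 1) of the panel's protein
#'   supply at which protein is held (default 0.5).
#' @param gdp_value GDP per capita at which to predict (default panel
#'   median).
#' @param year Calendar year at which to predict (default latest year).
#' @param n_grid Grid size used when grids are not supplied.
#' @return A `nutrient_surface` list: `fat`, `carb`, `values` (matrix,
#'   `NA` outside the mask, on the transformed modelling scale), `mask`,
#'   and the fixed `protein_value`, `gdp_value`, `year`.
#' @export
predict_nutrient_surface <- function(fit, fat_grid = NULL, carb_grid = NULL,
                                     protein_quantile = 0.5,
                                     gdp_value = NULL, year = NULL,
                                     n_grid = 41) {
  if (!is.numeric(protein_quantile) || length(protein_quantile) != 1 ||
      protein_quantile <= 0 || protein_quantile >= 1)
    stop("protein_quantile must be a single value in (0, 1)")
  d <- fit$data
  if (is.null(fat_grid))
    fat_grid <- seq(min(d$fat_kcal), max(d$fat_kcal), length.out = n_grid)
  if (is.null(carb_grid))
    carb_grid <- seq(min(d$carb_kcal), max(d$carb_kcal), length.out = n_grid)
  if (is.null(gdp_value)) gdp_value <- stats::median(d$gdp)
  if (is.null(year)) year <- max(d$year)
  protein_value <- unname(stats::quantile(d$protein_kcal, protein_quantile))

  grid <- expand.grid(fat_kcal = fat_grid, carb_kcal = carb_grid)
  grid$protein_kcal <- protein_value
  grid$gdp <- gdp_value
  grid$year <- year
  pred <- predict(fit, grid, include_random = FALSE)

  hull <- grDevices::chull(d$fat_kcal, d$carb_kcal)
  mask <- in_convex_hull(grid$fat_kcal, grid$carb_kcal,
                         d$fat_kcal[hull], d$carb_kcal[hull])
  values <- matrix(ifelse(mask, pred, NA_real_),
                   nrow = length(fat_grid), ncol = length(carb_grid))
  structure(list(fat = fat_grid, carb = carb_grid, values = values,
                 mask = matrix(mask, length(fat_grid), length(carb_grid)),
                 protein_value = protein_value, protein_quantile = protein_quantile,
                 gdp_value = gdp_value, year = year),
            class = "nutrient_surface")
}

#' Isocaloric line in (fat, carbohydrate) supply space
#'
#' The locus of supply pairs with a fixed total macronutrient energy,
#' given a fixed protein supply: `fat + carb = total - protein`, a segment
#' of slope -1 between the axes.
#'
#' @param total_energy Total macronutrient energy, kcal/capita/day.
#' @param protein_fixed Protein energy held fixed (0 < protein < total).
#' @return List with `fat` and `carb` endpoint coordinates, the
#'   `remaining_energy` shared by fat and carbohydrate, and `slope = -1`.
#' @export
#' @examples
#' isocaloric_line(2000, 300)  # endpoints (0, 1700) and (1700, 0)
isocaloric_line <- function(total_energy, protein_fixed) {
  if (!is.numeric(total_energy) || !is.numeric(protein_fixed) ||
      protein_fixed <= 0 || total_energy <= protein_fixed)
    stop("need total_energy > protein_fixed > 0")
  e <- total_energy - protein_fixed
  list(fat = c(0, e), carb = c(e, 0), remaining_energy = e, slope = -1)
}

#' Constant carbohydrate:fat ratio radial
#'
#' A ray from the origin of the (fat, carbohydrate) supply plane along
#' which the carbohydrate:fat ratio stays constant while total energy
#' increases: `carb = cf_ratio * fat`.
#'
#' @param cf_ratio Carbohydrate:fat energy ratio (> 0).
#' @param max_energy Largest fat + carbohydrate energy on the ray.
#' @return List with the ray endpoints `fat`, `carb`, the `cf_ratio` and
#'   the fat coordinate `fat_max` where the ray reaches `max_energy`.
#' @export
energy_radial <- function(cf_ratio, max_energy) {
  if (!is.numeric(cf_ratio) || length(cf_ratio) != 1 || cf_ratio <= 0)
    stop("cf_ratio must be a single positive ratio")
  if (!is.numeric(max_energy) || max_energy <= 0)
    stop("max_energy must be positive")
  fat_max <- max_energy / (1 + cf_ratio)
  list(fat = c(0, fat_max), carb = c(0, cf_ratio * fat_max),
       cf_ratio = cf_ratio, fat_max = fat_max)
}

#' Export a nutrient surface as CSV
#'
#' Long-format export `fat,carb,prediction,masked` of a
#' [predict_nutrient_surface()] result.
#'
#' @param surface A `nutrient_surface`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_nutrient_surface <- function(surface, path) {
  out <- expand.grid(fat = surface$fat, carb = surface$carb)
  out$prediction <- as.vector(surface$values)
  out$masked <- !as.vector(surface$mask)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Render a nutrient-supply surface with isocaloric and radial overlays
#'
#' Filled prediction surface in the (fat, carbohydrate) supply plane
#' (red = high, through to green = low, the convention of global-burden
#' panels), with labelled isolines, a purple isocaloric line through the
#' panel medians, and red constant-ratio radials.
#'
#' @param surface A `nutrient_surface`.
#' @param path Output PNG path.
#' @param isocaloric Optional [isocaloric_line()]; `NULL` draws one
#'   through the surface mid-range.
#' @param radial_ratios Carbohydrate:fat ratios for the red radials.
#' @param width,height Image size in pixels.
#' @return `path`, invisibly.
#' @export
render_nutrient_surface <- function(surface, path, isocaloric = NULL,
                                    radial_ratios = c(0.5, 1, 2, 4),
                                    width = 800, height = 800) {
  if (all(is.na(surface$values)))
    stop("empty masked region: nothing to render")
  if (is.null(isocaloric)) {
    tot <- mean(surface$fat) + mean(surface$carb) + surface$protein_value
    isocaloric <- isocaloric_line(tot, surface$protein_value)
  }
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  pal <- grDevices::colorRampPalette(c("darkgreen", "yellowgreen", "gold",
                                       "orange", "red"))(100)
  graphics::image(surface$fat, surface$carb, surface$values, col = pal,
                  xlab = "fat supply (kcal/capita/day)",
                  ylab = "carbohydrate supply (kcal/capita/day)",
                  main = sprintf("protein at %.0f kcal (q = %.2f), GDP %.0f, %d",
                                 surface$protein_value, surface$protein_quantile,
                                 surface$gdp_value, surface$year),
                  useRaster = FALSE)
  graphics::contour(surface$fat, surface$carb, surface$values, add = TRUE,
                    labcex = 0.9)
  graphics::lines(isocaloric$fat, isocaloric$carb, col = "purple", lwd = 3)
  for (r in radial_ratios) {
    ray <- energy_radial(r, max(surface$fat) + max(surface$carb))
    graphics::lines(ray$fat, ray$carb, col = "red", lwd = 1.5, lty = 2)
  }
  invisible(path)
}
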