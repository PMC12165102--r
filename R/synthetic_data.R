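#' @name synthetic_data
#' @title Seeded generators with known ground truth
#' @description
#' Two generators emulate the package's input classes: a global
#' country-year macronutrient-supply panel (~150 countries, 1990--2018,
#' intercorrelated supplies/GDP/time, smooth burden response) and a
#' 10-diet isocaloric Treg feeding experiment. Both return the generating
#' truth alongside the data, so every recovery and model-selection test
#' can compare against a known reference.
NULL

#' Configuration for the synthetic country-year panel
#'
#' Defaults emulate the study conditions of the global analysis: 150
#' countries over 1990--2018, log-GDP following a per-country random walk
#' with drift, and macronutrient supplies driven by a secular trend and a
#' positive GDP coupling (so supplies, GDP and time are intercorrelated).
#' The burden rate is generated on the log scale from a smooth nutrient
#' surface whose defaults encode a response rising in carbohydrate supply
#' and falling in fat supply, with a mild saturating nonlinearity, an
#' optional multiplicative GDP interaction, and a mild declining year
#' trend.
#'
#' @param n_countries Number of countries (default 150).
#' @param years Year range (default 1990:2018).
#' @param gdp_log_mean,gdp_log_sd Baseline distribution of log GDP per
#'   capita across countries.
#' @param gdp_drift,gdp_noise Per-year drift and innovation SD of the
#'   log-GDP random walk.
#' @param supply_base,supply_trend,supply_gdp_coupling,supply_noise Named
#'   `(protein, carb, fat)` vectors: baseline supply (kcal/capita/day),
#'   secular trend (kcal/year), coupling to centered log GDP (kcal per
#'   log-dollar), and residual SD (kcal).
#' @param carb_amplitude,fat_amplitude Log-scale amplitudes of the rising
#'   carbohydrate and falling fat effects.
#' @param nonlinearity Saturation weight in `[0, 1]` (0 = linear effects).
#' @param interaction Amplitude of the multiplicative nutrient-by-GDP
#'   interaction (0 = purely additive truth).
#' @param year_trend Log-scale trend per year (default mildly negative).
#' @param country_sd SD of country random intercepts (log scale).
#' @param noise_sd Residual SD (log scale).
#' @param base_log_rate Baseline log rate (per 100,000).
#' @param strata Strata to generate (default `"both"`).
#' @param dropout Uniform row-dropout probability.
#' @param seed Integer seed (required).
#' @return A `panel_config` list.
#' @export
panel_config <- function(n_countries = 150, years = 1990:2018,
                         gdp_log_mean = 8.5, gdp_log_sd = 1.0,
                         gdp_drift = 0.02, gdp_noise = 0.03,
                         supply_base = c(protein = 250, carb = 1400, fat = 550),
                         supply_trend = c(protein = 1.0, carb = 3.0, fat = 4.0),
                         supply_gdp_coupling = c(protein = 25, carb = 60, fat = 90),
                         supply_noise = c(protein = 15, carb = 60, fat = 45),
                         carb_amplitude = 0.5, fat_amplitude = 0.5,
                         nonlinearity = 0.5, interaction = 0.5,
                         year_trend = -0.005,
                         country_sd = 0.3, noise_sd = 0.15,
                         base_log_rate = log(30), strata = "both",
                         dropout = 0, seed) {
  if (missing(seed)) stop("seed is required")
  if (n_countries < 1) stop("n_countries must be positive")
  if (is.unsorted(years)) stop("years must be ordered")
  for (v in list(supply_base, supply_trend, supply_gdp_coupling, supply_noise))
    stopifnot(all(c("protein", "carb", "fat") %in% names(v)))
  if (any(c(gdp_noise, supply_noise, country_sd, noise_sd) < 0))
    stop("noise scales must be >= 0")
  if (nonlinearity < 0 || nonlinearity > 1)
    stop("nonlinearity must be in [0, 1]")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(as.list(environment()), class = "panel_config")
}

# Saturating effect curve: linear at nl = 0, tanh-flattened at nl = 1.
# Monotone for nl in [0, 1].
saturating <- function(z, nl) (1 - nl) * z + nl * 1.5 * tanh(z / 1.5)

#' Generate a synthetic country-year panel with known truth
#'
#' @param config A [panel_config()].
#' @return List of class `panel_sim` with elements `panel` (a
#'   `country_panel`), `truth` (a function
#'   `f(protein, carb, fat, gdp, year)` returning the population-level
#'   expected response on the `log(rate + 0.5)` scale), `country_effects`,
#'   and `config`. Byte-identical for identical configs.
#' @export
#' @examples
#' sim <- gen_country_panel(panel_config(n_countries = 20, seed = 1))
#' nrow(sim$panel)  # 20 countries x 29 years
gen_country_panel <- function(config) {
  if (!inherits(config, "panel_config")) stop("config must be a panel_config")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(config$seed))

  nc <- config$n_countries
  yrs <- config$years
  ny <- length(yrs)
  span <- if (ny > 1) yrs[ny] - yrs[1] else 1
  countries <- sprintf("C%03d", seq_len(nc))

  # log-GDP: per-country random walk with drift.
  lg <- matrix(0, nc, ny)
  lg[, 1] <- stats::rnorm(nc, config$gdp_log_mean, config$gdp_log_sd)
  if (ny > 1) for (t in 2:ny)
    lg[, t] <- lg[, t - 1] + config$gdp_drift + stats::rnorm(nc, 0, config$gdp_noise)

  # Supplies: baseline + secular trend + GDP coupling + noise.
  supply <- function(nutrient) {
    b <- config$supply_base[[nutrient]]
    tr <- config$supply_trend[[nutrient]]
    cp <- config$supply_gdp_coupling[[nutrient]]
    sd <- config$supply_noise[[nutrient]]
    s <- b + tr * outer(rep(1, nc), yrs - yrs[1]) +
      cp * (lg - config$gdp_log_mean) +
      matrix(stats::rnorm(nc * ny, 0, sd), nc, ny)
    pmax(s, 1)
  }
  P <- supply("protein"); C <- supply("carb"); F_ <- supply("fat")

  # Standardization constants of the truth surface are derived from the
  # config alone (mid-period moments), so the truth is a fixed function
  # independent of the realized sample.
  mid_lg_sd <- sqrt(config$gdp_log_sd^2 + config$gdp_noise^2 * span / 2)
  centers <- scales <- numeric(0)
  for (nutrient in c("protein", "carb", "fat")) {
    tr <- config$supply_trend[[nutrient]]
    cp <- config$supply_gdp_coupling[[nutrient]]
    centers[nutrient] <- config$supply_base[[nutrient]] + tr * span / 2 +
      cp * config$gdp_drift * span / 2
    scales[nutrient] <- sqrt((cp * mid_lg_sd)^2 + (tr * span / sqrt(12))^2 +
                               config$supply_noise[[nutrient]]^2)
  }
  g_center <- config$gdp_log_mean + config$gdp_drift * span / 2
  mid_year <- yrs[1] + span / 2
  amp_c <- config$carb_amplitude; amp_f <- config$fat_amplitude
  nl <- config$nonlinearity; inter <- config$interaction
  ytr <- config$year_trend; b0 <- config$base_log_rate
  truth <- function(protein, carb, fat, gdp, year) {
    zc <- (carb - centers[["carb"]]) / scales[["carb"]]
    zf <- (fat - centers[["fat"]]) / scales[["fat"]]
    zg <- (log(gdp) - g_center) / mid_lg_sd
    nutr <- amp_c * saturating(zc, nl) - amp_f * saturating(zf, nl)
    b0 + nutr * (1 + inter * zg) + ytr * (year - mid_year)
  }

  rows <- list()
  country_effects <- list()
  for (st in config$strata) {
    u <- stats::rnorm(nc, 0, config$country_sd)
    country_effects[[st]] <- stats::setNames(u, countries)
    eps <- matrix(stats::rnorm(nc * ny, 0, config$noise_sd), nc, ny)
    eta <- truth(P, C, F_, exp(lg), outer(rep(1, nc), yrs)) + u + eps
    rows[[st]] <- data.frame(
      country = rep(countries, ny), year = rep(yrs, each = nc), stratum = st,
      protein_kcal = as.vector(P), carb_kcal = as.vector(C),
      fat_kcal = as.vector(F_), gdp = as.vector(exp(lg)),
      rate = as.vector(pmax(exp(eta) - 0.5, 0)),
      stringsAsFactors = FALSE)
  }
  panel <- do.call(rbind, rows)
  if (config$dropout > 0)
    panel <- panel[stats::runif(nrow(panel)) >= config$dropout, , drop = FALSE]
  panel <- panel[order(panel$stratum, panel$country, panel$year), ]
  structure(list(panel = as_country_panel(panel), truth = truth,
                 country_effects = country_effects, config = config),
            class = "panel_sim")
}

#' Configuration for the synthetic diet-response experiment
#'
#' Defaults emulate the 10-diet isocaloric feeding array with 8 animals
#' per diet and a fat-dominant linear (Scheffe model 1) truth for the
#' Treg-percentage response.
#'
#' @param design A `diet_design`; default `make_full_design(10, seed = 1)`
#'   -- a fixed array, so replicate experiments vary only in noise.
#' @param n_per_diet Animals per diet (default 8).
#' @param truth_model Generating Scheffe model id (1--4).
#' @param beta True coefficient vector; length must match the model
#'   (3, 6, 7 or 10). Default `c(2, 4, 12)`: fat-dominant linear truth.
#' @param noise_sd Residual SD of the response (default 1).
#' @param seed Integer seed (required).
#' @return A `treg_config` list.
#' @export
treg_config <- function(design = NULL, n_per_diet = 8, truth_model = 1,
                        beta = c(2, 4, 12), noise_sd = 1, seed) {
  if (missing(seed)) stop("seed is required")
  if (is.null(design)) design <- make_full_design(10, seed = 1)
  validate_diet_design(design)
  if (n_per_diet < 1) stop("n_per_diet must be >= 1")
  k_needed <- length(mixture_term_names(truth_model))
  if (length(beta) != k_needed)
    stop("beta must have length ", k_needed, " for model ", truth_model)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(design = design, n_per_diet = as.integer(n_per_diet),
                 truth_model = as.character(truth_model),
                 beta = stats::setNames(beta, mixture_term_names(truth_model)),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "treg_config")
}

#' Generate a synthetic diet-response experiment
#'
#' Per-animal responses are drawn as
#' `Scheffe(truth_model, beta) + N(0, noise_sd)` at each design diet.
#'
#' @param config A [treg_config()].
#' @return List of class `treg_sim` with `data` (diet-response table:
#'   `label`, `protein`, `carb`, `fat`, `response`), `beta` (the
#'   generating coefficients), `design` and `config`.
#' @export
#' @examples
#' sim <- gen_treg_experiment(treg_config(seed = 7))
#' nrow(sim$data)  # 10 diets x 8 animals
gen_treg_experiment <- function(config) {
  if (!inherits(config, "treg_config")) stop("config must be a treg_config")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)
  d <- config$design
  idx <- rep(seq_len(nrow(d)), each = config$n_per_diet)
  X <- build_design_matrix(d[idx, ], config$truth_model)
  y <- drop(X %*% config$beta) + stats::rnorm(nrow(X), 0, config$noise_sd)
  out <- data.frame(label = d$label[idx],
                    protein = d$protein[idx], carb = d$carb[idx],
                    fat = d$fat[idx], response = y,
                    stringsAsFactors = FALSE)
  structure(list(data = out, beta = config$beta, design = d, config = config),
            class = "treg_sim")
}
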