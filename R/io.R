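#' @name nutrigeom_io
#' @title CSV/JSON interchange
#' @description CSV (UTF-8, header row, `.` decimal) is the single tabular
#'   interchange format; fitted models are exported as JSON so runs are
#'   diffable. Validation messages go to standard error, never to standard
#'   output.
NULL

log_msg <- function(...) message(...)  # messages go to stderr

# Shared CSV reader: checks the header, coerces declared numeric columns
# and reports the first offending row on parse failure.
read_checked_csv <- function(path, required, numeric_cols = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character", check.names = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !(d[[col]] %in% c("", "NA")))
    if (length(bad))
      stop("parse error in ", path, ": non-numeric value ",
           shQuote(d[[col]][bad[1]]), " in column ", col,
           " at data row ", bad[1])
    d[[col]] <- v
  }
  d
}

panel_columns <- c("country", "year", "stratum", "protein_kcal", "carb_kcal",
                   "fat_kcal", "gdp", "rate")

#' Read a country-year macronutrient-supply panel from CSV
#'
#' Expects columns `country,year,stratum,protein_kcal,carb_kcal,fat_kcal,
#' gdp,rate`: per-capita daily energy supplies (kcal) from each
#' macronutrient, GDP per capita, and an age-standardized disease burden
#' rate per 100,000. Rows violating the panel invariants (non-positive
#' supplies or GDP, negative rate, missing values) are dropped with a
#' logged reason; duplicated `(country, year, stratum)` keys are an error.
#'
#' @param path CSV file path.
#' @return A validated `country_panel` data frame.
#' @export
read_panel <- function(path) {
  d <- read_checked_csv(path, panel_columns,
    numeric_cols = c("year", "protein_kcal", "carb_kcal", "fat_kcal",
                     "gdp", "rate"))
  n0 <- nrow(d)
  bad <- !stats::complete.cases(d[, panel_columns]) |
    d$protein_kcal <= 0 | d$carb_kcal <= 0 | d$fat_kcal <= 0 |
    d$gdp <= 0 | d$rate < 0
  if (any(bad)) {
    log_msg("read_panel: dropped ", sum(bad), " invalid row(s) at data row(s) ",
            paste(utils::head(which(bad), 10), collapse = ", "),
            if (sum(bad) > 10) ", ..." else "")
    d <- d[!bad, , drop = FALSE]
  }
  if (!nrow(d)) stop("panel is empty after validation")
  key <- paste(d$country, d$year, d$stratum, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (country, year, stratum) record(s), e.g. ",
         gsub("\r", "/", key[duplicated(key)][1]))
  d <- as_country_panel(d)
  log_msg("read_panel: ", nrow(d), " of ", n0, " rows retained from ", path)
  d
}

as_country_panel <- function(d) {
  d <- as.data.frame(d)[, panel_columns]
  d$country <- as.character(d$country)
  d$stratum <- as.character(d$stratum)
  rownames(d) <- NULL
  class(d) <- c("country_panel", "data.frame")
  d
}

#' Write a country panel to CSV
#'
#' @param panel A `country_panel` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel)[, panel_columns], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a diet-response table from CSV
#'
#' Expects columns `label,protein_pct,carb_pct,fat_pct,response` with one
#' row per animal (macronutrients in percent of diet energy; normalized to
#' fractions with simplex closure validated at `1e-8`).
#'
#' @param path CSV file path.
#' @return Data frame with columns `label`, `protein`, `carb`, `fat`,
#'   `response`.
#' @export
read_diet_response <- function(path) {
  d <- read_checked_csv(path,
    c("label", "protein_pct", "carb_pct", "fat_pct", "response"),
    numeric_cols = c("protein_pct", "carb_pct", "fat_pct", "response"))
  out <- data.frame(label = as.character(d$label),
                    protein = d$protein_pct / 100,
                    carb = d$carb_pct / 100,
                    fat = d$fat_pct / 100,
                    response = d$response,
                    stringsAsFactors = FALSE)
  fr <- as.matrix(out[, c("protein", "carb", "fat")])
  bad <- which(abs(rowSums(fr) - 1) > 1e-8)
  if (length(bad))
    stop("compositions do not close to 100% within tolerance at data row(s) ",
         paste(utils::head(bad, 10), collapse = ", "))
  if (!all(is.finite(out$response))) stop("responses must be finite")
  out
}

#' Write a diet-response table to CSV
#'
#' @param data Data frame with `label`, `protein`, `carb`, `fat`,
#'   `response` (fractions).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_diet_response <- function(data, path) {
  out <- data.frame(label = data$label,
                    protein_pct = data$protein * 100,
                    carb_pct = data$carb * 100,
                    fat_pct = data$fat * 100,
                    response = data$response)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a mixture-model fit (and its AIC table) as JSON
#'
#' @param fit A `mixture_fit`, ideally from [select_model()] so the full
#'   candidate AIC table is included.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_mixture_fit_json <- function(fit, path) {
  obj <- list(model_id = fit$model_id,
              term_names = fit$term_names,
              coefficients = as.list(fit$coefficients),
              n = fit$n_obs, k = fit$k, rss = fit$rss, aic = fit$aic,
              exact = fit$exact)
  if (!is.null(fit$aic_table)) obj$aic_table <- fit$aic_table
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' Export a GAMM fit report as JSON
#'
#' Writes the model structure, per-block smoothing parameters, effective
#' degrees of freedom, residual sum of squares and the candidate AIC table
#' (when the fit came from [select_gamm()]).
#'
#' @param fit A `gamm_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_gamm_fit_json <- function(fit, path) {
  obj <- list(
    terms = lapply(fit$spec$terms, function(t)
      list(variables = t$variables, k = t$k, penalty_order = t$penalty_order)),
    random_country = fit$spec$include_random_country,
    response_transform = fit$spec$response_transform,
    lambda = as.list(fit$lambda),
    edf = fit$edf, rss = fit$rss, gcv = fit$gcv, aic = fit$aic,
    n = fit$n_obs)
  if (!is.null(fit$aic_table)) obj$aic_table <- fit$aic_table
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
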