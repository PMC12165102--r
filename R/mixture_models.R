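#' @name mixture_models
#' @title Scheffe polynomial mixture models for diet-response data
#' @description
#' Diet-response experiments on the macronutrient simplex are modelled with
#' the Scheffe polynomial family for mixture experiments. Because the
#' components (protein, carbohydrate, fat energy fractions) sum to one, the
#' models carry no intercept; the candidate family comprises a null
#' (intercept-only) model and the four Lawson-Willden polynomials:
#' linear (model 1), quadratic (model 2), special cubic (model 3) and full
#' cubic (model 4). Candidates are compared by AIC and the lowest-AIC fit
#' is selected.
NULL

mixture_model_ids <- c("null", "1", "2", "3", "4")

mixture_term_names <- function(model_id) {
  lin <- c("protein", "carb", "fat")
  quad <- c("protein:carb", "protein:fat", "carb:fat")
  cubic_special <- "protein:carb:fat"
  cubic_full <- c("protein:carb:(p-c)", "protein:fat:(p-f)", "carb:fat:(c-f)")
  switch(as.character(model_id),
    "null" = "(Intercept)",
    "1" = lin,
    "2" = c(lin, quad),
    "3" = c(lin, quad, cubic_special),
    "4" = c(lin, quad, cubic_full, cubic_special),
    stop("unknown model_id: ", model_id,
         " (must be one of null, 1, 2, 3, 4)"))
}

#' Build a Scheffe mixture design matrix
#'
#' Maps diet compositions `(x1, x2, x3) = (protein, carb, fat)` to the model
#' matrix of a Scheffe polynomial. No intercept column is included for
#' models 1--4: the sum-to-one constraint of the simplex makes it redundant.
#'
#' @param diets A `diet_design` or data frame with columns
#'   `protein`, `carb`, `fat` (energy fractions).
#' @param model_id One of `"null"`, `1`, `2`, `3`, `4`.
#' @return Numeric matrix, one row per diet, with labelled term columns:
#'   null `[1]`; model 1 `[x1, x2, x3]`; model 2 adds `[x1 x2, x1 x3,
#'   x2 x3]`; model 3 adds `x1 x2 x3`; model 4 adds the cubic asymmetry
#'   terms `x_i x_j (x_i - x_j)` and `x1 x2 x3`.
#' @export
#' @examples
#' build_design_matrix(make_apex_diets(), 2)
build_design_matrix <- function(diets, model_id) {
  terms <- mixture_term_names(model_id)  # validates model_id
  diets <- as.data.frame(diets)
  if (!all(c("protein", "carb", "fat") %in% names(diets)))
    stop("diets must have protein, carb and fat columns")
  x1 <- diets$protein; x2 <- diets$carb; x3 <- diets$fat
  n <- length(x1)
  X <- switch(as.character(model_id),
    "null" = matrix(1, n, 1),
    "1" = cbind(x1, x2, x3),
    "2" = cbind(x1, x2, x3, x1 * x2, x1 * x3, x2 * x3),
    "3" = cbind(x1, x2, x3, x1 * x2, x1 * x3, x2 * x3, x1 * x2 * x3),
    "4" = cbind(x1, x2, x3, x1 * x2, x1 * x3, x2 * x3,
                x1 * x2 * (x1 - x2), x1 * x3 * (x1 - x3),
                x2 * x3 * (x2 - x3), x1 * x2 * x3))
  colnames(X) <- terms
  X
}

#' Akaike information criterion from a residual sum of squares
#'
#' Uses the least-squares convention `AIC = n log(rss / n) + 2 (k + 1)`,
#' counting the error variance as an estimated parameter. Only AIC
#' differences matter for selection; the convention is fixed so that
#' results are reproducible bit-for-bit.
#'
#' @param n Number of observations.
#' @param rss Residual sum of squares (> 0).
#' @param k Number of mean-model coefficients.
#' @return The AIC value.
#' @export
#' @examples
#' mixture_aic(10, 1, 3)  # 10*log(0.1) + 8
mixture_aic <- function(n, rss, k) {
  if (!is.finite(rss) || rss < 0) stop("rss must be finite and >= 0")
  if (rss == 0)
    stop("degenerate fit: rss is 0, AIC is undefined for an exact fit")
  n * log(rss / n) + 2 * (k + 1)
}

#' Fit one Scheffe mixture model by least squares
#'
#' Coefficients are estimated by QR (rank-revealing orthogonal)
#' decomposition of the no-intercept Scheffe design matrix.
#'
#' @param data Diet-response table: data frame with columns `protein`,
#'   `carb`, `fat` (energy fractions) and `response`.
#' @param model_id One of `"null"`, `1`, `2`, `3`, `4`.
#' @return An object of class `mixture_fit`: list with `model_id`,
#'   `coefficients` (named), `term_names`, `n_obs`, `k`, `rss`, `aic`
#'   (`NA` for an exact fit), `fitted`, `exact` flag.
#' @export
#' @examples
#' dd <- make_full_design(10, seed = 1)
#' dat <- data.frame(dd[, c("protein", "carb", "fat")],
#'                   response = 1 * dd$protein + 2 * dd$carb + 3 * dd$fat)
#' fit_mixture_model(dat, 1)$coefficients
fit_mixture_model <- function(data, model_id) {
  data <- as.data.frame(data)
  if (!"response" %in% names(data)) stop("data must have a response column")
  y <- data$response
  if (!all(is.finite(y))) stop("responses must be finite")
  X <- build_design_matrix(data, model_id)
  k <- ncol(X)
  n <- nrow(X)
  if (n < k)
    stop("insufficient data: ", n, " observations for ", k,
         " parameters of model ", model_id)
  qrX <- qr(X)
  if (qrX$rank < k) {
    collinear <- colnames(X)[qrX$pivot[(qrX$rank + 1):k]]
    stop("singular design for model ", model_id,
         ": collinear term(s) ", paste(collinear, collapse = ", "))
  }
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)
  rss <- sum((y - fitted)^2)
  # An rss indistinguishable from 0 at double precision is an exact fit.
  exact <- rss <= 1e-12 * max(1, sum(y^2))
  fit <- list(model_id = as.character(model_id),
              coefficients = stats::setNames(as.numeric(beta), colnames(X)),
              term_names = colnames(X),
              n_obs = n, k = k, rss = rss,
              aic = if (exact) NA_real_ else mixture_aic(n, rss, k),
              fitted = fitted, exact = exact)
  class(fit) <- "mixture_fit"
  fit
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Scheffe mixture model", x$model_id,
      sprintf("(k = %d, n = %d)\n", x$k, x$n_obs))
  print(round(x$coefficients, 4))
  cat(sprintf("rss = %.6g, AIC = %s\n", x$rss,
              if (is.na(x$aic)) "undefined (exact fit)" else format(x$aic)))
  invisible(x)
}

#' AIC of a fitted mixture model
#'
#' @param object A `mixture_fit`.
#' @param ... Unused.
#' @param k Ignored (fixed at 2 by the least-squares convention used here).
#' @return The AIC; errors for an exact (rss = 0) fit.
#' @export
AIC.mixture_fit <- function(object, ..., k = 2) {
  mixture_aic(object$n_obs, object$rss, object$k)
}

#' Predict from a fitted mixture model
#'
#' @param object A `mixture_fit`.
#' @param newdata A `diet_design` or data frame with `protein`, `carb`,
#'   `fat` columns.
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.mixture_fit <- function(object, newdata, ...) {
  X <- build_design_matrix(newdata, object$model_id)
  drop(X %*% object$coefficients)
}

#' @rdname predict.mixture_fit
#' @param fit A `mixture_fit`.
#' @param diets Compositions to predict at.
#' @export
predict_mixture <- function(fit, diets) predict.mixture_fit(fit, diets)

#' Select the best mixture model by AIC
#'
#' Fits every candidate (null and models 1--4) whose parameter count does
#' not exceed the number of observations and whose design is full rank,
#' then returns the lowest-AIC fit. Exact fits (rss = 0) are preferred
#' outright over positive-rss candidates, since their AIC diverges to
#' negative infinity; ties (within `1e-9` AIC, or among exact fits) are
#' broken toward the smaller model.
#'
#' @param data Diet-response table (see [fit_mixture_model()]).
#' @param candidates Character vector of model ids to consider.
#' @return The selected `mixture_fit`, with an `aic_table` element: a data
#'   frame of all feasible candidates (model_id, k, rss, aic, selected).
#' @export
select_model <- function(data, candidates = mixture_model_ids) {
  fits <- list()
  failures <- character()
  for (m in candidates) {
    f <- tryCatch(fit_mixture_model(data, m), error = function(e) e)
    if (inherits(f, "error")) failures[m] <- conditionMessage(f) else fits[[m]] <- f
  }
  if (!length(fits))
    stop("no feasible candidate model: ",
         paste(sprintf("[%s] %s", names(failures), failures), collapse = "; "))
  ks <- vapply(fits, `[[`, 0, "k")
  exact <- vapply(fits, `[[`, FALSE, "exact")
  aics <- vapply(fits, `[[`, 0, "aic")
  ord <- order(ks)  # smaller models first for tie-breaks
  if (any(exact)) {
    best <- names(fits)[ord][which(exact[ord])[1]]
  } else {
    cand <- names(fits)[ord]
    a <- aics[cand]
    best <- cand[which(a <= min(a) + 1e-9)[1]]
  }
  sel <- fits[[best]]
  sel$aic_table <- data.frame(
    model_id = names(fits), k = ks, rss = vapply(fits, `[[`, 0, "rss"),
    aic = aics, selected = names(fits) == best, row.names = NULL)
  sel$aic_table <- sel$aic_table[order(ifelse(is.na(sel$aic_table$aic), -Inf,
                                              sel$aic_table$aic)), ]
  rownames(sel$aic_table) <- NULL
  sel
}
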