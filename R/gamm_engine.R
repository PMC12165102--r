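#' @name gamm_engine
#' @title Penalized B-spline GAMM engine for country panels
#' @description
#' A generalized additive mixed model engine built from P-splines: cubic
#' B-spline bases on equally spaced knots with difference penalties on the
#' coefficients, tensor-product smooths for interactions, country random
#' intercepts as a ridge-penalized dummy block, smoothing parameters chosen
#' by GCV coordinate descent, and candidate structures compared by an
#' edf-based AIC. The response is modelled on the `log(rate + 0.5)` scale
#' by default; GDP enters all smooths as log GDP.
NULL

#' Cubic B-spline basis on equally spaced knots
#'
#' Knots are placed uniformly over `xrange` with the usual P-spline
#' boundary extension of `degree` extra knots on each side, so the basis
#' forms a partition of unity on `xrange`.
#'
#' @param x Evaluation points; must lie within `xrange`.
#' @param n_basis Number of basis functions (>= degree + 1).
#' @param degree Spline degree (default cubic, 3).
#' @param xrange Knot range; defaults to `range(x)`.
#' @return Matrix of basis evaluations (rows sum to 1) with attributes
#'   `knots`, `xrange`, `degree`.
#' @export
bspline_basis <- function(x, n_basis, degree = 3, xrange = range(x)) {
  if (n_basis < degree + 1) stop("n_basis must be at least degree + 1")
  if (diff(xrange) <= 0) stop("xrange must have positive width")
  tol <- 1e-8 * max(1, diff(xrange))
  if (any(x < xrange[1] - tol | x > xrange[2] + tol))
    stop("evaluation point outside the boundary knots [",
         xrange[1], ", ", xrange[2], "]")
  nseg <- n_basis - degree
  h <- diff(xrange) / nseg
  knots <- xrange[1] + (-degree:(nseg + degree)) * h
  # pin the boundary knots so clamped data cannot fall outside by rounding
  knots[degree + 1] <- xrange[1]
  knots[degree + 1 + nseg] <- xrange[2]
  x <- pmin(pmax(x, xrange[1]), xrange[2])
  B <- splines::splineDesign(knots, x, ord = degree + 1)
  structure(B, knots = knots, xrange = xrange, degree = degree)
}

#' Difference penalty matrix for P-spline coefficients
#'
#' Returns `S = D' D` where `D` is the `order`-th difference operator on
#' coefficient index; `S` is symmetric positive semidefinite with null
#' space spanned by polynomials of degree < `order` in the index.
#'
#' @param n_basis Number of coefficients (> order).
#' @param order Difference order (default 2).
#' @return `n_basis x n_basis` penalty matrix.
#' @export
difference_penalty <- function(n_basis, order = 2) {
  if (n_basis <= order) stop("n_basis must exceed the penalty order")
  D <- diff(diag(n_basis), differences = order)
  crossprod(D)
}

gamm_variables <- c("protein", "carb", "fat", "gdp", "year")

# Extract a model variable from the panel; GDP enters on the log scale.
panel_variable <- function(panel, var) {
  switch(var,
    protein = panel$protein_kcal,
    carb = panel$carb_kcal,
    fat = panel$fat_kcal,
    gdp = log(panel$gdp),
    year = panel$year,
    stop("unknown model variable: ", var))
}

default_margin_k <- function(n_vars) c(5L, 4L, 4L, 3L)[n_vars]

#' Define a (tensor-product) smooth term
#'
#' @param variables Character vector of 1--4 variables from
#'   `protein`, `carb`, `fat`, `gdp`, `year`.
#' @param k Marginal basis size per variable; defaults to 5 (1 variable),
#'   4 (2--3 variables) or 3 (4 variables) to keep tensor blocks tractable.
#' @param penalty_order Difference-penalty order (default 2); `k` must be
#'   at least `penalty_order + 1`.
#' @return A `smooth_term` list.
#' @export
smooth_term <- function(variables, k = NULL, penalty_order = 2) {
  variables <- as.character(variables)
  if (length(variables) < 1 || length(variables) > 4)
    stop("a smooth term uses 1 to 4 variables")
  if (anyDuplicated(variables)) stop("duplicated variable in smooth term")
  bad <- setdiff(variables, gamm_variables)
  if (length(bad)) stop("unknown model variable: ", paste(bad, collapse = ", "))
  if (is.null(k)) k <- default_margin_k(length(variables))
  if (k < penalty_order + 1)
    stop("marginal basis size must be at least penalty_order + 1")
  # cubic margins where the basis allows, else the largest feasible degree
  structure(list(variables = variables, k = as.integer(k),
                 penalty_order = as.integer(penalty_order),
                 degree = min(3L, as.integer(k) - 1L)),
            class = "smooth_term")
}

#' Specify a GAMM structure
#'
#' @param terms List of [smooth_term()]s with distinct variable sets.
#' @param include_random_country Include a country random intercept block.
#' @param response_transform `"log"` (models `log(rate + 0.5)`) or
#'   `"identity"`.
#' @param name Optional label used in candidate tables.
#' @return A `gamm_spec` list.
#' @export
gamm_spec <- function(terms = list(), include_random_country = TRUE,
                      response_transform = c("log", "identity"),
                      name = NULL) {
  response_transform <- match.arg(response_transform)
  if (inherits(terms, "smooth_term")) terms <- list(terms)
  keys <- vapply(terms, function(t) paste(sort(t$variables), collapse = ","), "")
  if (anyDuplicated(keys)) stop("smooth terms must have distinct variable sets")
  if (!length(terms) && !include_random_country)
    stop("model needs at least one smooth term or the random effect")
  structure(list(terms = terms,
                 include_random_country = isTRUE(include_random_country),
                 response_transform = response_transform,
                 name = name),
            class = "gamm_spec")
}

#' Build tensor-product smooth columns and penalty blocks
#'
#' Columns are the row-wise Kronecker product of the marginal B-spline
#' bases (first variable slowest); each margin contributes one penalty
#' block, its difference penalty Kronecker-expanded with identities on the
#' other margins. Columns are mean-centered for identifiability against
#' the model intercept.
#'
#' @param term A [smooth_term()].
#' @param panel A `country_panel` (or data frame with the panel columns).
#' @param xranges Optional named list of knot ranges per variable (used at
#'   prediction time to reuse the training knots).
#' @param center Column means to subtract; computed from the data when
#'   `NULL`.
#' @return List with `X` (centered columns), `penalties` (list of
#'   penalty matrices, one per margin), `xranges`, `center`.
#' @export
tensor_smooth <- function(term, panel, xranges = NULL, center = NULL) {
  vars <- term$variables
  B_list <- lapply(vars, function(v) {
    x <- panel_variable(panel, v)
    xr <- if (!is.null(xranges)) xranges[[v]] else range(x)
    deg <- if (is.null(term$degree)) 3L else term$degree
    bspline_basis(x, term$k, degree = deg, xrange = xr)
  })
  names(B_list) <- vars
  X <- B_list[[1]]
  for (j in seq_along(B_list)[-1]) {
    Bj <- B_list[[j]]
    X <- X[, rep(seq_len(ncol(X)), each = ncol(Bj)), drop = FALSE] *
      Bj[, rep(seq_len(ncol(Bj)), times = ncol(X)), drop = FALSE]
  }
  if (is.null(center) && nrow(panel) > 0 && ncol(X) > nrow(panel))
    warning("smooth term (", paste(vars, collapse = ","), ") has more columns (",
            ncol(X), ") than rows (", nrow(panel), "); penalties regularize")
  S_marg <- difference_penalty(term$k, term$penalty_order)
  penalties <- lapply(seq_along(vars), function(m) {
    mats <- rep(list(diag(term$k)), length(vars))
    mats[[m]] <- S_marg
    Reduce(kronecker, mats)
  })
  names(penalties) <- vars
  if (is.null(center)) center <- colMeans(X)
  X <- sweep(X, 2, center)
  colnames(X) <- paste0("s(", paste(vars, collapse = ","), ").", seq_len(ncol(X)))
  list(X = X, penalties = penalties,
       xranges = lapply(B_list, attr, "xrange"), center = center)
}

#' Enumerate the candidate GAMM structures
#'
#' A fixed, deterministic candidate set built from the blocks
#' N = joint smooth(protein, carb, fat), G = smooth(gdp), Y = smooth(year)
#' and NxG = joint smooth(protein, carb, fat, gdp):
#' null, N, G, Y, N+G, N+Y, G+Y, N+G+Y, NxG, NxG+Y. Every candidate
#' includes the country random intercept.
#'
#' @param response_transform Passed to each [gamm_spec()].
#' @return Named list of 10 `gamm_spec`s.
#' @export
enumerate_candidates <- function(response_transform = "log") {
  N <- smooth_term(c("protein", "carb", "fat"))
  G <- smooth_term("gdp")
  Y <- smooth_term("year")
  NG <- smooth_term(c("protein", "carb", "fat", "gdp"))
  mk <- function(name, ...) gamm_spec(list(...), TRUE, response_transform, name)
  list(
    "null"   = mk("null"),
    "N"      = mk("N", N),
    "G"      = mk("G", G),
    "Y"      = mk("Y", Y),
    "N+G"    = mk("N+G", N, G),
    "N+Y"    = mk("N+Y", N, Y),
    "G+Y"    = mk("G+Y", G, Y),
    "N+G+Y"  = mk("N+G+Y", N, G, Y),
    "NxG"    = mk("NxG", NG),
    "NxG+Y"  = mk("NxG+Y", NG, Y))
}

# Orthonormal complement of the all-ones coefficient vector. B-spline
# partition of unity makes the mean-centered block annihilate the
# all-ones coefficient direction, which the difference penalty also
# leaves unpenalized; absorbing that constant-function constraint by
# reparameterization keeps the penalized system nonsingular.
ones_complement <- function(k) {
  qr.Q(qr(matrix(1, k, 1)), complete = TRUE)[, -1, drop = FALSE]
}

transform_response <- function(rate, transform) {
  if (transform == "log") log(rate + 0.5) else rate
}

# Penalized normal-equation evaluation for one lambda vector.
pls_eval <- function(XtX, Xty, yty, n, penalties, lambda) {
  A <- XtX
  for (b in seq_along(penalties)) {
    idx <- penalties[[b]]$idx
    A[idx, idx] <- A[idx, idx] + lambda[b] * penalties[[b]]$S
  }
  # Cholesky with escalating jitter: penalty null spaces can leave A
  # numerically singular when a lambda is tiny and basis columns are
  # nearly collinear; an unreliable inverse corrupts the edf trace.
  R <- tryCatch(chol(A), error = function(e) NULL)
  jitter <- 1e-10 * mean(diag(A))
  while ((is.null(R) || min(diag(R)) < 1e-9 * max(diag(R))) && jitter < mean(diag(A))) {
    A <- A + diag(jitter, nrow(A))
    R <- tryCatch(chol(A), error = function(e) NULL)
    jitter <- jitter * 100
  }
  if (is.null(R)) return(list(beta = rep(0, nrow(A)), edf = NA_real_,
                              rss = Inf, gcv = Inf))
  beta <- backsolve(R, forwardsolve(t(R), Xty))
  Ainv <- chol2inv(R)
  edf <- sum(Ainv * XtX)
  rss <- max(yty - 2 * sum(beta * Xty) + sum(beta * (XtX %*% beta)), 1e-300)
  gcv <- if (!is.finite(edf) || edf < 0 || edf > min(n, nrow(A)) || edf >= n)
    Inf else n * rss / (n - edf)^2
  list(beta = beta, edf = edf, rss = rss, gcv = gcv)
}

#' Fit a penalized-spline GAMM to a country panel
#'
#' Solves the penalized least-squares problem
#' `min ||y - X b||^2 + sum_b lambda_b b' S_b b` where the penalty blocks
#' are the marginal difference penalties of each smooth term plus an
#' identity (ridge) penalty on the country-dummy block. Smoothing
#' parameters are chosen by GCV `n rss / (n - edf)^2` via coordinate
#' descent over a log10 grid from 1e-4 to 1e4, three sweeps. The effective
#' degrees of freedom is the trace of the influence matrix and
#' `AIC = n log(rss/n) + 2 (edf + 1)`.
#'
#' @param spec A [gamm_spec()].
#' @param panel A `country_panel`; must contain a single stratum or
#'   `stratum` must name one.
#' @param stratum Stratum to fit (required when the panel has several).
#' @param lambda Optional fixed smoothing parameters (one per penalty
#'   block, smooth-term margins in order then `country`), bypassing GCV.
#' @param gcv_grid Candidate lambda grid for coordinate descent.
#' @param sweeps Number of coordinate-descent sweeps.
#' @return A `gamm_fit` list: coefficients, per-block `lambda`, `edf`,
#'   `rss`, `gcv`, `aic`, fitted values, and the frozen basis ranges and
#'   centering needed for prediction.
#' @export
fit_gamm <- function(spec, panel, stratum = NULL, lambda = NULL,
                     gcv_grid = 10^(-4:4), sweeps = 3) {
  panel <- as.data.frame(panel)
  missing_cols <- setdiff(panel_columns, names(panel))
  if (length(missing_cols))
    stop("panel is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!nrow(panel)) stop("panel is empty")
  strata <- unique(panel$stratum)
  if (is.null(stratum)) {
    if (length(strata) > 1)
      stop("panel has several strata (", paste(strata, collapse = ", "),
           "); pass stratum =")
    stratum <- strata
  }
  panel <- panel[panel$stratum == stratum, , drop = FALSE]
  if (!nrow(panel)) stop("no rows in stratum ", stratum)
  y <- transform_response(panel$rate, spec$response_transform)
  if (!all(is.finite(y))) stop("non-finite response after transform")
  n <- length(y)

  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  penalties <- list()
  term_blocks <- list()
  for (t in spec$terms) {
    ts <- tensor_smooth(t, panel)
    Z <- ones_complement(ncol(ts$X))
    Xb <- ts$X %*% Z
    colnames(Xb) <- paste0("s(", paste(t$variables, collapse = ","), ").",
                           seq_len(ncol(Xb)))
    idx <- ncol(X) + seq_len(ncol(Xb))
    X <- cbind(X, Xb)
    for (m in seq_along(ts$penalties)) {
      Sr <- crossprod(Z, ts$penalties[[m]] %*% Z)
      penalties[[length(penalties) + 1]] <-
        list(idx = idx, S = (Sr + t(Sr)) / 2)
      names(penalties)[length(penalties)] <-
        paste0("s(", paste(t$variables, collapse = ","), "):", names(ts$penalties)[m])
    }
    term_blocks[[length(term_blocks) + 1]] <-
      list(term = t, idx = idx, xranges = ts$xranges, center = ts$center,
           Z = Z)
  }
  countries <- NULL
  random_idx <- NULL
  if (spec$include_random_country) {
    countries <- sort(unique(panel$country))
    Z <- outer(panel$country, countries, "==") * 1
    colnames(Z) <- paste0("country.", countries)
    random_idx <- ncol(X) + seq_len(ncol(Z))
    X <- cbind(X, Z)
    penalties[[length(penalties) + 1]] <-
      list(idx = random_idx, S = diag(length(countries)))
    names(penalties)[length(penalties)] <- "country"
  }

  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  yty <- sum(y^2)
  nb <- length(penalties)
  if (nb == 0L) {
    beta <- solve(XtX, Xty)
    fitted <- drop(X %*% beta)
    rss <- sum((y - fitted)^2)
    edf <- ncol(X)
    lam <- numeric(0)
    gcv <- n * rss / (n - edf)^2
  } else {
    if (!is.null(lambda)) {
      if (length(lambda) != nb)
        stop("lambda must have one value per penalty block (", nb, ")")
      lam <- as.numeric(lambda)
      ev <- pls_eval(XtX, Xty, yty, n, penalties, lam)
    } else {
      lam <- rep(1, nb)
      ev <- pls_eval(XtX, Xty, yty, n, penalties, lam)
      for (s in seq_len(sweeps)) {
        for (b in seq_len(nb)) {
          for (g in gcv_grid) {
            if (g == lam[b]) next
            trial <- lam; trial[b] <- g
            evt <- pls_eval(XtX, Xty, yty, n, penalties, trial)
            if (evt$gcv < ev$gcv) { lam <- trial; ev <- evt }
          }
        }
      }
    }
    if (!is.finite(ev$edf) || ev$edf < 0)
      stop("penalized least-squares system is numerically singular for the ",
           "requested smoothing parameters")
    beta <- ev$beta
    fitted <- drop(X %*% beta)
    rss <- ev$rss
    edf <- ev$edf
    gcv <- ev$gcv
    names(lam) <- names(penalties)
  }
  aic <- n * log(max(rss, 1e-300) / n) + 2 * (edf + 1)
  fit <- list(spec = spec, coefficients = stats::setNames(drop(beta), colnames(X)),
              term_blocks = term_blocks, random_idx = random_idx,
              countries = countries, lambda = lam, edf = edf, rss = rss,
              gcv = gcv, aic = aic, n_obs = n, n_columns = ncol(X),
              fitted = fitted, y = y, stratum = stratum, data = panel)
  class(fit) <- "gamm_fit"
  fit
}

#' @export
print.gamm_fit <- function(x, ...) {
  nm <- if (!is.null(x$spec$name)) x$spec$name else
    paste(vapply(x$spec$terms, function(t)
      paste0("s(", paste(t$variables, collapse = ","), ")"), ""), collapse = " + ")
  cat("Penalized-spline GAMM [", nm, "]\n", sep = "")
  cat(sprintf("n = %d, columns = %d, edf = %.2f, rss = %.4g, AIC = %.2f\n",
              x$n_obs, x$n_columns, x$edf, x$rss, x$aic))
  if (length(x$lambda)) {
    cat("smoothing parameters:\n")
    print(signif(x$lambda, 3))
  }
  invisible(x)
}

#' Predict from a fitted GAMM
#'
#' @param object A `gamm_fit`.
#' @param newdata Data frame with the panel predictor columns
#'   (`protein_kcal`, `carb_kcal`, `fat_kcal`, `gdp`, `year`, and
#'   `country` when `include_random = TRUE`).
#' @param include_random Add the estimated country intercept (unknown
#'   countries get 0). `FALSE` gives the population-level prediction.
#' @param type `"link"` returns predictions on the modelling
#'   (transformed) scale; `"response"` back-transforms to the rate scale.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.gamm_fit <- function(object, newdata, include_random = FALSE,
                             type = c("link", "response"), ...) {
  type <- match.arg(type)
  eta <- rep(object$coefficients[["(Intercept)"]], nrow(newdata))
  for (tb in object$term_blocks) {
    ts <- tensor_smooth(tb$term, newdata, xranges = tb$xranges,
                        center = tb$center)
    eta <- eta + drop((ts$X %*% tb$Z) %*% object$coefficients[tb$idx])
  }
  if (include_random && !is.null(object$random_idx)) {
    u <- object$coefficients[object$random_idx]
    pos <- match(newdata$country, object$countries)
    eta <- eta + ifelse(is.na(pos), 0, u[pos])
  }
  if (type == "response" && object$spec$response_transform == "log")
    eta <- exp(eta) - 0.5
  unname(eta)
}

#' Select the best GAMM candidate by AIC
#'
#' Fits every candidate and returns the lowest-AIC fit; ties (within
#' `1e-9`) are broken toward fewer model columns. The complete candidate
#' table is attached as `aic_table`.
#'
#' @param panel A `country_panel`.
#' @param candidates Named list of [gamm_spec()]s
#'   (default [enumerate_candidates()]).
#' @param stratum Stratum to fit.
#' @param ... Passed to [fit_gamm()].
#' @return The selected `gamm_fit` with an `aic_table` data frame
#'   (candidate, n_columns, edf, rss, aic, selected), sorted by AIC.
#' @export
select_gamm <- function(panel, candidates = enumerate_candidates(),
                        stratum = NULL, ...) {
  fits <- list(); errs <- character()
  for (nm in names(candidates)) {
    f <- tryCatch(fit_gamm(candidates[[nm]], panel, stratum = stratum, ...),
                  error = function(e) e)
    if (inherits(f, "error")) errs[nm] <- conditionMessage(f) else fits[[nm]] <- f
  }
  if (!length(fits))
    stop("all candidate fits failed: ",
         paste(sprintf("[%s] %s", names(errs), errs), collapse = "; "))
  aics <- vapply(fits, `[[`, 0, "aic")
  ncols <- vapply(fits, `[[`, 0, "n_columns")
  ord <- order(ncols)
  cand <- names(fits)[ord]
  best <- cand[which(aics[cand] <= min(aics) + 1e-9)[1]]
  sel <- fits[[best]]
  tab <- data.frame(candidate = names(fits), n_columns = ncols,
                    edf = vapply(fits, `[[`, 0, "edf"),
                    rss = vapply(fits, `[[`, 0, "rss"),
                    aic = aics, selected = names(fits) == best,
                    row.names = NULL)
  sel$aic_table <- tab[order(tab$aic), ]
  rownames(sel$aic_table) <- NULL
  sel$failed_candidates <- errs
  sel
}
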