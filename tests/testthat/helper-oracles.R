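# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: the B-spline oracle is the textbook
# Cox-de Boor recursion, and the least-squares oracle solves the normal
# equations explicitly.

# Cox-de Boor recursion for a single B-spline basis function B_{i,p}(x)
# over a knot vector (0-based index i).
cox_de_boor <- function(x, knots, i, p) {
  if (p == 0)
    return(as.numeric(knots[i + 1] <= x &
                        (x < knots[i + 2] |
                           (x == knots[i + 2] && knots[i + 2] == max(knots)))))
  d1 <- knots[i + p + 1] - knots[i + 1]
  d2 <- knots[i + p + 2] - knots[i + 2]
  a <- if (d1 > 0) (x - knots[i + 1]) / d1 * cox_de_boor(x, knots, i, p - 1) else 0
  b <- if (d2 > 0) (knots[i + p + 2] - x) / d2 * cox_de_boor(x, knots, i + 1, p - 1) else 0
  a + b
}

# Full basis row at one x by the recursion.
cox_de_boor_row <- function(x, knots, p) {
  nb <- length(knots) - p - 1
  vapply(seq_len(nb) - 1L, function(i) cox_de_boor(x, knots, i, p), 0)
}

# Normal-equations least squares (the brute-force oracle).
normal_eq_solve <- function(X, y) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# Independent AIC-table oracle for mixture-model selection: fit all five
# candidates by normal equations and apply the documented AIC convention.
oracle_select <- function(data) {
  ids <- c("null", "1", "2", "3", "4")
  tab <- lapply(ids, function(m) {
    X <- build_design_matrix(data, m)
    if (nrow(X) < ncol(X) || qr(X)$rank < ncol(X)) return(NULL)
    beta <- normal_eq_solve(X, data$response)
    rss <- sum((data$response - drop(X %*% beta))^2)
    exact <- rss <= 1e-12 * max(1, sum(data$response^2))
    data.frame(model_id = m, k = ncol(X), rss = rss, exact = exact,
               aic = if (exact) -Inf else
                 nrow(X) * log(rss / nrow(X)) + 2 * (ncol(X) + 1))
  })
  tab <- do.call(rbind, tab)
  tab <- tab[order(tab$k), ]
  if (any(tab$exact)) tab$model_id[tab$exact][1] else
    tab$model_id[which(tab$aic <= min(tab$aic) + 1e-9)[1]]
}

# Small single-stratum panel for GAMM unit tests (kept tiny for speed).
small_panel <- function(n_countries = 12, years = 2000:2009, seed = 5, ...) {
  gen_country_panel(panel_config(n_countries = n_countries, years = years,
                                 seed = seed, ...))
}
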