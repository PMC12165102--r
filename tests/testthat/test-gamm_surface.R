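test_that("B-spline bases are a partition of unity, local, and match the Cox-de Boor recursion", {
  set.seed(31)
  x <- runif(100, -2, 7)
  B <- bspline_basis(x, 9, xrange = c(-2, 7))
  expect_equal(rowSums(B), rep(1, 100), tolerance = 1e-12)
  # locality at the left boundary
  Bl <- bspline_basis(-2, 9, xrange = c(-2, 7))
  expect_gt(Bl[1, 1], 0)
  expect_equal(Bl[1, 9], 0)
  # independent Cox-de Boor oracle at 100 random points
  knots <- attr(B, "knots")
  for (i in sample(100, 100)) {
    expect_equal(unname(B[i, ]), cox_de_boor_row(x[i], knots, 3),
                 tolerance = 1e-10)
  }
  expect_error(bspline_basis(10, 9, xrange = c(-2, 7)), "outside")
  expect_error(bspline_basis(1:5, 3, degree = 3), "degree \\+ 1")
})

test_that("difference penalties annihilate low-order trends and equal D'D", {
  S <- difference_penalty(5, 2)
  b_lin <- 1:5
  expect_equal(drop(t(b_lin) %*% S %*% b_lin), 0)
  e1 <- c(1, 0, 0, 0, 0)
  expect_equal(drop(t(e1) %*% S %*% e1), 1)
  # independent construction of D
  D <- matrix(0, 3, 5)
  for (i in 1:3) D[i, i:(i + 2)] <- c(1, -2, 1)
  expect_equal(unname(S), t(D) %*% D)
  expect_true(all(eigen(S, symmetric = TRUE, only.values = TRUE)$values > -1e-12))
  expect_error(difference_penalty(2, 2), "exceed")
})

test_that("tensor smooths are row-wise Kronecker products with one penalty per margin", {
  sim <- small_panel()
  p <- sim$panel
  # 1-variable term reduces to the centered marginal basis
  t1 <- smooth_term("gdp", k = 5)
  ts1 <- tensor_smooth(t1, p)
  B <- bspline_basis(log(p$gdp), 5)
  expect_equal(unname(ts1$X), unname(sweep(B, 2, colMeans(B))),
               tolerance = 1e-12)
  expect_length(ts1$penalties, 1)
  # 2-variable term with K = 3 margins: 9 columns, 2 penalty blocks
  t2 <- smooth_term(c("gdp", "year"), k = 3)
  ts2 <- tensor_smooth(t2, p)
  expect_equal(ncol(ts2$X), 9)
  expect_length(ts2$penalties, 2)
  # columns are element-wise products of marginal columns
  B1 <- bspline_basis(log(p$gdp), 3, degree = 2)
  B2 <- bspline_basis(p$year, 3, degree = 2)
  rows <- sample(nrow(p), 20)
  raw <- ts2$X[rows, ] + matrix(ts2$center, length(rows), 9, byrow = TRUE)
  for (i in seq_along(rows)) {
    prod_oracle <- as.vector(outer(B2[rows[i], ], B1[rows[i], ]))
    # column order: first variable slowest
    expect_equal(unname(raw[i, ]),
                 as.vector(t(outer(B1[rows[i], ], B2[rows[i], ]))),
                 tolerance = 1e-12)
    expect_setequal(round(unname(raw[i, ]), 12), round(prod_oracle, 12))
  }
})

test_that("the candidate set is the fixed ten-structure list with country random intercepts", {
  cands <- enumerate_candidates()
  expect_length(cands, 10)
  expect_setequal(names(cands), c("null", "N", "G", "Y", "N+G", "N+Y", "G+Y",
                                  "N+G+Y", "NxG", "NxG+Y"))
  expect_true(all(vapply(cands, `[[`, TRUE, "include_random_country")))
  fav <- cands[["NxG+Y"]]
  expect_length(fav$terms, 2)
  expect_setequal(fav$terms[[1]]$variables, c("protein", "carb", "fat", "gdp"))
  expect_identical(names(enumerate_candidates()), names(cands))
})

test_that("penalty limits reproduce the straight line and the unpenalized fit", {
  set.seed(42)
  n <- 120
  x <- sort(runif(n, 0, 10))
  pan <- data.frame(country = rep(sprintf("C%02d", 1:10), 12), year = 2000,
                    stratum = "both", protein_kcal = x, carb_kcal = 500,
                    fat_kcal = 500, gdp = 1000,
                    rate = pmax(sin(x) + 2 + rnorm(n, 0, 0.1), 0.01))
  sp <- gamm_spec(list(smooth_term("protein", k = 8)),
                  include_random_country = FALSE,
                  response_transform = "identity")
  # lambda -> infinity: order-2 penalty null space leaves a straight line
  f_inf <- fit_gamm(sp, pan, lambda = 1e8)
  ols <- stats::lm(rate ~ protein_kcal, pan)
  expect_equal(f_inf$fitted, unname(fitted(ols)), tolerance = 1e-4)
  # lambda = 0: matches the dense unpenalized least-squares oracle
  f0 <- fit_gamm(sp, pan, lambda = 0)
  B <- bspline_basis(x, 8)
  Bc <- sweep(B, 2, colMeans(B))
  oracle <- stats::lm.fit(cbind(1, Bc), pan$rate)
  expect_equal(f0$fitted, unname(oracle$fitted.values), tolerance = 1e-8)
  # GCV sits between the two extremes and recovers the smooth signal
  fg <- fit_gamm(sp, pan)
  expect_gt(stats::cor(fg$fitted, sin(x) + 2), 0.99)
  expect_error(fit_gamm(sp, pan[, -4]), "missing column")
})

test_that("effective degrees of freedom fall monotonically as lambda grows", {
  set.seed(9)
  n <- 150
  x <- runif(n, 0, 1)
  pan <- data.frame(country = "C01", year = 2000, stratum = "both",
                    protein_kcal = x, carb_kcal = 1, fat_kcal = 1, gdp = 1,
                    rate = rnorm(n, 5, 1))
  sp <- gamm_spec(list(smooth_term("protein", k = 10)),
                  include_random_country = FALSE,
                  response_transform = "identity")
  edfs <- vapply(10^seq(-4, 6, by = 1), function(l)
    fit_gamm(sp, pan, lambda = l)$edf, 0)
  expect_true(all(diff(edfs) < 1e-8))
  expect_gt(edfs[1], 9)     # nearly unpenalized
  expect_lt(edfs[11], 3.1)  # near the 2-dimensional penalty null space
})

test_that("GCV drives noiseless residuals toward zero as the basis grows", {
  x <- seq(0, 1, length.out = 200)
  pan <- data.frame(country = "C01", year = 2000, stratum = "both",
                    protein_kcal = x, carb_kcal = 1, fat_kcal = 1, gdp = 1,
                    rate = sin(2 * pi * x) + 2)
  rss <- vapply(c(5, 10, 20), function(k) {
    sp <- gamm_spec(list(smooth_term("protein", k = k)),
                    include_random_country = FALSE,
                    response_transform = "identity")
    fit_gamm(sp, pan)$rss
  }, 0)
  expect_true(all(diff(rss) < 0))
  expect_lt(rss[3], 1e-4)
})

test_that("country intercepts are ridge-shrunk relative to raw country means", {
  sim <- small_panel(n_countries = 20, seed = 13)
  spec <- enumerate_candidates()[["N+Y"]]
  fit <- fit_gamm(spec, sim$panel)
  u_hat <- fit$coefficients[fit$random_idx]
  # raw per-country mean residuals around the smooth part
  res <- fit$y - (fit$fitted - u_hat[match(fit$data$country, fit$countries)])
  raw_means <- tapply(res, fit$data$country, mean)
  expect_lt(stats::var(u_hat), stats::var(raw_means))
  expect_gt(stats::cor(u_hat, raw_means[fit$countries]), 0.95)
})

test_that("training-point predictions reproduce fitted values with the random intercept", {
  sim <- small_panel(seed = 21)
  fit <- fit_gamm(enumerate_candidates()[["N+G+Y"]], sim$panel)
  pred <- predict(fit, fit$data, include_random = TRUE)
  expect_equal(pred, fit$fitted, tolerance = 1e-8)
  # unknown country falls back to the population level
  nd <- fit$data[1, ]
  nd$country <- "ZZZ"
  expect_equal(predict(fit, nd, include_random = TRUE),
               predict(fit, nd, include_random = FALSE))
  # response-scale prediction inverts the log transform
  expect_equal(predict(fit, fit$data[1:5, ], include_random = TRUE,
                       type = "response"),
               exp(fit$fitted[1:5]) - 0.5, tolerance = 1e-10)
})

test_that("a random-intercept-only model predicts a constant near the transformed mean", {
  sim <- small_panel(seed = 3)
  fit <- fit_gamm(enumerate_candidates()[["null"]], sim$panel)
  surf <- predict_nutrient_surface(fit, n_grid = 11)
  vals <- surf$values[surf$mask]
  expect_equal(diff(range(vals)), 0, tolerance = 1e-10)
  expect_equal(vals[1], mean(log(sim$panel$rate + 0.5)), tolerance = 0.05)
})

test_that("the fitted nutrient surface recovers the generating truth and its signs", {
  sim <- gen_country_panel(panel_config(seed = 11))
  fit <- fit_gamm(enumerate_candidates()[["NxG+Y"]], sim$panel)
  surf <- predict_nutrient_surface(fit, n_grid = 25)
  g <- expand.grid(fat = surf$fat, carb = surf$carb)
  truth <- sim$truth(surf$protein_value, g$carb, g$fat, surf$gdp_value,
                     surf$year)
  m <- as.vector(surf$mask)
  expect_gte(stats::cor(as.vector(surf$values)[m], truth[m]), 0.9)
  v <- surf$values
  d_carb <- v[, -1] - v[, -ncol(v)]
  d_fat <- v[-1, ] - v[-nrow(v), ]
  expect_gte(mean(d_carb > 0, na.rm = TRUE), 0.9)
  expect_gte(mean(d_fat < 0, na.rm = TRUE), 0.9)
  expect_error(predict_nutrient_surface(fit, protein_quantile = 1.2),
               "quantile")
})

test_that("AIC selection prefers the interaction structure only when the truth has one", {
  sim_int <- gen_country_panel(panel_config(seed = 11))
  sel_int <- select_gamm(sim_int$panel)
  expect_equal(sel_int$aic_table$candidate[1], "NxG+Y")
  sim_add <- gen_country_panel(panel_config(seed = 11, interaction = 0))
  sel_add <- select_gamm(sim_add$panel)
  expect_false(grepl("NxG", sel_add$aic_table$candidate[1]))
  # report contract: one row per candidate, ascending AIC
  expect_equal(nrow(sel_int$aic_table), 10)
  expect_false(is.unsorted(sel_int$aic_table$aic))
  expect_equal(sum(sel_int$aic_table$selected), 1)
})

test_that("isocaloric lines and radials obey their defining geometry", {
  iso <- isocaloric_line(2000, 300)
  expect_equal(iso$fat, c(0, 1700))
  expect_equal(iso$carb, c(1700, 0))
  expect_equal(iso$slope, -1)
  expect_equal(diff(iso$carb) / diff(iso$fat), -1)
  expect_error(isocaloric_line(300, 2000), "total_energy > protein_fixed")
  expect_error(isocaloric_line(2000, -1), "> 0")

  ray <- energy_radial(1, 2000)
  expect_equal(ray$carb[2] / ray$fat[2], 1)
  ray2 <- energy_radial(2.5, 3000)
  f <- seq(1e-6, ray2$fat_max, length.out = 20)
  expect_equal((2.5 * f) / f, rep(2.5, 20), tolerance = 1e-12)
  expect_error(energy_radial(0, 100), "positive")
  # unique intersection of a radial with an isocaloric line:
  # cf * f = E - f has the single solution f = E / (1 + cf)
  E <- iso$remaining_energy
  f_star <- E / (1 + ray2$cf_ratio)
  expect_equal(ray2$cf_ratio * f_star, E - f_star, tolerance = 1e-12)
  # carb:fat ratio along the isocaloric line is strictly decreasing in fat
  ff <- seq(100, 1600, by = 100)
  expect_true(all(diff((E - ff) / ff) < 0))
})

test_that("fit reports export as JSON with lambdas, edf and the AIC table", {
  sim <- small_panel(seed = 8)
  sel <- select_gamm(sim$panel,
                     candidates = enumerate_candidates()[c("null", "G", "N+Y")])
  path <- withr::local_tempfile(fileext = ".json")
  write_gamm_fit_json(sel, path)
  obj <- jsonlite::read_json(path)
  expect_named(obj$lambda)
  expect_equal(length(obj$aic_table), 3)
  expect_true(obj$random_country)
  expect_equal(obj$n, nrow(sim$panel))
})
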