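test_that("design matrices carry the Scheffe polynomial terms without intercept", {
  vertex <- data.frame(protein = 1, carb = 0, fat = 0)
  expect_equal(unname(build_design_matrix(vertex, 1)[1, ]), c(1, 0, 0))
  hc <- data.frame(protein = 0.05, carb = 0.75, fat = 0.20)
  expect_equal(unname(build_design_matrix(hc, 1)[1, ]), c(0.05, 0.75, 0.20))
  mix <- data.frame(protein = 0.2, carb = 0.3, fat = 0.5)
  expect_equal(unname(build_design_matrix(mix, 2)[1, ]),
               c(0.2, 0.3, 0.5, 0.06, 0.10, 0.15))
  expect_equal(ncol(build_design_matrix(mix, "null")), 1L)
  expect_equal(ncol(build_design_matrix(mix, 3)), 7L)
  expect_equal(ncol(build_design_matrix(mix, 4)), 10L)
  expect_error(build_design_matrix(mix, 7), "unknown model_id")
})

test_that("least-squares fits interpolate noiseless truths and match the normal-equations oracle", {
  dd <- make_full_design(10, seed = 1)
  dat <- data.frame(dd[, c("protein", "carb", "fat")],
                    response = 1 * dd$protein + 2 * dd$carb + 3 * dd$fat)
  f1 <- fit_mixture_model(dat, 1)
  expect_equal(unname(f1$coefficients), c(1, 2, 3), tolerance = 1e-10)
  expect_lt(f1$rss, 1e-10)
  expect_true(f1$exact)

  # constant response: null model reproduces the mean exactly
  datc <- transform(dat, response = 5)
  f0 <- fit_mixture_model(datc, "null")
  expect_equal(unname(f0$coefficients), 5)
  expect_lt(f0$rss, 1e-20)

  # oracle equivalence over random tables, all five models
  set.seed(101)
  for (rep in 1:10) {
    n <- 20
    p <- runif(n, 0.05, 0.6); f <- runif(n, 0.2, 0.7)
    keep <- 1 - p - f >= 0.1
    tab <- data.frame(protein = p, carb = 1 - p - f, fat = f,
                      response = rnorm(n, 10, 3))[keep, ]
    for (m in c("null", "1", "2", "3", "4")) {
      X <- build_design_matrix(tab, m)
      if (qr(X)$rank < ncol(X)) next
      expect_equal(unname(fit_mixture_model(tab, m)$coefficients),
                   unname(normal_eq_solve(X, tab$response)),
                   tolerance = 1e-8)
    }
  }
})

test_that("degenerate and deficient designs raise informative errors", {
  dd <- make_full_design(10, seed = 1)
  small <- data.frame(dd[1:4, c("protein", "carb", "fat")], response = 1:4)
  expect_error(fit_mixture_model(small, 2), "insufficient data")
  # duplicated single diet: columns proportional -> singular
  one <- data.frame(protein = rep(0.3, 12), carb = 0.3, fat = 0.4,
                    response = rnorm(12))
  expect_error(fit_mixture_model(one, 1), "collinear")
})

test_that("the AIC convention penalizes parameters by 2 per term and ignores row order", {
  expect_equal(mixture_aic(50, 2, 5) - mixture_aic(50, 2, 3), 4)
  expect_equal(mixture_aic(10, 1, 3), 10 * log(0.1) + 8)
  expect_error(mixture_aic(10, 0, 3), "degenerate")
  sim <- gen_treg_experiment(treg_config(seed = 4))
  shuf <- sim$data[sample(nrow(sim$data)), ]
  expect_equal(AIC(fit_mixture_model(sim$data, 2)),
               AIC(fit_mixture_model(shuf, 2)))
})

test_that("AIC selection agrees with an independent all-candidate oracle", {
  # quadratic truth with strong pairwise terms, small noise: selection
  # matches the oracle seed by seed and picks the quadratic model most often
  dd <- make_full_design(10, seed = 1)
  idx <- rep(1:10, each = 8)
  X2 <- build_design_matrix(dd[idx, ], 2)
  picks2 <- character(10)
  for (s in 1:10) {
    set.seed(s)
    y <- drop(X2 %*% c(2, 3, 8, 40, -35, 30)) + rnorm(80, 0, 0.5)
    dat2 <- data.frame(dd[idx, c("protein", "carb", "fat")], response = y)
    sel2 <- select_model(dat2)
    expect_equal(sel2$model_id, oracle_select(dat2))
    picks2[s] <- sel2$model_id
  }
  expect_equal(names(which.max(table(picks2))), "2")

  # pure noise around a constant: null wins
  set.seed(3)
  dat0 <- data.frame(dd[idx, c("protein", "carb", "fat")],
                     response = rnorm(80, 10, 1))
  sel0 <- select_model(dat0)
  expect_equal(sel0$model_id, "null")
  expect_equal(sel0$model_id, oracle_select(dat0))

  # fat-dominant linear truth: selection matches the oracle seed by seed,
  # and the modal outcome is the linear model with fat dominant
  picks <- character(20); fat_dom <- logical(20)
  for (s in 1:20) {
    sim <- gen_treg_experiment(treg_config(seed = s))
    sel <- select_model(sim$data)
    expect_equal(sel$model_id, oracle_select(sim$data))
    picks[s] <- sel$model_id
    fat_dom[s] <- names(which.max(sel$coefficients[c("protein", "carb", "fat")])) == "fat"
  }
  expect_equal(names(which.max(table(picks))), "1")
  # whenever the linear model is chosen, fat carries the largest coefficient
  expect_true(all(fat_dom[picks == "1"]))
  # the AIC table covers every feasible candidate, sorted ascending
  sim <- gen_treg_experiment(treg_config(seed = 1))
  tab <- select_model(sim$data)$aic_table
  expect_setequal(tab$model_id, c("null", "1", "2", "3", "4"))
  expect_false(is.unsorted(tab$aic))
})

test_that("selection is consistent as noise vanishes (exact fits break ties toward the truth)", {
  betas <- list("1" = c(2, 4, 12),
                "2" = c(2, 4, 12, 30, -25, 18),
                "3" = c(2, 4, 12, 30, -25, 18, 60),
                "4" = c(2, 4, 12, 30, -25, 18, 12, -9, 7, 60))
  for (m in names(betas)) {
    for (s in 1:5) {
      sim <- gen_treg_experiment(treg_config(truth_model = m, beta = betas[[m]],
                                             noise_sd = 1e-8, seed = s))
      expect_equal(select_model(sim$data)$model_id, m)
    }
  }
})

test_that("model nesting never increases the residual sum of squares", {
  set.seed(11)
  for (rep in 1:5) {
    sim <- gen_treg_experiment(treg_config(seed = rep, noise_sd = 2))
    r <- vapply(c("null", "1", "2", "3"), function(m)
      fit_mixture_model(sim$data, m)$rss, 0)
    expect_true(all(diff(r) <= 1e-8))
    expect_lte(fit_mixture_model(sim$data, 4)$rss, r[["2"]] + 1e-8)
  }
})

test_that("coefficient estimates are unbiased with the sampling variance the design implies", {
  # Analytic reference: for least squares on the fixed 10-diet design with
  # N = 8/diet and sigma = 1, sd(beta_j) = sqrt(diag((X'X)^-1)) and the
  # expected mean absolute error is sqrt(2/pi) * mean(sd).
  dd <- make_full_design(10, seed = 1)
  X <- build_design_matrix(dd[rep(1:10, each = 8), ], 1)
  sds <- sqrt(diag(solve(crossprod(X))))
  expected_mae <- sqrt(2 / pi) * mean(sds)
  est <- sapply(1:200, function(s) {
    sim <- gen_treg_experiment(treg_config(seed = s))
    fit_mixture_model(sim$data, 1)$coefficients
  })
  err <- est - c(2, 4, 12)
  expect_equal(mean(abs(err)), expected_mae, tolerance = 0.1)
  # unbiasedness: each coefficient's mean error within 3 MC standard errors
  for (j in 1:3)
    expect_lt(abs(mean(err[j, ])), 3 * sds[j] / sqrt(200))
})

test_that("predictions are the design-matrix dot product and respect nesting", {
  fit <- structure(list(model_id = "1",
                        coefficients = c(protein = 1, carb = 2, fat = 3),
                        term_names = c("protein", "carb", "fat"),
                        n_obs = 10, k = 3, rss = 1, aic = 0,
                        fitted = NULL, exact = FALSE),
                   class = "mixture_fit")
  expect_equal(predict_mixture(fit, data.frame(protein = 0.5, carb = 0.25,
                                               fat = 0.25)), 1.75)
  sim <- gen_treg_experiment(treg_config(seed = 2))
  f2 <- fit_mixture_model(sim$data, 2)
  expect_equal(predict(f2, sim$data), f2$fitted, tolerance = 1e-10)
  # a quadratic fit with zero pairwise terms predicts like the linear fit
  f2z <- f2
  f2z$coefficients[4:6] <- 0
  f1 <- f2
  f1$model_id <- "1"; f1$coefficients <- f2$coefficients[1:3]; f1$k <- 3
  nd <- make_full_design(6, seed = 9)
  expect_equal(predict(f2z, nd), predict(f1, nd), tolerance = 1e-12)
})
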