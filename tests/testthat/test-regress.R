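test_that("weighted_mlr recovers an exact line and matches the
           normal-equations oracle on random designs", {
  x <- 1:10
  f <- weighted_mlr(cbind(1, x), 2 + 3 * x, sd = rep(0.3, 10))
  expect_equal(unname(f$coefficients), c(2, 3), tolerance = 1e-10)

  set.seed(101)
  for (p in 2:5) {
    n <- 20 + p
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
    y <- rnorm(n)
    sdv <- runif(n, 0.02, 1)
    fit <- weighted_mlr(X, y, sdv)
    oracle <- wls_normal_equations(X, y, sdv)
    expect_equal(unname(fit$coefficients), unname(oracle$coefficients),
                 tolerance = 1e-8)
    expect_equal(unname(fit$se), unname(oracle$se), tolerance = 1e-8)
  }
})

test_that("inverse-variance weighting pulls the fit to precise points", {
  # two repeated measurements, SDs 0.1 and 10: closed-form weighted mean
  X <- cbind(c(1, 1, 1))
  y <- c(0, 5, 0.001)  # third point breaks n > p; tiny weight via big SD
  sdv <- c(0.1, 10, 10)
  fit <- weighted_mlr(X, y, sdv)
  w <- 1 / pmax(sdv, 0.05)^2
  expect_equal(unname(fit$coefficients), sum(w * y) / sum(w),
               tolerance = 1e-12)
  expect_lt(abs(fit$coefficients[[1]] - 0), 0.02)
})

test_that("rank deficiency is reported with the dependent columns", {
  x <- rnorm(20)
  X <- cbind(a = 1, b = x, c = 2 * x)
  expect_error(weighted_mlr(X, rnorm(20)), "rank deficient.*c")
  expect_error(weighted_mlr(cbind(1, 1:3, (1:3)^2), 1:3, rep(0.1, 3)),
               "more observations")
})

test_that("full-component PLS equals weighted MLR; collinearity is safe", {
  set.seed(7)
  n <- 80
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("v", 1:4)))
  y <- drop(X %*% c(1, -2, 0.5, 3)) + rnorm(n, 0, 0.4)
  sdv <- runif(n, 0.05, 0.8)

  pls <- pls_fit(X, y, sdv, n_components = 4)
  mlr <- weighted_mlr(cbind(1, X), y, sdv)
  expect_equal(unname(pls$coefficients), unname(mlr$coefficients),
               tolerance = 1e-8)

  # duplicated column: MLR is singular, PLS stays finite
  Xd <- cbind(X, v5 = X[, 1])
  expect_error(weighted_mlr(cbind(1, Xd), y), "rank deficient")
  plsd <- pls_fit(Xd, y, sdv, n_components = 5)
  expect_true(all(is.finite(plsd$fitted)))
})

test_that("one component suffices for a rank-one response", {
  set.seed(11)
  t <- rnorm(50)
  X <- outer(t, c(1, 2, -1))          # rank-1 design
  colnames(X) <- paste0("d", 1:3)
  fit <- pls_fit(X, 2 * t, n_components = 1)
  expect_equal(evaluate_predictions(2 * t, fit$fitted)$r2, 1,
               tolerance = 1e-10)
})

test_that("PLS1 fit agrees with an independent PLS implementation", {
  set.seed(3)
  n <- 60
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("x", 1:5)))
  y <- drop(X %*% c(1, -1, 0.5, 0, 2)) + rnorm(n, 0, 0.5)
  for (nc in c(1, 2, 3)) {
    ours <- pls_fit(X, y, n_components = nc)
    theirs <- mixOmics::pls(X, y, ncomp = nc, scale = FALSE,
                            mode = "regression")
    ref <- drop(predict(theirs, X)$predict[, , nc])
    expect_equal(unname(ours$fitted), unname(ref), tolerance = 1e-8)
  }
})

test_that("component selection is deterministic and in range", {
  set.seed(13)
  X <- matrix(rnorm(200 * 4), 200, 4)
  y <- drop(X %*% c(2, 0, 0, 0)) + rnorm(200, 0, 0.2)
  s1 <- choose_pls_components(X, y, seed = 42)
  s2 <- choose_pls_components(X, y, seed = 42)
  expect_identical(s1, s2)
  expect_true(s1$n_components >= 1 && s1$n_components <= 4)
  fit <- pls_fit(X, y, seed = 42)
  expect_equal(fit$pls_components, s1$n_components)
  expect_error(pls_fit(X, y, n_components = 9), "n_components")
})

test_that("the metric suite matches hand computation and its invariants", {
  obs <- c(0, 0, 0, 0)
  pred <- c(0.4, 0.6, 0.6, 0.6)
  m <- evaluate_predictions(obs, pred)
  expect_equal(m$mpp, 25)

  ident <- evaluate_predictions(c(-1, -2, -3), c(-1, -2, -3))
  expect_equal(ident$rmse, 0)
  expect_equal(ident$r2, 1)
  expect_equal(ident$mpp, 100)

  # permutation invariance and rmse >= |bias|
  set.seed(17)
  o <- rnorm(40); p <- o + rnorm(40)
  perm <- sample(40)
  m1 <- evaluate_predictions(o, p)
  m2 <- evaluate_predictions(o[perm], p[perm])
  expect_equal(m1, m2)
  expect_gte(m1$rmse, abs(m1$bias))

  # r2 floored at 0 when the model is worse than the mean
  bad <- evaluate_predictions(c(-1, 1, -1, 1), c(5, -5, 5, -5))
  expect_equal(bad$r2, 0)

  # F-statistic definition
  o2 <- c(1, 2, 3, 5, 4); p2 <- c(1.1, 1.8, 3.2, 4.6, 4.4)
  mf <- evaluate_predictions(o2, p2, n_params = 2)
  expect_equal(mf$f_stat,
               (5 - 2 - 1) / 2 * sum((o2 - mean(o2))^2) / sum((o2 - p2)^2))
  expect_equal(mf$sd, sqrt(mean((o2 - mean(o2))^2)))

  expect_error(evaluate_predictions(1:3, 1:4), "equal length")
})

test_that("metrics reports serialize to flat JSON", {
  m <- evaluate_predictions(c(1, 2), c(1.1, 2.2), n_params = 1)
  tmp <- tempfile(fileext = ".json")
  write_metrics(m, tmp)
  back <- jsonlite::read_json(tmp)
  expect_equal(back$n, 2)
  expect_equal(back$mpp, m$mpp)
})
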