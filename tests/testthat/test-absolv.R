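test_that("the ABSOLV preset reproduces the reference predictions", {
  p <- fixture_properties
  pred <- predict_absolv(p)
  expect_true(all(abs(pred - fixture_predictions$absolv) <= 0.05))
  expect_equal(pred[p$id == "cyclosporine-a"], -7.12, tolerance = 0.05)
})

test_that("over-determined inversion of the reference table pins the
           preset coefficients", {
  # 31 equations, 7 unknowns: least squares on the printed predictions
  p <- fixture_properties
  X <- with(p, cbind(1, A, B, S_pi, E, V, A * B))
  cf <- qr.solve(qr(X), fixture_predictions$absolv)
  expect_true(max(abs(drop(X %*% cf) - fixture_predictions$absolv)) <= 0.05)
  a <- absolv_2020()
  expect_equal(unname(cf),
               c(a$c0, a$c_a, a$c_b, a$c_s, a$c_e, a$c_v, a$c_ab),
               tolerance = 1e-8)
})

test_that("prediction is linear in each descriptor (superposition)", {
  co <- absolv_2020()
  base <- data.frame(A = 1, B = 2, S_pi = 3, E = 1.5, V = 2.5)
  f0 <- predict_absolv(base, co) - co$c0
  for (d in c("S_pi", "E", "V")) {   # descriptors without cross terms
    up <- base; up[[d]] <- base[[d]] * 2
    f1 <- predict_absolv(up, co) - co$c0
    single <- base; single[setdiff(names(base), d)] <- 0
    expect_equal(f1 - f0, predict_absolv(single, co) - co$c0,
                 tolerance = 1e-12)
  }
  zero <- data.frame(A = 0, B = 0, S_pi = 0, E = 0, V = 0)
  expect_equal(predict_absolv(zero, co), co$c0)
})

test_that("missing or incomplete descriptors raise named errors", {
  expect_error(predict_absolv(data.frame(A = 1, B = 2, E = 1, V = 1)),
               "S_pi")
  expect_error(predict_absolv(data.frame(A = 1, B = NA, S_pi = 1,
                                         E = 1, V = 1)), "B")
})

test_that("B^z uses the zero limit at B = 0", {
  co <- absolv_coefficients(0, 0, 0, 0, 0, 0, 0, c_bz = 2, z = 1.5)
  d <- data.frame(A = 0, B = c(0, 4), S_pi = 0, E = 0, V = 0)
  expect_equal(predict_absolv(d, co), c(0, 2 * 4^1.5))
  expect_error(absolv_coefficients(0, 0, 0, 0, 0, 0, 0, c_bz = 1),
               "together")
  expect_error(absolv_coefficients(0, 0, 0, 0, 0, 0, 0, c_bz = 1, z = -1),
               "z must be > 0")
})

test_that("fit_absolv recovers generating coefficients", {
  d0 <- generate_small_set(generator_config(80, seed = 6, model = "absolv",
                                            noise_sd = 0))
  f0 <- fit_absolv(d0)
  a <- absolv_2020()
  expect_equal(
    unlist(unclass(f0$coefficients)[c("c0", "c_a", "c_b", "c_s", "c_e",
                                      "c_v", "c_ab")]),
    c(c0 = a$c0, c_a = a$c_a, c_b = a$c_b, c_s = a$c_s, c_e = a$c_e,
      c_v = a$c_v, c_ab = a$c_ab),
    tolerance = 1e-7)

  dn <- generate_small_set(generator_config(2000, seed = 10,
                                            model = "absolv",
                                            noise_sd = 0.5))
  fn <- fit_absolv(dn)
  truth <- c(a$c0, a$c_a, a$c_b, a$c_s, a$c_e, a$c_v, a$c_ab)
  crit <- qt(0.975, fn$fit$df_residual)
  expect_true(all(abs(fn$fit$coefficients - truth) <= crit * fn$fit$se))
})

test_that("a degenerate descriptor column is flagged inestimable", {
  d <- generate_small_set(generator_config(40, seed = 2, model = "absolv"))
  d$A <- 0   # kills both the A and the A*B columns
  expect_error(fit_absolv(d), "rank deficient.*A")
  expect_error(fit_absolv(d[1:5, ]), "at least 9")
})

test_that("noiseless exponent scan lands exactly on the generating grid
           point", {
  d <- generate_bz_set(generator_config(120, seed = 15, model = "absolv_bz",
                                        z_true = 1.11, noise_sd = 0))
  zs <- z_scan(d, n_components = 7)
  expect_equal(zs$z_best, 1.11, tolerance = 1e-9)
  expect_equal(min(zs$table$rmse), 0, tolerance = 1e-8)
  expect_equal(nrow(zs$table), 111)
  expect_error(z_scan(d, z_grid = numeric(0)), "non-empty")
  d$B[1] <- 0
  expect_error(z_scan(d), "B > 0")
})

test_that("the rotatable-bond correction fits the flexibility line", {
  # two-point closed form
  two <- fit_nrot_correction(obs = c(1, 2), pred = c(0, 0),
                             nrot = c(0, 10))
  expect_equal(two$slope, 0.1, tolerance = 1e-12)
  expect_equal(two$intercept, 1, tolerance = 1e-12)

  # zero residuals give the null line
  null <- fit_nrot_correction(obs = c(-1, -2, -3), pred = c(-1, -2, -3),
                              nrot = c(1, 5, 9))
  expect_equal(null$slope, 0, tolerance = 1e-12)
  expect_equal(null$intercept, 0, tolerance = 1e-12)

  expect_error(fit_nrot_correction(1:4, 1:4, rep(2, 4)), "singular")
  expect_error(fit_nrot_correction(1, 1, 1), "at least 2")
})

test_that("on the big set the correction removes the ABSOLV bias", {
  p <- fixture_properties
  pred <- predict_absolv(p)
  corr <- fit_nrot_correction(p$log_s0, pred, p$nrot)
  expect_equal(corr$slope, 0.13, tolerance = 0.02)
  expect_equal(corr$intercept, 0.75, tolerance = 0.05)
  expect_equal(corr$r2, 0.44, tolerance = 0.02)

  fixed <- apply_nrot_correction(corr, pred, p$nrot)
  before <- evaluate_predictions(p$log_s0, pred)
  after <- evaluate_predictions(p$log_s0, fixed)
  expect_lt(after$rmse, before$rmse)
  expect_lt(abs(after$bias), 0.2)
})
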