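test_that("single-component PLS recovers a noiseless rank-one response", {
  # all predictors proportional to one latent factor: A = 1 is exact
  withr::with_seed(1, z <- rnorm(15))
  X <- outer(z, c(1, -2, 0.5, 3))
  colnames(X) <- paste0("x", 1:4)
  y <- 2 * z
  m <- fit_pls(X, ncomp = 1, y = y)
  expect_equal(r_squared(y, predict(m, X)), 1, tolerance = 1e-9)
  # with noise predictors present, one component still captures nearly
  # everything when the signal dominates
  withr::with_seed(2, Xn <- cbind(X, e1 = rnorm(15, sd = 0.01)))
  mn <- fit_pls(Xn, ncomp = 1, y = y)
  expect_gt(r_squared(y, predict(mn, Xn)), 0.99)
})

test_that("full-order PLS equals the least-squares oracle", {
  for (seed in c(4, 8, 15)) {
    d <- make_linear_data(n = 14, p = 5, sigma = 0.5, seed = seed)
    m <- fit_pls(d$X, ncomp = 5, y = d$y)
    expect_equal(unname(predict(m, d$X)), ols_predict(d$X, d$y),
                 tolerance = 1e-8)
  }
})

test_that("NIPALS predictions agree with an independent SIMPLS oracle", {
  d <- make_linear_data(n = 16, p = 6, sigma = 0.4, seed = 99)
  for (a in 1:4) {
    m <- fit_pls(d$X, ncomp = a, y = d$y)
    expect_equal(unname(predict(m, d$X)),
                 unname(simpls1_predict(d$X, d$y, a)), tolerance = 1e-8)
  }
})

test_that("prediction honours centering, scaling and input contracts", {
  d <- make_linear_data(seed = 21)
  m <- fit_pls(d$X, ncomp = 2, y = d$y)
  # at the feature centroid the prediction is the response mean
  expect_equal(unname(predict(m, colMeans(d$X))), mean(d$y),
               tolerance = 1e-10)
  # scale equivariance: autoscaling absorbs positive column rescaling
  X2 <- d$X; X2[, 2] <- X2[, 2] * 40
  m2 <- fit_pls(X2, ncomp = 2, y = d$y)
  expect_equal(unname(predict(m2, X2)), unname(predict(m, d$X)),
               tolerance = 1e-9)
  expect_error(predict(m, c(1, 2)), "length")
  expect_error(fit_pls(d$X, ncomp = 99, y = d$y), "ncomp")
})

test_that("constant feature columns are dropped with a note", {
  d <- make_linear_data(seed = 31)
  Xc <- cbind(d$X, konst = 5)
  expect_message(m <- fit_pls(Xc, ncomp = 2, y = d$y), "konst")
  expect_equal(unname(m$coefficients["konst"]), 0)
  expect_error(fit_pls(matrix(1, 6, 2), ncomp = 1, y = 1:6), "constant")
})

test_that("r_squared matches hand arithmetic", {
  expect_equal(r_squared(c(0, 1, 2), c(0, 1, 2)), 1)
  expect_equal(r_squared(c(0, 1, 2), rep(1, 3)), 0)
  expect_equal(r_squared(c(0, 1, 2), c(0, 1, 3)), 0.5)
  expect_error(r_squared(c(1, 1), c(1, 2)), "constant")
})

test_that("leave-one-out CV matches a brute-force re-fit oracle", {
  d <- make_linear_data(n = 9, p = 4, sigma = 0.3, seed = 77)
  cv <- loo_cv(d$X, a_max = 3, y = d$y)
  for (a in 1:3)
    expect_equal(cv$r2_val[a], loo_brute_r2val(d$X, d$y, a),
                 tolerance = 1e-9)
  expect_error(loo_cv(d$X, a_max = 8, y = d$y), "a_max")
})

test_that("noiseless rank-one data validate perfectly at one component", {
  withr::with_seed(6, z <- rnorm(10))
  X <- outer(z, c(2, -1, 0.5, 1))
  colnames(X) <- paste0("x", 1:4)
  cv <- loo_cv(X, a_max = 2, y = 3 * z)
  expect_equal(cv$r2_val[1], 1, tolerance = 1e-9)
})

test_that("calibration R-squared is monotone non-decreasing in A", {
  for (seed in c(2, 12, 22)) {
    d <- make_linear_data(n = 15, p = 6, sigma = 1, seed = seed)
    cv <- loo_cv(d$X, a_max = 5, y = d$y)
    expect_true(all(diff(cv$r2_cal) >= -1e-10))
    expect_true(all(cv$r2_cal <= 1 + 1e-12 & cv$r2_val <= 1 + 1e-12))
  }
})

test_that("component selection maximizes validation R2, ties to fewer", {
  mk <- function(v) structure(data.frame(ncomp = seq_along(v),
                                         r2_cal = v, r2_val = v),
                              class = c("pls_cv", "data.frame"))
  expect_equal(select_components(mk(c(0.90, 0.95, 0.93))), 2L)
  expect_equal(select_components(mk(c(0.95, 0.95))), 1L)
  expect_error(select_components(data.frame()), "non-empty")
})

test_that("prediction RMSE approaches the noise floor as replicates grow", {
  sig <- 0.3
  rmse <- sapply(c(20, 200), function(n) {
    d <- make_linear_data(n = n, p = 4, sigma = sig, seed = 101)
    m <- fit_pls(d$X, ncomp = 4, y = d$y)
    sqrt(mean((predict(m, d$X) - drop(d$X %*% d$beta))^2))
  })
  expect_lt(rmse[2], rmse[1])
  expect_lt(rmse[2], sig / 2)
})

test_that("working-range scan keeps linear spans and finds plateaus", {
  withr::with_seed(55, {
    lv <- rep(c(2, 5, 10, 15, 20, 25, 30), each = 3)
    X <- cbind(a = 200 - 2.5 * lv + rnorm(21, 0, 0.5),
               b = 150 - 1.5 * lv + rnorm(21, 0, 0.5),
               c = rnorm(21))
    cs_lin <- calibration_set(as_channels8(X), lv)
    scan_lin <- working_range_scan(cs_lin, c(15, 20, 30))
    expect_equal(scan_lin$best_upper, 30)
    expect_equal(scan_lin$best_model$range[2], 30)

    # response saturates above 15 mg/L: the chosen bound must not exceed it
    sat <- pmin(lv, 15)
    Xs <- cbind(a = 200 - 2.5 * sat + rnorm(21, 0, 0.3),
                b = 150 - 1.5 * sat + rnorm(21, 0, 0.3),
                c = rnorm(21))
    scan_sat <- working_range_scan(calibration_set(as_channels8(Xs), lv),
                                   c(10, 15, 20, 25, 30))
    expect_lte(scan_sat$best_upper, 15)
  })
  expect_error(
    suppressWarnings(working_range_scan(
      calibration_set(as_channels8(matrix(rnorm(12), 4, 3)),
                      rep(c(1, 2), each = 2)), 2)),
    "3 concentration levels")
})

test_that("models survive a JSON save/load round trip bit-for-bit", {
  d <- make_linear_data(n = 12, p = 4, sigma = 0.2, seed = 61)
  m <- fit_pls(d$X, ncomp = 3, y = d$y)
  p <- tempfile(fileext = ".json")
  save_pls(m, p)
  m2 <- load_pls(p)
  expect_identical(predict(m, d$X), predict(m2, d$X))
  expect_identical(m2$ncomp, m$ncomp)
  expect_identical(m2$range, m$range)
})

test_that("hue sentinel is resolved explicitly at feature assembly", {
  ch <- expand_channels(rbind(c(100, 100, 100), c(200, 50, 10)))
  expect_warning(expect_warning(X <- as_feature_matrix(ch), "0 degrees"),
                 "mixes")
  expect_equal(unname(X[1, "H"]), 0)
})
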