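test_that("identical specs give bit-identical reconstructions", {
  s1 <- reconstruct_replicates(synthetic_spec(seed = 123))
  s2 <- reconstruct_replicates(synthetic_spec(seed = 123))
  s3 <- reconstruct_replicates(synthetic_spec(seed = 124))
  expect_identical(s1$X, s2$X)
  expect_false(identical(s1$X, s3$X))
  expect_equal(dim(s1$X), c(21, 8))  # 7 levels x 3 replicates
})

test_that("zero noise reproduces the knot means with consistent channels", {
  std <- tartrazine_channels("standards")
  nz <- data.frame(concentration = std$concentration,
                   R_sd = 0, G_sd = 0, B_sd = 0)
  cs <- reconstruct_replicates(synthetic_spec(noise = nz, seed = 1))
  row30 <- cs$X[cs$y == 30, ][1, ]
  expect_equal(unname(row30[c("R", "G", "B")]), c(181.0, 125.0, 1.7))
  expect_equal(unname(row30["I"]), (181 + 125 + 1.7) / 3, tolerance = 1e-12)
  # every replicate at a level is identical
  expect_equal(cs$X[cs$y == 10, ][1, ], cs$X[cs$y == 10, ][3, ])
})

test_that("consistent mode preserves the channel-vector identities", {
  cs <- reconstruct_replicates(synthetic_spec(seed = 42))
  expect_equal(cs$X[, "I"], unname(rowMeans(cs$X[, c("R", "G", "B")])),
               tolerance = 1e-9)
  expect_true(all(cs$X[, "V"] >= cs$X[, "L"]))
  ind <- reconstruct_replicates(synthetic_spec(seed = 42),
                                mode = "independent")
  expect_identical(attr(ind, "mode"), "independent")
  # independent draws break the intensity identity (that is their point)
  expect_gt(max(abs(ind$X[, "I"] - rowMeans(ind$X[, c("R", "G", "B")]))),
            0.1)
})

test_that("generator moments match their parameters within 3 SE", {
  n <- 1e4
  spec <- synthetic_spec(grid = c(5, 30), replicates = n, seed = 77)
  cs <- reconstruct_replicates(spec)
  std <- tartrazine_channels("standards")
  for (lv in c(5, 30)) {
    mu <- unlist(std[std$concentration == lv, c("R", "G", "B")])
    sg <- unlist(std[std$concentration == lv, c("R_sd", "G_sd", "B_sd")])
    Xl <- cs$X[cs$y == lv, ]
    for (k in 1:3) {
      expect_lt(abs(mean(Xl[, k]) - mu[k]), 3 * sg[k] / sqrt(n) + 1e-3)
      expect_lt(abs(sd(Xl[, k]) - sg[k]), 3 * sg[k] / sqrt(2 * n) + 1e-3)
    }
  }
  expect_error(reconstruct_replicates(synthetic_spec(grid = 7, seed = 1)),
               "7")
})

test_that("the response model interpolates linearly inside its span", {
  rm_ <- response_model()
  expect_equal(unname(response_rgb(rm_, 30)), c(181.0, 125.0, 1.7))
  mid <- response_rgb(rm_, 27.5)
  expect_equal(unname(mid), c((186 + 181) / 2, (130 + 125) / 2,
                              (1.3 + 1.7) / 2))
  expect_error(response_rgb(rm_, 2), "outside the response span")
  # R and G decrease with concentration over the default knots
  grid <- seq(5, 30, by = 0.5)
  rg <- sapply(grid, function(cc) response_rgb(rm_, cc)[1:2])
  expect_true(all(diff(rg[1, ]) <= 0))
  expect_true(all(diff(rg[2, ]) <= 0))
  # explicit lower extension makes low concentrations renderable
  rml <- response_model(extend_lower = 0)
  expect_equal(min(rml$knots$concentration), 0)
  expect_silent(response_rgb(rml, 4))
})

test_that("rendered patches hit the target color", {
  spec0 <- synthetic_spec(pixel_noise_sd = 0, quantize = TRUE, seed = 5)
  img <- render_patch(30, spec = spec0)
  blk <- extract_roi(img, roi_spec(side = 16))
  expect_true(all(blk[, , 1] == 181 & blk[, , 2] == 125 & blk[, , 3] == 2))

  spec1 <- synthetic_spec(pixel_noise_sd = 2, seed = 6)
  m <- roi_mean_rgb(extract_roi(render_patch(10, spec = spec1)))$mean
  expect_equal(unname(m), c(206.5, 151.8, 1.9), tolerance = 0.5)

  expect_error(render_patch(50, spec = spec1), "outside the response span")
})

test_that("the illumination gradient tilts columns, not rows", {
  spec <- synthetic_spec(pixel_noise_sd = 0, gradient = 40, seed = 9)
  px <- render_patch(15, spec = spec)$pixels
  expect_gt(mean(px[, 64, 1]) - mean(px[, 1, 1]), 30)     # across columns
  expect_lt(abs(mean(px[64, , 1]) - mean(px[1, , 1])), 1) # flat across rows
})

test_that("simulated repeatability is deterministic and noise-scaled", {
  train <- reconstruct_replicates(
    synthetic_spec(grid = c(5, 10, 15, 20), seed = 31))
  m <- fit_pls(train, ncomp = 3)
  spec0 <- synthetic_spec(pixel_noise_sd = 0, seed = 11)
  found0 <- simulate_repeatability(15, 5, m, spec = spec0)
  expect_equal(length(unique(round(found0, 10))), 1)

  spec_lo <- synthetic_spec(pixel_noise_sd = 1, seed = 11)
  spec_hi <- synthetic_spec(pixel_noise_sd = 4, seed = 11)
  sd_lo <- sd(simulate_repeatability(15, 20, m, spec = spec_lo))
  sd_hi <- sd(simulate_repeatability(15, 20, m, spec = spec_hi))
  expect_equal(sd_hi / sd_lo, 4, tolerance = 1.5)
  # identical seeds give identical experiments
  expect_identical(simulate_repeatability(8, 5, m, spec = spec_lo),
                   simulate_repeatability(8, 5, m, spec = spec_lo))
})

test_that("the rendered pipeline closes the loop on concentration", {
  # train on rendered standards, then recover an off-grid concentration
  spec <- synthetic_spec(pixel_noise_sd = 1, seed = 21)
  rm_ <- response_model()
  levels <- c(5, 10, 15, 20)
  rows <- list()
  k <- 0
  for (cc in levels) for (r in 1:3) {
    k <- k + 1
    img <- render_patch(cc, rm_, spec, seed = spec$seed + k)
    rgb <- roi_mean_rgb(extract_roi(img))$mean
    rows[[k]] <- cbind(concentration = cc, expand_channels(rgb))
  }
  tab <- do.call(rbind, rows)
  cs <- calibration_set(tab, tab$concentration)
  m <- fit_pls(cs, ncomp = select_components(loo_cv(cs, a_max = 4)))
  found <- simulate_repeatability(12, 10, m, rm_,
                                  synthetic_spec(pixel_noise_sd = 1,
                                                 seed = 99))
  sigma <- max(sd(found), 0.05)
  expect_lt(abs(mean(found) - 12), 3 * sigma + 0.3)
})
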