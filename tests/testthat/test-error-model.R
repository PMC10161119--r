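random_features <- function(n, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    target_x_mm = runif(n, -60, 60), target_y_mm = runif(n, -60, 60),
    target_mu = runif(n, 0.5, 2),
    gantry_angle_deg = sample(c(0, 90, 180, 270), n, replace = TRUE),
    snout_extension_mm = runif(n, 100, 250),
    nominal_energy_MeV = runif(n, 70, 160)))
}

test_that("dataset splitting honours the 70/15/15 convention", {
  cfg <- train_config(seed = 5)
  s <- split_dataset(1000, cfg)
  expect_length(s$train, 700)
  expect_length(s$val, 150)
  expect_length(s$test, 150)
  expect_identical(sort(c(s$train, s$val, s$test)), 1:1000)
  expect_length(intersect(s$train, s$val), 0)
  expect_length(intersect(s$train, s$test), 0)
  s2 <- split_dataset(1000, cfg)
  expect_identical(s, s2)
  expect_error(split_dataset(5, cfg), "at least 10")
  expect_error(train_config(fractions = c(0.5, 0.2, 0.2)), "sum")
})

test_that("dataset assembly excludes zero-MU spots and aligns beam headers", {
  ph <- tiny_phantom()
  plan <- tiny_plan(ph)
  logs <- generate_log_files(plan, error_truth(), 2, seed = 2)
  # zero out one spot's MUs in beam 1
  sid <- logs[[1]]$pulses$spot_index[1]
  logs[[1]]$pulses$actual_MU[logs[[1]]$pulses$spot_index == sid] <- 0
  ds <- assemble_dataset(logs)
  expect_equal(ds$n_excluded, 1)
  expect_equal(nrow(ds$features), n_spots(plan) - 1)
  expect_named(ds$features, c("target_x_mm", "target_y_mm", "target_mu",
                              "gantry_angle_deg", "snout_extension_mm",
                              "nominal_energy_MeV"))
  for (b in unique(ds$index$beam_id)) {
    expect_length(unique(ds$features$gantry_angle_deg[ds$index$beam_id == b]), 1)
  }
})

test_that("a noiseless recoverable mapping is fit almost perfectly", {
  f <- random_features(2000)
  targ <- tibble::tibble(delivered_x_mm = f$target_x_mm + 1,
                         delivered_y_mm = f$target_y_mm - 0.5,
                         delivered_mu = f$target_mu)
  # deep convergence: the affine map lives in the small-weight limit of the
  # tanh layer, so the optimizer needs room to travel there
  m <- train_error_model(f, targ,
                         train_config(seed = 3, max_epochs = 2000,
                                      patience = 2000))
  expect_gte(m$metrics$r_squared_std, 0.9999)
  pred <- suppressWarnings(predict(m, f[m$split$test, ]))
  expect_lt(max(abs(pred$delivered_x_mm - targ$delivered_x_mm[m$split$test])),
            0.01)
  expect_lt(max(abs(pred$delivered_y_mm - targ$delivered_y_mm[m$split$test])),
            0.01)
})

test_that("pure-noise targets give a test R-squared near zero", {
  f <- random_features(10000, seed = 8)
  targ <- withr::with_seed(9, tibble::tibble(
    delivered_x_mm = rnorm(10000), delivered_y_mm = rnorm(10000),
    delivered_mu = rnorm(10000)))
  m <- train_error_model(f, targ, train_config(seed = 10, max_epochs = 60))
  expect_lt(abs(m$metrics$r_squared_std), 0.05)
})

test_that("the quasi-Newton fallback also recovers a clean mapping", {
  f <- random_features(1500, seed = 11)
  targ <- tibble::tibble(delivered_x_mm = f$target_x_mm + 0.7,
                         delivered_y_mm = f$target_y_mm,
                         delivered_mu = f$target_mu * 1.01)
  m <- train_error_model(f, targ,
                         train_config(seed = 12, optimizer = "quasi_newton",
                                      max_epochs = 400))
  expect_gte(m$metrics$r_squared_std, 0.999)
})

test_that("metrics are invariant to feature column order", {
  f <- random_features(1200, seed = 13)
  targ <- tibble::tibble(delivered_x_mm = f$target_x_mm + 0.4,
                         delivered_y_mm = f$target_y_mm - 0.1,
                         delivered_mu = f$target_mu)
  m1 <- train_error_model(f, targ, train_config(seed = 14))
  m2 <- train_error_model(f[rev(names(f))], targ, train_config(seed = 14))
  expect_identical(m1$metrics$mse_std, m2$metrics$mse_std)
})

test_that("plan prediction is order-preserving and deterministic", {
  ph <- tiny_phantom()
  plan <- tiny_plan(ph)
  logs <- generate_log_files(plan, error_truth(), 2, seed = 20)
  ds <- assemble_dataset(logs)
  m <- train_error_model(ds$features, ds$targets,
                         train_config(seed = 21, max_epochs = 60))
  p1 <- predict_plan(m, plan)
  p2 <- predict_plan(m, plan)
  expect_identical(p1, p2)
  expect_equal(p1$spot_id, plan$spots$spot_id)
  # feature mismatch errors; extrapolation only warns
  expect_error(predict(m, ds$features[, -1]), "lacks feature")
  far <- ds$features[1, ]
  far$target_x_mm <- 1e4
  expect_warning(predict(m, far), "extrapolating")
})

test_that("a serialized model reloads to bit-identical predictions", {
  f <- random_features(800, seed = 30)
  targ <- tibble::tibble(delivered_x_mm = f$target_x_mm + 0.2,
                         delivered_y_mm = f$target_y_mm,
                         delivered_mu = f$target_mu)
  m <- train_error_model(f, targ, train_config(seed = 31, max_epochs = 40))
  path <- withr::local_tempfile(fileext = ".json")
  save_error_model(m, path)
  m2 <- load_error_model(path)
  newf <- f[1:200, ]
  expect_identical(as.data.frame(suppressWarnings(predict(m, newf))),
                   as.data.frame(suppressWarnings(predict(m2, newf))))
})

test_that("tidy() and glance() expose the network coefficients and fit", {
  f <- random_features(600, seed = 40)
  targ <- tibble::tibble(delivered_x_mm = f$target_x_mm,
                         delivered_y_mm = f$target_y_mm,
                         delivered_mu = f$target_mu)
  m <- train_error_model(f, targ, train_config(seed = 41, max_epochs = 30))
  td <- tidy(m)
  expect_equal(nrow(td), 5 * 6 + 5 + 3 * 5 + 3)   # 53 parameters
  gl <- glance(m)
  expect_equal(gl$hidden_neurons, 5L)
  expect_equal(gl$n_train + gl$n_val + gl$n_test, 600)
})

test_that("constant systematic offsets are recovered within sampling error", {
  ph <- tiny_phantom()
  plan <- generate_plan(ph, plan_spec(
    gantry_angles_deg = c(0, 120, 240), spot_spacing_mm = 5,
    layer_spacing_mm = 5, depth_margin_mm = 8, aperture_margin_mm = 12,
    optimize_weights = FALSE), seed = 50)
  truth <- error_truth(systematic_x_mm = 0.6, systematic_y_mm = -0.4,
                       random_sigma_x_mm = 0.3, random_sigma_y_mm = 0.3,
                       mu_noise_frac = 0.01)
  logs <- generate_log_files(plan, truth, 2, seed = 51)
  ds <- assemble_dataset(logs)
  m <- train_error_model(ds$features, ds$targets, train_config(seed = 52))
  idx <- m$split$test
  pred <- predict(m, ds$features[idx, ])
  errx <- pred$delivered_x_mm - ds$features$target_x_mm[idx]
  erry <- pred$delivered_y_mm - ds$features$target_y_mm[idx]
  tol <- 3 * 0.3 / sqrt(length(idx)) + 0.05   # 3 SE plus fit slack
  expect_lt(abs(mean(errx) - 0.6), tol)
  expect_lt(abs(mean(erry) + 0.4), tol)
  # residual SD reflects the generator's random sigma
  resx <- pred$delivered_x_mm - ds$targets$delivered_x_mm[idx]
  expect_lt(abs(sd(resx) - 0.3) / 0.3, 0.10)
})

test_that("an independent single-hidden-layer fit agrees on the recovered offset", {
  skip_if_not_installed("nnet")
  f <- random_features(3000, seed = 60)
  targ <- tibble::tibble(
    delivered_x_mm = f$target_x_mm + 0.8 +
      withr::with_seed(61, rnorm(3000, 0, 0.3)),
    delivered_y_mm = f$target_y_mm,
    delivered_mu = f$target_mu)
  m <- train_error_model(f, targ, train_config(seed = 62))
  ours <- mean(suppressWarnings(predict(m, f))$delivered_x_mm - f$target_x_mm)
  X <- scale(as.matrix(f))
  y <- scale(targ$delivered_x_mm)
  fit <- withr::with_seed(63,
    nnet::nnet(X, y, size = 5, linout = TRUE, trace = FALSE,
               maxit = 300, decay = 1e-4))
  theirs <- mean(predict(fit, X) * attr(y, "scaled:scale") +
                   attr(y, "scaled:center") - f$target_x_mm)
  expect_lt(abs(ours - 0.8), 0.05)
  expect_lt(abs(theirs - 0.8), 0.1)
})
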