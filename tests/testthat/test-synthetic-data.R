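test_that("phantom rasterization reproduces analytic structure volumes", {
  ph <- generate_phantom(phantom_spec(
    dim_vox = c(50, 50, 50), spacing_mm = c(2, 2, 2),
    structures = list(struct_sphere("CTV", c(0, 0, 0), 20))))
  analytic_cc <- 4 / 3 * pi * 2^3   # 20 mm radius in cc
  got <- ph$volumes$volume_cc[ph$volumes$structure == "CTV"]
  expect_lt(abs(got - analytic_cc) / analytic_cc, 0.01)
  # box volume is exact up to voxel-centre inclusion at the faces
  # odd grid: voxel centres fall on even mm, faces included -> 11^3 voxels
  ph2 <- generate_phantom(phantom_spec(
    dim_vox = c(41, 41, 41), spacing_mm = c(2, 2, 2),
    structures = list(struct_box("B", c(0, 0, 0), c(10, 10, 10)))))
  expect_equal(ph2$volumes$volume_cc, (22 / 10)^3, tolerance = 1e-9)
})

test_that("phantom generation is deterministic and validates structures", {
  spec <- phantom_spec(dim_vox = c(20, 20, 20), spacing_mm = c(2, 2, 2),
                       structures = list(struct_sphere("CTV", c(0, 0, 0), 8)))
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$masks, b$masks)
  expect_identical(a$rsp, b$rsp)
  # structure escaping the grid is rejected by name
  expect_error(generate_phantom(phantom_spec(
    dim_vox = c(20, 20, 20), spacing_mm = c(2, 2, 2),
    structures = list(struct_sphere("huge", c(0, 0, 0), 50)))),
    "huge")
  # empty structure list: grid fine, later CTV lookup errors
  ph0 <- generate_phantom(phantom_spec(dim_vox = c(10, 10, 10)))
  expect_length(ph0$masks, 0)
  expect_error(generate_plan(ph0, plan_spec()), "CTV")
})

test_that("plan presets emit the configured beam counts", {
  ph <- tiny_phantom()
  p2 <- generate_plan(ph, plan_spec(preset = "apbi", spot_spacing_mm = 8,
                                    layer_spacing_mm = 8))
  expect_equal(nrow(p2$beams), 2)
  p6 <- generate_plan(ph, plan_spec(preset = "ependymoma", spot_spacing_mm = 8,
                                    layer_spacing_mm = 8))
  expect_equal(nrow(p6$beams), 6)
  expect_equal(p6$prescription_cGy, 5040)
})

test_that("a lattice wider than the target still emits a centre spot per layer", {
  ph <- tiny_phantom()
  plan <- generate_plan(ph, plan_spec(spot_spacing_mm = 500,
                                      layer_spacing_mm = 8,
                                      aperture_margin_mm = 2,
                                      optimize_weights = FALSE))
  counts <- table(paste(plan$spots$beam_id, plan$spots$layer))
  expect_true(all(counts >= 1))
})

test_that("every generated spot centroid lies inside its aperture", {
  ph <- tiny_phantom()
  for (mode in c("static", "per_layer")) {
    plan <- generate_plan(ph, plan_spec(
      gantry_angles_deg = c(40, 200), spot_spacing_mm = 7,
      layer_spacing_mm = 6, aperture_margin_mm = 8, aperture_mode = mode,
      optimize_weights = FALSE))
    flt <- aperture_filter(plan$spots[plan$spots$beam_id == 1 &
                                        plan$spots$layer == 1, ],
                           plan$apertures[[1]]$polygons[[1]])
    expect_equal(nrow(flt$deleted), 0)
  }
})

test_that("log generation honours the injected error truth exactly in degenerate cases", {
  ph <- tiny_phantom()
  plan <- tiny_plan(ph)
  # all-zero truth: delivered identical to planned
  t0 <- error_truth(0, 0, 0, 0, mu_noise_frac = 0, pulse_jitter_sigma_mm = 0)
  logs <- generate_log_files(plan, t0, pulses_per_spot = 2, seed = 7)
  sp <- aggregate_pulses(logs[[1]])
  expect_equal(sp$delivered_x_mm, sp$planned_x_mm, tolerance = 1e-12)
  expect_equal(sp$delivered_y_mm, sp$planned_y_mm, tolerance = 1e-12)
  expect_equal(sp$delivered_mu, sp$planned_mu, tolerance = 1e-12)
  # pure systematic offset survives aggregation exactly (jitter recentred)
  t1 <- error_truth(systematic_x_mm = 1, random_sigma_x_mm = 0,
                    random_sigma_y_mm = 0, mu_noise_frac = 0,
                    pulse_jitter_sigma_mm = 0.4)
  sp1 <- aggregate_pulses(generate_log_files(plan, t1, 3, seed = 8)[[1]])
  expect_equal(sp1$delivered_x_mm - sp1$planned_x_mm,
               rep(1, nrow(sp1)), tolerance = 1e-9)
})

test_that("gantry/energy-dependent systematic terms are resolved per beam", {
  ph <- tiny_phantom()
  plan <- tiny_plan(ph)
  tr <- error_truth(
    systematic_x_mm = function(g, e) ifelse(g > 180, 1, -1),
    random_sigma_x_mm = 0, random_sigma_y_mm = 0,
    mu_noise_frac = 0, pulse_jitter_sigma_mm = 0)
  logs <- generate_log_files(plan, tr, 1, seed = 1)
  s1 <- aggregate_pulses(logs[[1]])  # gantry 350
  s2 <- aggregate_pulses(logs[[2]])  # gantry 10
  expect_equal(unique(round(s1$delivered_x_mm - s1$planned_x_mm, 9)), 1)
  expect_equal(unique(round(s2$delivered_x_mm - s2$planned_x_mm, 9)), -1)
})

test_that("generated error distribution matches the truth over many spots", {
  ph <- robustness_phantom()
  plan <- generate_plan(ph, plan_spec(
    gantry_angles_deg = seq(0, 315, by = 45),
    spot_spacing_mm = 4, layer_spacing_mm = 5, depth_margin_mm = 10,
    aperture_margin_mm = 14, optimize_weights = FALSE), seed = 2)
  n <- n_spots(plan)
  expect_gt(n, 1e4)
  truth <- error_truth(systematic_x_mm = 0.4, systematic_y_mm = -0.2,
                       random_sigma_x_mm = 0.5, random_sigma_y_mm = 0.3,
                       mu_noise_frac = 0.02, pulse_jitter_sigma_mm = 0.2)
  logs <- generate_log_files(plan, truth, pulses_per_spot = 2, seed = 11)
  sp <- dplyr::bind_rows(lapply(logs, aggregate_pulses))
  ex <- sp$delivered_x_mm - sp$planned_x_mm
  ey <- sp$delivered_y_mm - sp$planned_y_mm
  m <- nrow(sp)
  # means within 3 standard errors, SDs within 3 SE of an SD estimate
  expect_lt(abs(mean(ex) - 0.4), 3 * 0.5 / sqrt(m))
  expect_lt(abs(mean(ey) + 0.2), 3 * 0.3 / sqrt(m))
  expect_lt(abs(sd(ex) - 0.5), 3 * 0.5 / sqrt(2 * m))
  expect_lt(abs(sd(ey) - 0.3), 3 * 0.3 / sqrt(2 * m))
  rel_mu <- sp$delivered_mu / sp$planned_mu - 1
  expect_lt(abs(sd(rel_mu) - 0.02), 3 * 0.02 / sqrt(2 * m))
})

test_that("pulse MU conservation and seed determinism hold", {
  ph <- tiny_phantom()
  plan <- tiny_plan(ph)
  truth <- error_truth()
  logs <- generate_log_files(plan, truth, pulses_per_spot = 4, seed = 5)
  p <- logs[[1]]$pulses
  sums <- tapply(p$actual_MU, p$spot_index, sum)
  sp <- aggregate_pulses(logs[[1]])
  expect_equal(as.numeric(sums[as.character(sp$spot_index)]),
               sp$delivered_mu, tolerance = 1e-9)
  logs2 <- generate_log_files(plan, truth, pulses_per_spot = 4, seed = 5)
  expect_identical(logs[[1]]$pulses, logs2[[1]]$pulses)
  logs3 <- generate_log_files(plan, truth, pulses_per_spot = 4, seed = 6)
  expect_false(identical(logs[[1]]$pulses, logs3[[1]]$pulses))
})

test_that("QA grid has the stated pattern, quantization and degenerate limits", {
  truth0 <- error_truth(0, 0, 0, 0, mu_noise_frac = 0,
                        pulse_jitter_sigma_mm = 0)
  qa <- generate_qa_grid(0, truth0, detector_noise_sigma_mm = 0, seed = 3)
  expect_equal(nrow(qa), 121)
  expect_equal(qa$recorded_x_mm, qa$measured_x_mm)
  expect_equal(qa$recorded_y_mm - qa$measured_y_mm, rep(0, 121))
  qa2 <- generate_qa_grid(90, error_truth(), detector_resolution_mm = 0.5,
                          seed = 4)
  expect_true(all(abs(qa2$measured_x_mm / 0.5 -
                        round(qa2$measured_x_mm / 0.5)) < 1e-9))
  expect_true(all(abs(qa2$measured_y_mm / 0.5 -
                        round(qa2$measured_y_mm / 0.5)) < 1e-9))
  expect_error(generate_qa_grid(0, error_truth(), n_side = 10), "odd|%%")
})
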