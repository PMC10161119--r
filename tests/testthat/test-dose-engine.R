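square10 <- cbind(c(-10, 10, 10, -10), c(-10, -10, 10, 10))

test_that("point-in-polygon is boundary-inclusive and agrees with mgcv inside/outside", {
  expect_true(point_in_polygon(c(0, 0), square10))
  expect_false(point_in_polygon(c(10.5, 0), square10))
  expect_true(point_in_polygon(c(10, 0), square10))     # on an edge
  expect_true(point_in_polygon(c(10, 10), square10))    # on a vertex
  expect_error(point_in_polygon(c(0, 0), square10[1:2, ]), "degenerate")

  skip_if_not_installed("mgcv")
  set.seed(5)
  pts <- cbind(runif(400, -15, 15), runif(400, -15, 15))
  clear <- abs(abs(pts[, 1]) - 10) > 1e-3 & abs(abs(pts[, 2]) - 10) > 1e-3
  pts <- pts[clear, ]
  ours <- point_in_polygon(pts, square10)
  theirs <- mgcv::in.out(rbind(square10, square10[1, ]), pts)
  expect_equal(ours, as.logical(theirs))
})

test_that("aperture filtering keeps inside and boundary spots with their MU", {
  spots <- tibble::tibble(x_mm = c(0, 10.5, 10), y_mm = c(0, 0, 0),
                          mu = c(1, 2, 3))
  flt <- aperture_filter(spots, square10)
  expect_equal(flt$kept$mu, c(1, 3))
  expect_equal(flt$deleted$mu, 2)
})

test_that("range, spot size and peak depth behave monotonically", {
  opt <- spot_optics()
  e <- c(70, 100, 150, 200)
  expect_true(all(diff(proton_range_mm(opt, e)) > 0))
  expect_true(all(diff(sigma_air_mm(opt, e)) < 0))
  expect_equal(sigma_air_mm(opt, 150), 10)
  expect_equal(proton_range_mm(opt, 150), 10 * 0.0022 * 150^1.77)
  peaks <- vapply(e, function(E) bragg_peak_depth_mm(opt, E), numeric(1))
  expect_true(all(diff(peaks) > 0))
  # density scaling moves the peak as 1/(1+f)
  expect_equal(bragg_peak_depth_mm(opt, 150, 1.035),
               bragg_peak_depth_mm(opt, 150) / 1.035, tolerance = 1e-9)
  expect_error(proton_range_mm(opt, 300), "outside the optics validity")
})

test_that("doubling the MU doubles every voxel dose exactly", {
  ph <- tiny_phantom()
  d1 <- spot_dose(ph, spot_optics(), 0, 100, 2, -3, 1.25)
  d2 <- spot_dose(ph, spot_optics(), 0, 100, 2, -3, 2.5)
  expect_identical(as.vector(unclass(d2)), 2 * as.vector(unclass(d1)))
})

test_that("the lateral profile is Gaussian with the advertised sigma", {
  # flat-entry geometry, no depth broadening: sigma is exactly sigma_air
  opt <- spot_optics(depth_broadening = 0)
  ph <- generate_phantom(phantom_spec(dim_vox = c(21, 21, 40),
                                      spacing_mm = c(5, 5, 2)))
  sig <- sigma_air_mm(opt, 150)   # 10 mm = 2 lateral voxels
  d <- spot_dose(ph, opt, 0, 150, 0, 0, 1)
  arr <- unclass(d)
  mid <- 11
  depth_idx <- 30   # well inside, same depth for both columns
  on_axis <- arr[mid, mid, depth_idx]
  off_sigma <- arr[mid + 2, mid, depth_idx]   # +10 mm = 1 sigma
  expect_gt(on_axis, 0)
  expect_equal(off_sigma / on_axis, exp(-0.5), tolerance = 1e-6)
})

test_that("the lateral integral per MU reproduces the depth-dose curve", {
  opt <- spot_optics(depth_broadening = 0)
  # fine lateral sampling out to > 4 sigma
  ph <- generate_phantom(phantom_spec(dim_vox = c(91, 91, 30),
                                      spacing_mm = c(1.5, 1.5, 2)))
  mu <- 2
  d <- spot_dose(ph, opt, 0, 110, 0, 0, mu)
  arr <- unclass(d)
  for (depth_idx in c(10, 20)) {
    z <- ph$origin_mm[3] + (depth_idx - 1) * ph$spacing_mm[3]
    depth <- z - (ph$origin_mm[3] - ph$spacing_mm[3] / 2)
    lateral_integral <- sum(arr[, , depth_idx]) * prod(ph$spacing_mm[1:2])
    expected <- mu * spotrobust:::MU_CALIBRATION_CGy *
      depth_dose(opt, depth, 110)
    expect_equal(lateral_integral / expected, 1, tolerance = 1e-3)
  }
})

test_that("plan dose is the superposition of its spot doses", {
  ph <- tiny_phantom()
  plan <- tiny_plan(ph)
  plan$spots <- plan$spots[1, ]
  one <- compute_dose(plan, ph)
  alone <- spot_dose(ph, spot_optics(), plan$beams$gantry_angle_deg[1],
                     plan$spots$energy_MeV[1], plan$spots$x_mm[1],
                     plan$spots$y_mm[1], plan$spots$mu[1])
  expect_equal(as.vector(unclass(one)), as.vector(unclass(alone)),
               tolerance = 1e-12)
  # two identical spots give exactly twice the dose
  plan2 <- plan
  plan2$spots <- dplyr::bind_rows(plan$spots, plan$spots)
  plan2$spots$spot_id <- 1:2
  two <- compute_dose(plan2, ph)
  expect_equal(as.vector(unclass(two)), 2 * as.vector(unclass(one)),
               tolerance = 1e-12)
})

test_that("a denser medium pulls the Bragg peak proximally by 1/(1+f)", {
  opt <- spot_optics()
  ph <- generate_phantom(phantom_spec(dim_vox = c(21, 21, 120),
                                      spacing_mm = c(5, 5, 1)))
  peak_z <- function(density) {
    d <- spot_dose(ph, opt, 0, 120, 0, 0, 1,
                   scen = scenario(density_scale = density))
    which.max(unclass(d)[11, 11, ])
  }
  p1 <- peak_z(1)
  p2 <- peak_z(1.035)
  expect_equal(p2 / p1, 1 / 1.035, tolerance = 0.02)
  expect_gt(peak_z(0.965), p1)
})

test_that("dose is shift-equivariant on a uniform phantom", {
  opt <- spot_optics()
  ph <- generate_phantom(phantom_spec(dim_vox = c(30, 30, 30),
                                      spacing_mm = c(2.5, 2.5, 2.5)))
  base <- unclass(spot_dose(ph, opt, 0, 100, 0, 0, 1))
  # shifting the isocenter +1 voxel along IS translates the dose with it:
  # the shifted pattern at voxel j equals the unshifted one at voxel j - 1
  sh <- unclass(spot_dose(ph, opt, 0, 100, 0, 0, 1,
                          scen = scenario(shift_mm = c(0, 2.5, 0))))
  expect_equal(sh[, 2:30, ], base[, 1:29, ], tolerance = 1e-9)
})

test_that("integrated spot dose is invariant under small lateral shifts", {
  opt <- spot_optics()
  ph <- generate_phantom(phantom_spec(dim_vox = c(61, 61, 40),
                                      spacing_mm = c(2.5, 2.5, 2.5)))
  a <- sum(unclass(spot_dose(ph, opt, 0, 110, 0, 0, 1)))
  b <- sum(unclass(spot_dose(ph, opt, 0, 110, 6, -4, 1)))
  expect_equal(a, b, tolerance = 1e-3)
})

test_that("D99 normalization hits the prescription and is idempotent", {
  ph <- tiny_phantom()
  plan <- tiny_plan(ph)
  norm <- normalize_plan(plan, ph)
  mask <- as.vector(ph$masks$CTV)
  dv <- as.vector(unclass(norm$dose))[mask]
  expect_equal(d_percent(dv, 99), plan$prescription_cGy, tolerance = 0.1)
  norm2 <- normalize_plan(norm$plan, ph)
  expect_equal(norm2$factor, 1, tolerance = 1e-4)
  # bisection oracle on the scaling factor agrees
  nominal <- compute_dose(plan, ph)
  dvec <- as.vector(unclass(nominal))[mask]
  lo <- 0; hi <- 1e6
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (d_percent(dvec * mid, 99) < plan$prescription_cGy) lo <- mid else hi <- mid
  }
  expect_equal(norm$factor, (lo + hi) / 2, tolerance = 1e-6)
})

test_that("deletion impact matches direct recomputation and its limits", {
  ph <- tiny_phantom()
  plan <- tiny_plan(ph)
  norm <- normalize_plan(plan, ph)
  plan <- norm$plan
  # a zero-MU spot changes nothing
  plan0 <- plan
  plan0$spots$mu[3] <- 0
  imp0 <- deletion_impact(plan0, ph, spot_ids = plan0$spots$spot_id[3])
  expect_equal(imp0$delta_d99, 0)
  expect_equal(imp0$delta_d003cc, 0)
  # deleting everything removes all dose
  imp_all <- deletion_impact(plan, ph, spot_ids = plan$spots$spot_id)
  expect_equal(imp_all$d99_without, 0)
  # one low-MU edge spot has a sub-percent effect; equals direct recompute
  edge_id <- plan$spots$spot_id[which.min(plan$spots$mu)]
  imp <- deletion_impact(plan, ph, spot_ids = edge_id)
  expect_lt(abs(imp$delta_d99), 0.01 * plan$prescription_cGy)
  plan_wo <- plan
  plan_wo$spots <- plan_wo$spots[plan_wo$spots$spot_id != edge_id, ]
  direct <- compute_dose(plan_wo, ph)
  dv <- as.vector(unclass(direct))[as.vector(ph$masks$CTV)]
  expect_equal(imp$d99_without, d_percent(dv, 99), tolerance = 1e-9)
  expect_error(deletion_impact(plan, ph, spot_ids = 99999), "unknown spot")
})
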