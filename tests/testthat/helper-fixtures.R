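# Shared fixtures, built in code: a small phantom, compact plans, and the
# default optics. Sizes are kept small so the whole suite stays fast.

tiny_phantom <- function(with_oar = FALSE) {
  structs <- list(struct_sphere("CTV", c(0, 0, 0), 12))
  if (with_oar) {
    structs <- c(structs, list(struct_box("OAR", c(0, 0, 22), c(8, 8, 5))))
  }
  generate_phantom(phantom_spec(dim_vox = c(28, 28, 28),
                                spacing_mm = c(2.5, 2.5, 2.5),
                                structures = structs))
}

tiny_plan <- function(phantom, seed = 1, ...) {
  generate_plan(phantom,
                plan_spec(gantry_angles_deg = c(350, 10),
                          spot_spacing_mm = 8, layer_spacing_mm = 6,
                          depth_margin_mm = 8, aperture_margin_mm = 10,
                          optimize_weights = FALSE, ...),
                seed = seed)
}

# the margin-generous / zero-margin pair used for end-to-end checks
generous_plan <- function(phantom, seed = 1) {
  generate_plan(phantom,
                plan_spec(preset = "apbi", spot_spacing_mm = 7,
                          layer_spacing_mm = 5, depth_margin_mm = 12,
                          aperture_margin_mm = 18),
                seed = seed)
}

zero_margin_plan <- function(phantom, seed = 1) {
  generate_plan(phantom,
                plan_spec(preset = "apbi", spot_spacing_mm = 7,
                          layer_spacing_mm = 5, depth_margin_mm = 0,
                          aperture_margin_mm = 0),
                seed = seed)
}

robustness_phantom <- function() {
  generate_phantom(phantom_spec(dim_vox = c(40, 40, 32),
                                spacing_mm = c(2.5, 2.5, 2.5),
                                structures = list(
                                  struct_sphere("CTV", c(0, 0, 0), 15))))
}

new_log_for_test <- function(pulses, gantry = 0) {
  spotrobust:::new_proton_log(
    header = list(date = "2026-01-01", plan_id = "test", beam_id = 1,
                  gantry_angle_deg = gantry, snout_extension_mm = 150,
                  total_prescribed_MU = sum(pulses$target_MU)),
    pulses = pulses)
}

# brute-force MU-weighted pulse aggregation (independent of the package's
# dplyr implementation)
brute_aggregate <- function(pulses) {
  ids <- sort(unique(pulses$spot_index))
  out <- data.frame(spot_index = ids, x = NA_real_, y = NA_real_,
                    mu = NA_real_)
  for (k in seq_along(ids)) {
    rows <- pulses[pulses$spot_index == ids[k], ]
    mu <- 0; wx <- 0; wy <- 0
    for (i in seq_len(nrow(rows))) {
      mu <- mu + rows$actual_MU[i]
      wx <- wx + rows$actual_x_mm[i] * rows$actual_MU[i]
      wy <- wy + rows$actual_y_mm[i] * rows$actual_MU[i]
    }
    out$mu[k] <- mu
    out$x[k] <- if (mu > 0) wx / mu else NA_real_
    out$y[k] <- if (mu > 0) wy / mu else NA_real_
  }
  out
}

# brute-force D_p% / D_cc by explicit order statistics and hand-rolled
# linear interpolation (no approx())
brute_d_index <- function(doses, count) {
  s <- sort(doses, decreasing = TRUE)
  n <- length(s)
  c <- min(max(count, 1), n)
  k <- floor(c)
  if (k >= n) return(s[n])
  s[k] + (c - k) * (s[k + 1] - s[k])
}

# brute-force cumulative DVH by counting
brute_dvh_volume <- function(doses, edge) {
  100 * sum(doses >= edge) / length(doses)
}
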