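## Simplified analytic pencil-beam dose engine.
##
## Per spot: dose(voxel) = MU * DD(radiological depth) * G(lateral r;
## sigma(E, depth)) with a normalized 2-D lateral Gaussian, superposed over
## all kept spots of all beams. Radiological depth is accumulated along a
## single central ray per spot (piecewise-uniform phantoms make lateral
## heterogeneity negligible). A constant RBE of 1.1 and the MU-to-dose
## conversion are folded into one calibration constant; absolute scale is
## set by D99 normalization anyway.

MU_CALIBRATION_CGy <- 110  # cGy(RBE) mm^2 per MU per unit depth-dose

#' A perturbation scenario
#'
#' @param shift_mm Length-3 isocenter displacement in patient axes
#'   (RL, IS, PA), mm.
#' @param density_scale Multiplier applied to every voxel's relative
#'   stopping power (e.g. 1.035 for +3.5% density).
#' @param label Scenario label.
#' @return A `scenario` object (named list).
#' @export
scenario <- function(shift_mm = c(0, 0, 0), density_scale = 1,
                     label = "nominal") {
  stopifnot(length(shift_mm) == 3, density_scale > 0)
  structure(list(shift_mm = as.numeric(shift_mm),
                 density_scale = density_scale, label = label),
            class = "scenario")
}

#' Filter spots by an aperture polygon
#'
#' A spot is kept iff its centroid lies inside or exactly on the polygon
#' boundary (boundary-inclusive). Deleted spots are returned with their MU
#' so the unmodelled dose can be reported: the treatment machine still
#' delivers partial dose from a spot trimmed by the aperture, but the
#' engine (like the TPS it stands in for) cannot compute it.
#'
#' @param spots Tibble with `x_mm`, `y_mm` (beam's-eye-view) and `mu`.
#' @param aperture Polygon vertex matrix (m x 2), same frame as the spots.
#' @return List with tibbles `kept` and `deleted`.
#' @export
aperture_filter <- function(spots, aperture) {
  inside <- point_in_polygon(cbind(spots$x_mm, spots$y_mm), aperture)
  list(kept = spots[inside, , drop = FALSE],
       deleted = spots[!inside, , drop = FALSE])
}

# Apply each beam/layer aperture to a plan's spots. Returns the plan with
# only kept spots plus a tibble of deleted spots (with MU).
filter_plan_aperture <- function(plan) {
  keep <- logical(nrow(plan$spots))
  for (b in plan$beams$beam_id) {
    rows <- which(plan$spots$beam_id == b)
    for (l in unique(plan$spots$layer[rows])) {
      lr <- rows[plan$spots$layer[rows] == l]
      poly <- aperture_polygon(plan, b, l)
      keep[lr] <- point_in_polygon(
        cbind(plan$spots$x_mm[lr], plan$spots$y_mm[lr]), poly)
    }
  }
  deleted <- plan$spots[!keep, , drop = FALSE]
  plan$spots <- plan$spots[keep, , drop = FALSE]
  list(plan = plan, deleted = deleted)
}

#' Replace a plan's spots with (predicted) delivered spots
#'
#' Builds the "as-delivered" plan: planned positions and MUs are swapped
#' for the supplied values (e.g. from [predict_plan()]), everything else
#' (beams, apertures, prescription) is unchanged.
#'
#' @param plan A `treatment_plan`.
#' @param delivered Tibble with `spot_id`, `x_mm`, `y_mm`, `mu` covering
#'   every spot of the plan.
#' @return A `treatment_plan`.
#' @export
plan_with_spots <- function(plan, delivered) {
  if (!all(plan$spots$spot_id %in% delivered$spot_id)) {
    abort("`delivered` must contain every spot_id of the plan")
  }
  m <- match(plan$spots$spot_id, delivered$spot_id)
  plan$spots$x_mm <- delivered$x_mm[m]
  plan$spots$y_mm <- delivered$y_mm[m]
  plan$spots$mu <- delivered$mu[m]
  plan
}

# Precomputed per-beam, per-scenario geometry: projections of voxel
# centres onto the beam frame (relative to the shifted isocenter).
# `voxels` restricts the evaluation to a subset of linear voxel indices
# (e.g. structure voxels only), which is much cheaper when only DVHs of
# named structures are needed.
beam_context <- function(phantom, gantry_angle_deg, scen, voxels = NULL) {
  fr <- beam_frame(gantry_angle_deg)
  V <- voxel_coords(phantom)
  if (!is.null(voxels)) V <- V[voxels, , drop = FALSE]
  rel <- sweep(V, 2, scen$shift_mm)
  T3 <- rel %*% cbind(fr$u, fr$e1, fr$e2)
  lo <- phantom$origin_mm - phantom$spacing_mm / 2
  hi <- phantom$origin_mm + (phantom$dim_vox - 1) * phantom$spacing_mm +
    phantom$spacing_mm / 2
  rr <- range(phantom$rsp)
  list(frame = fr, T3 = T3, lo = lo, hi = hi, shift = scen$shift_mm,
       density_scale = scen$density_scale, step = min(phantom$spacing_mm) / 2,
       uniform_rsp = if (rr[2] - rr[1] < 1e-12) rr[1] else NA_real_)
}

# Radiological depth profile along one central ray: returns a function-like
# list (t0, step, cumulative radiological depth at uniform samples).
trace_ray <- function(phantom, ctx, sx, sy) {
  fr <- ctx$frame
  origin <- ctx$shift + sx * fr$e1 + sy * fr$e2
  t0 <- ray_box_entry(origin, fr$u, ctx$lo, ctx$hi)
  if (is.na(t0)) return(NULL)
  span <- sqrt(sum((ctx$hi - ctx$lo)^2))
  tau <- seq(0, span, by = ctx$step)
  P <- cbind(origin[1] + (t0 + tau) * fr$u[1],
             origin[2] + (t0 + tau) * fr$u[2],
             origin[3] + (t0 + tau) * fr$u[3])
  idx <- sapply(1:3, function(a) {
    pmin(pmax(round((P[, a] - phantom$origin_mm[a]) / phantom$spacing_mm[a]) + 1,
              1), phantom$dim_vox[a])
  })
  lin <- idx[, 1] + (idx[, 2] - 1) * phantom$dim_vox[1] +
    (idx[, 3] - 1) * phantom$dim_vox[1] * phantom$dim_vox[2]
  inside <- P[, 1] >= ctx$lo[1] & P[, 1] <= ctx$hi[1] &
    P[, 2] >= ctx$lo[2] & P[, 2] <= ctx$hi[2] &
    P[, 3] >= ctx$lo[3] & P[, 3] <= ctx$hi[3]
  rsp <- as.vector(phantom$rsp)[lin] * ctx$density_scale
  rsp[!inside] <- 0
  # cumulative radiological depth at geometric depth tau (midpoint rule)
  rad <- cumsum(rsp) * ctx$step - rsp * ctx$step / 2
  list(t0 = t0, step = ctx$step, rad = rad, n = length(tau))
}

# dose vector over all voxels for one spot
spot_dose_vec <- function(phantom, optics, ctx, energy_MeV, sx, sy, mu) {
  nvox <- nrow(ctx$T3)
  dose <- numeric(nvox)
  R <- proton_range_mm(optics, energy_MeV)
  sig_air <- sigma_air_mm(optics, energy_MeV)
  sig_peak <- peak_sigma_mm(optics, R)
  sig_max <- sqrt(sig_air^2 + (optics$depth_broadening * (R + 5 * sig_peak))^2)
  lat <- 4 * sig_max
  d_max <- R + 6 * sig_peak
  uniform <- !is.na(ctx$uniform_rsp)
  if (uniform) {
    # uniform medium: radiological depth is linear in geometric depth and
    # no ray sampling is needed, only the ray's box-entry parameter
    fr <- ctx$frame
    origin <- ctx$shift + sx * fr$e1 + sy * fr$e2
    t0 <- ray_box_entry(origin, fr$u, ctx$lo, ctx$hi)
    if (is.na(t0)) return(dose)
    k <- ctx$uniform_rsp * ctx$density_scale
    cand <- which(ctx$T3[, 1] >= t0 & ctx$T3[, 1] <= t0 + d_max / k &
                    abs(ctx$T3[, 2] - sx) <= lat &
                    abs(ctx$T3[, 3] - sy) <= lat)
    if (!length(cand)) return(dose)
    d_rad <- (ctx$T3[cand, 1] - t0) * k
  } else {
    ray <- trace_ray(phantom, ctx, sx, sy)
    if (is.null(ray)) return(dose)
    cand <- which(ctx$T3[, 1] >= ray$t0 &
                    abs(ctx$T3[, 2] - sx) <= lat &
                    abs(ctx$T3[, 3] - sy) <= lat)
    if (!length(cand)) return(dose)
    fi <- pmin(pmax((ctx$T3[cand, 1] - ray$t0) / ray$step, 0), ray$n - 1)
    i0 <- floor(fi)
    frac <- fi - i0
    d_rad <- ray$rad[i0 + 1] * (1 - frac) + ray$rad[pmin(i0 + 2, ray$n)] * frac
  }
  r2 <- (ctx$T3[cand, 2] - sx)^2 + (ctx$T3[cand, 3] - sy)^2
  sel <- d_rad <= d_max & r2 <= lat^2
  if (!any(sel)) return(dose)
  d <- d_rad[sel]
  sig2 <- sig_air^2 + (optics$depth_broadening * d)^2
  dose[cand[sel]] <- mu * MU_CALIBRATION_CGy *
    depth_dose(optics, d, energy_MeV) *
    exp(-r2[sel] / (2 * sig2)) / (2 * pi * sig2)
  dose
}

#' Dose contribution of a single spot
#'
#' Convenience wrapper around the engine kernel for one spot; for whole
#' plans use [compute_dose()], which shares geometry across spots.
#'
#' @param phantom A `phantom`.
#' @param optics A [spot_optics()].
#' @param gantry_angle_deg Beam gantry angle, degrees.
#' @param energy_MeV Nominal energy.
#' @param x_mm,y_mm Spot position, beam's-eye-view at isocenter, mm.
#' @param mu Spot monitor units.
#' @param scen A [scenario()] (nominal by default).
#' @return A `dose_grid`: 3-D array of cGy(RBE) on the phantom geometry.
#' @export
spot_dose <- function(phantom, optics, gantry_angle_deg, energy_MeV,
                      x_mm, y_mm, mu, scen = scenario()) {
  check_energy(optics, energy_MeV)
  ctx <- beam_context(phantom, gantry_angle_deg, scen)
  d <- spot_dose_vec(phantom, optics, ctx, energy_MeV, x_mm, y_mm, mu)
  new_dose_grid(phantom, d)
}

new_dose_grid <- function(phantom, dose_vec) {
  structure(array(dose_vec, dim = phantom$dim_vox),
            class = "dose_grid",
            origin_mm = phantom$origin_mm, spacing_mm = phantom$spacing_mm,
            voxel_cc = phantom$voxel_cc)
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %s voxels; max %.1f cGy(RBE)\n",
              paste(dim(x), collapse = " x "), max(x)))
  invisible(x)
}

#' Compute the dose of a plan under a scenario
#'
#' Applies the aperture (spots whose centroid falls outside are deleted
#' and deposit no dose), displaces the beam isocenters by the scenario
#' shift, scales every voxel's stopping power by the scenario density
#' scale, and superposes all kept spots' dose kernels.
#'
#' @param plan A `treatment_plan`.
#' @param phantom A `phantom`.
#' @param optics A [spot_optics()].
#' @param scen A [scenario()]; nominal (no shift, density 1) by default.
#' @param apply_aperture If `FALSE`, skip aperture filtering.
#' @return A `dose_grid` with attributes `deleted_spots` (tibble of
#'   aperture-deleted spots with their MU) and `scenario_label`.
#' @export
compute_dose <- function(plan, phantom, optics = spot_optics(),
                         scen = scenario(), apply_aperture = TRUE) {
  stopifnot(inherits(plan, "treatment_plan"), inherits(phantom, "phantom"),
            inherits(scen, "scenario"))
  res <- compute_dose_at(plan, phantom, optics, scen, voxels = NULL,
                         apply_aperture = apply_aperture)
  out <- new_dose_grid(phantom, res$dose)
  attr(out, "deleted_spots") <- res$deleted
  attr(out, "scenario_label") <- scen$label
  out
}

# dose at a subset of linear voxel indices (all voxels when NULL)
compute_dose_at <- function(plan, phantom, optics, scen, voxels = NULL,
                            apply_aperture = TRUE) {
  if (apply_aperture) {
    flt <- filter_plan_aperture(plan)
    plan_k <- flt$plan; deleted <- flt$deleted
  } else {
    plan_k <- plan
    deleted <- plan$spots[0, , drop = FALSE]
  }
  n <- if (is.null(voxels)) prod(phantom$dim_vox) else length(voxels)
  total <- numeric(n)
  for (b in plan_k$beams$beam_id) {
    sp <- plan_k$spots[plan_k$spots$beam_id == b, ]
    if (!nrow(sp)) next
    ctx <- beam_context(phantom, plan_k$beams$gantry_angle_deg[
      plan_k$beams$beam_id == b], scen, voxels = voxels)
    for (i in seq_len(nrow(sp))) {
      total <- total + spot_dose_vec(phantom, optics, ctx, sp$energy_MeV[i],
                                     sp$x_mm[i], sp$y_mm[i], sp$mu[i])
    }
  }
  list(dose = total, deleted = deleted)
}

#' Normalize a plan so that D99 of the target equals the prescription
#'
#' Dose is linear in a global MU factor, so the factor is
#' `prescription / D99(nominal dose)` exactly; the nominal dose is
#' computed once and rescaled.
#'
#' @param plan A `treatment_plan`.
#' @param phantom,optics Engine inputs.
#' @param structure Target structure name (default the plan's target).
#' @param prescription_cGy Prescription; defaults to the plan's.
#' @return List: `plan` (MUs rescaled), `factor`, `d99_before`,
#'   `dose` (the rescaled nominal `dose_grid`).
#' @export
normalize_plan <- function(plan, phantom, optics = spot_optics(),
                           structure = plan$target,
                           prescription_cGy = plan$prescription_cGy) {
  dose <- compute_dose(plan, phantom, optics)
  mask <- get_mask(phantom, structure)
  dvec <- as.vector(unclass(dose))[as.vector(mask)]
  d99 <- dvh_index_dp(dvec, 99)
  if (d99 <= 0) abort("target receives zero dose; cannot normalize")
  factor <- prescription_cGy / d99
  plan$spots$mu <- plan$spots$mu * factor
  dose2 <- new_dose_grid(phantom, as.vector(unclass(dose)) * factor)
  attr(dose2, "deleted_spots") <- attr(dose, "deleted_spots")
  attr(dose2, "scenario_label") <- "nominal"
  list(plan = plan, factor = factor, d99_before = d99, dose = dose2)
}

#' Impact of deleting spots from a plan
#'
#' Recomputes the nominal dose without the listed spots (using engine
#' linearity: the deleted spots' contributions are subtracted) and reports
#' the change in target D99 and D0.03cc.
#'
#' @param plan A `treatment_plan` (normalized).
#' @param phantom,optics Engine inputs.
#' @param spot_ids Spot ids to delete.
#' @param structure Structure over which indices are evaluated.
#' @return One-row tibble: index values with and without the spots and the
#'   deltas (cGy(RBE)).
#' @export
deletion_impact <- function(plan, phantom, optics = spot_optics(), spot_ids,
                            structure = plan$target) {
  unknown <- setdiff(spot_ids, plan$spots$spot_id)
  if (length(unknown)) {
    abort(sprintf("unknown spot id(s): %s", paste(unknown, collapse = ", ")))
  }
  mask_idx <- which(as.vector(get_mask(phantom, structure)))
  v_full <- compute_dose_at(plan, phantom, optics, scenario(),
                            voxels = mask_idx)$dose
  kept <- filter_plan_aperture(plan)$plan$spots
  del <- kept[kept$spot_id %in% spot_ids, ]
  contrib <- numeric(length(mask_idx))
  for (b in unique(del$beam_id)) {
    ctx <- beam_context(phantom,
                        plan$beams$gantry_angle_deg[plan$beams$beam_id == b],
                        scenario(), voxels = mask_idx)
    sp <- del[del$beam_id == b, ]
    for (i in seq_len(nrow(sp))) {
      contrib <- contrib + spot_dose_vec(phantom, optics, ctx,
                                         sp$energy_MeV[i], sp$x_mm[i],
                                         sp$y_mm[i], sp$mu[i])
    }
  }
  v_without <- pmax(v_full - contrib, 0)
  vox_cc <- phantom$voxel_cc
  tibble(structure = structure, n_deleted = nrow(del),
         deleted_mu = sum(del$mu),
         d99_full = dvh_index_dp(v_full, 99),
         d99_without = dvh_index_dp(v_without, 99),
         delta_d99 = dvh_index_dp(v_without, 99) - dvh_index_dp(v_full, 99),
         d003cc_full = dvh_index_dcc(v_full, vox_cc, 0.03),
         d003cc_without = dvh_index_dcc(v_without, vox_cc, 0.03),
         delta_d003cc = dvh_index_dcc(v_without, vox_cc, 0.03) -
           dvh_index_dcc(v_full, vox_cc, 0.03))
}
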