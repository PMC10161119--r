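#' Specify a pencil-beam scanning treatment plan
#'
#' Describes beams (gantry angle, snout extension), energy-layer selection,
#' the spot lattice and the aperture for [generate_plan()]. Two presets
#' mirror common clinical configurations: a two-anterior-beam partial
#' breast irradiation ("apbi") geometry at 3000 cGy(RBE) in 5 fractions,
#' and a six-beam posterior-fossa ("ependymoma") geometry at 5040 cGy(RBE)
#' in 28 fractions. Presets fix beam count and prescription only; the
#' anatomy is whatever phantom they are paired with.
#'
#' @param preset `"apbi"`, `"ependymoma"`, or `NULL` for fully manual.
#' @param prescription_cGy Total prescription dose, cGy(RBE).
#' @param fractions Number of fractions.
#' @param gantry_angles_deg Numeric vector, one gantry angle per beam, in
#'   `[0, 360)`.
#' @param snout_mm Snout extension per beam (recycled), mm.
#' @param spot_spacing_mm Lateral spot lattice spacing, mm.
#' @param layer_spacing_mm Radiological depth spacing between energy
#'   layers, mm.
#' @param depth_margin_mm Proximal/distal margin added to the target's
#'   depth extent when choosing energy layers, mm.
#' @param aperture_mode `"static"` (one polygon per beam) or `"per_layer"`
#'   (one polygon per energy layer).
#' @param aperture_margin_mm Uniform dilation of the target's beam's-eye
#'   view outline, mm. Spots are placed inside the aperture, so this is
#'   also the lateral coverage margin.
#' @param mu_range Length-2 range of per-spot monitor units (uniform draw).
#' @param optimize_weights Flatten the dose with depth and lateral MU
#'   weighting (default). Disable for large training-corpus plans where
#'   only spot geometry and raw MUs matter.
#' @param target Name of the structure the plan targets (default "CTV").
#' @return An object of class `plan_spec`.
#' @export
plan_spec <- function(preset = NULL,
                      prescription_cGy = 3000, fractions = 5,
                      gantry_angles_deg = c(350, 10),
                      snout_mm = 150,
                      spot_spacing_mm = 5,
                      layer_spacing_mm = 6,
                      depth_margin_mm = 6,
                      aperture_mode = c("static", "per_layer"),
                      aperture_margin_mm = 6,
                      mu_range = c(0.5, 2),
                      optimize_weights = TRUE,
                      target = "CTV") {
  aperture_mode <- match.arg(aperture_mode)
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("apbi", "ependymoma"))
    if (preset == "apbi") {
      prescription_cGy <- 3000; fractions <- 5
      gantry_angles_deg <- c(350, 10)     # two anterior beams
      aperture_mode <- "static"
    } else {
      prescription_cGy <- 5040; fractions <- 28
      # RAO, LAO, LPO, RPO, LL, RL
      gantry_angles_deg <- c(315, 45, 135, 225, 90, 270)
      aperture_mode <- "per_layer"
    }
  }
  stopifnot(prescription_cGy > 0, fractions >= 1,
            all(gantry_angles_deg >= 0 & gantry_angles_deg < 360),
            spot_spacing_mm > 0, layer_spacing_mm > 0, depth_margin_mm >= 0,
            aperture_margin_mm >= 0,
            length(mu_range) == 2, all(mu_range > 0),
            mu_range[1] <= mu_range[2])
  structure(list(preset = preset, prescription_cGy = prescription_cGy,
                 fractions = fractions,
                 gantry_angles_deg = gantry_angles_deg,
                 snout_mm = rep_len(snout_mm, length(gantry_angles_deg)),
                 spot_spacing_mm = spot_spacing_mm,
                 layer_spacing_mm = layer_spacing_mm,
                 depth_margin_mm = depth_margin_mm,
                 aperture_mode = aperture_mode,
                 aperture_margin_mm = aperture_margin_mm,
                 mu_range = mu_range, optimize_weights = optimize_weights,
                 target = target),
            class = "plan_spec")
}

#' Generate a treatment plan on a phantom
#'
#' Places energy layers covering the target's radiological depth extent per
#' beam (plus the configured margin), lays a lateral spot lattice over the
#' target's beam's-eye-view cross-section, builds the aperture polygon as
#' the dilated target outline, and assigns per-spot monitor units.
#' MU weighting emulates an optimized plan: energy layers are weighted
#' recursively (distal to proximal) to flatten the spread-out Bragg peak,
#' spots within a layer are iteratively weighted to flatten the lateral
#' Gaussian superposition, and a random modulation drawn from `mu_range`
#' is applied on top. Every spot
#' centroid lies inside its aperture by construction. If the lattice
#' spacing exceeds the target extent, a single centre spot is still emitted
#' per layer.
#'
#' @param phantom A [generate_phantom()] result containing the target mask.
#' @param spec A [plan_spec()].
#' @param seed Integer seed for the monitor-unit draws.
#' @param optics A [spot_optics()] used to convert depths to energies.
#' @return An object of class `treatment_plan` with elements
#'   `prescription_cGy`, `fractions`, `beams` (tibble), `spots` (tibble:
#'   one row per spot with beam, layer, energy, position, MU) and
#'   `apertures` (per-beam polygon lists).
#' @export
generate_plan <- function(phantom, spec, seed = 1, optics = spot_optics()) {
  stopifnot(inherits(phantom, "phantom"), inherits(spec, "plan_spec"))
  mask <- get_mask(phantom, spec$target)
  if (!any(mask)) abort(sprintf("target structure '%s' is empty", spec$target))
  V <- voxel_coords(phantom)[as.vector(mask), , drop = FALSE]
  lo <- phantom$origin_mm - phantom$spacing_mm / 2
  hi <- phantom$origin_mm + (phantom$dim_vox - 1) * phantom$spacing_mm +
    phantom$spacing_mm / 2
  rsp_bg <- stats::median(phantom$rsp)

  beams <- tibble(beam_id = seq_along(spec$gantry_angles_deg),
                  gantry_angle_deg = spec$gantry_angles_deg,
                  snout_extension_mm = spec$snout_mm)
  spots_list <- list()
  apertures <- list()
  spot_counter <- 0L

  for (b in seq_len(nrow(beams))) {
    fr <- beam_frame(beams$gantry_angle_deg[b])
    c1 <- V %*% fr$e1; c2 <- V %*% fr$e2; tdep <- V %*% fr$u
    if (!length(c1)) {
      abort(sprintf("beam %d does not intersect target '%s'", b, spec$target))
    }
    # geometric depth of each target voxel from the grid entry of its ray,
    # converted to radiological depth with the background stopping power
    t0 <- ray_box_entry(c(0, 0, 0) + drop(mean(c1)) * fr$e1 +
                          drop(mean(c2)) * fr$e2, fr$u, lo, hi)
    depth <- (drop(tdep) - t0) * rsp_bg
    # clamp to depths reachable within the optics' supported energies
    reach <- proton_range_mm(optics, optics$energy_range_MeV + c(1, -1) * 1e-6)
    d_lo <- min(max(min(depth) - spec$depth_margin_mm, reach[1]), reach[2])
    d_hi <- max(min(max(depth) + spec$depth_margin_mm, reach[2]), d_lo)
    n_layers <- max(1L, ceiling((d_hi - d_lo) / spec$layer_spacing_mm) + 1L)
    layer_depths <- seq(d_hi, d_lo, length.out = n_layers)  # distal first
    energies <- energy_for_range_mm(optics, layer_depths)

    bev <- cbind(drop(c1), drop(c2))
    full_poly <- convex_outline(bev, spec$aperture_margin_mm)
    layer_polys <- vector("list", n_layers)
    for (l in seq_len(n_layers)) {
      if (spec$aperture_mode == "per_layer") {
        slab <- abs(depth - layer_depths[l]) <= spec$layer_spacing_mm
        pts <- if (sum(slab) >= 3) bev[slab, , drop = FALSE] else bev
        layer_polys[[l]] <- convex_outline(pts, spec$aperture_margin_mm)
      } else {
        layer_polys[[l]] <- full_poly
      }
    }
    apertures[[b]] <- list(mode = spec$aperture_mode, polygons = layer_polys)

    # depth weighting: recursive distal-to-proximal flattening of the
    # spread-out Bragg peak (the distal layer only receives its own peak;
    # proximal layers sit on the plateaus of all deeper layers)
    depth_w <- rep(1, n_layers)
    if (spec$optimize_weights) {
      ddmat <- vapply(seq_len(n_layers), function(k)
        depth_dose(optics, layer_depths, energies[k]), numeric(n_layers))
      for (j in seq_len(n_layers)) {
        got <- if (j > 1) sum(ddmat[j, seq_len(j - 1)] * depth_w[seq_len(j - 1)]) else 0
        depth_w[j] <- max((1 - got) / ddmat[j, j], 0.02)
      }
    }

    # lateral lattice over the aperture bounding box, centred on the target
    ctr <- colMeans(bev)
    for (l in seq_len(n_layers)) {
      poly <- layer_polys[[l]]
      rx <- range(poly[, 1]); ry <- range(poly[, 2])
      gx <- lattice_axis(ctr[1], rx, spec$spot_spacing_mm)
      gy <- lattice_axis(ctr[2], ry, spec$spot_spacing_mm)
      cand <- as.matrix(expand.grid(x = gx, y = gy))
      keep <- point_in_polygon(cand, poly)
      pts <- cand[keep, , drop = FALSE]
      if (nrow(pts) == 0) pts <- matrix(ctr, ncol = 2)  # degenerate-lattice rule
      # lateral fluence flattening: iteratively boost edge spots so the
      # Gaussian superposition is level across the covered cross-section
      # (emulating what an optimizer does; otherwise edges sag)
      sig_lat <- sigma_at_depth_mm(optics, energies[l], layer_depths[l])
      lat_w <- rep(1, nrow(pts))
      if (spec$optimize_weights && nrow(pts) > 1) {
        # ridge-regularized solve of K w = 1: produces the edge-enhanced
        # ("horned") weights needed for a level profile out to the last
        # spot ring, since the kernel is much wider than the spot pitch
        K <- exp(-as.matrix(stats::dist(pts))^2 / (2 * sig_lat^2))
        w <- tryCatch(
          solve(K + 0.01 * nrow(pts) * mean(diag(K)) *
                  diag(nrow(pts)) / nrow(pts), rep(1, nrow(pts))),
          error = function(e) rep(1 / nrow(pts), nrow(pts)))
        w <- pmax(w, 0.02 * max(w))
        for (it in 1:3) {   # proportional refinement after clamping
          F <- as.vector(K %*% w)
          w <- w * pmin(pmax(mean(F) / F, 0.5), 2)
        }
        lat_w <- w / mean(w)
      }
      spots_list[[length(spots_list) + 1L]] <- tibble(
        beam_id = b, layer = l, energy_MeV = energies[l],
        x_mm = pts[, 1], y_mm = pts[, 2],
        weight = depth_w[l] * lat_w)
    }
  }
  spots <- bind_rows(spots_list)
  spots$spot_id <- seq_len(nrow(spots))
  # per-spot MU: flattening weight times a random modulation in mu_range,
  # rescaled so the mean spot MU equals the mu_range midpoint
  modulation <- with_seed(derive_seed(seed, "plan-mu"),
                          runif(nrow(spots), spec$mu_range[1], spec$mu_range[2]))
  mu <- spots$weight * modulation
  spots$mu <- mu * mean(spec$mu_range) / mean(mu)
  spots <- spots[, c("spot_id", "beam_id", "layer", "energy_MeV",
                     "x_mm", "y_mm", "mu")]
  structure(list(prescription_cGy = spec$prescription_cGy,
                 fractions = spec$fractions, target = spec$target,
                 beams = beams, spots = spots, apertures = apertures,
                 seed = seed),
            class = "treatment_plan")
}

# symmetric lattice about a centre covering [rng[1], rng[2]]
lattice_axis <- function(center, rng, pitch) {
  n_lo <- ceiling((center - rng[1]) / pitch)
  n_hi <- ceiling((rng[2] - center) / pitch)
  center + pitch * seq(-n_lo, n_hi)
}

#' @export
print.treatment_plan <- function(x, ...) {
  cat(sprintf("<treatment_plan> %g cGy(RBE) in %d fx; %d beam(s), %d spot(s)\n",
              x$prescription_cGy, x$fractions, nrow(x$beams), nrow(x$spots)))
  invisible(x)
}

#' Total number of spots in a plan
#' @param plan A `treatment_plan`.
#' @return Integer count.
#' @export
n_spots <- function(plan) nrow(plan$spots)

#' Write / read a treatment plan as JSON
#'
#' The on-disk layout nests beams, energy layers, spot lists and aperture
#' vertex rings under a header with prescription and fractions. Numeric
#' values are stored at full precision so a written plan reads back
#' bit-identically.
#'
#' @param plan A `treatment_plan`.
#' @param path Output file path.
#' @return `write_plan` returns `path` invisibly; `read_plan` returns the
#'   `treatment_plan`.
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "treatment_plan"))
  obj <- list(
    format = "spotrobust-plan-v1",
    prescription_cGy = plan$prescription_cGy, fractions = plan$fractions,
    target = plan$target, seed = plan$seed,
    beams = lapply(seq_len(nrow(plan$beams)), function(b) {
      sp <- plan$spots[plan$spots$beam_id == b, ]
      ap <- plan$apertures[[b]]
      list(beam_id = b,
           gantry_angle_deg = plan$beams$gantry_angle_deg[b],
           snout_extension_mm = plan$beams$snout_extension_mm[b],
           aperture_mode = ap$mode,
           aperture_polygons = lapply(ap$polygons, function(p)
             list(x = fmt_full(p[, 1]), y = fmt_full(p[, 2]))),
           layers = lapply(sort(unique(sp$layer)), function(l) {
             s <- sp[sp$layer == l, ]
             list(layer = l, energy_MeV = fmt_full(s$energy_MeV[1]),
                  spot_id = s$spot_id,
                  x_mm = fmt_full(s$x_mm), y_mm = fmt_full(s$y_mm),
                  mu = fmt_full(s$mu))
           }))
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "spotrobust-plan-v1")) {
    abort("not a spotrobust plan file (missing format tag)")
  }
  beams <- tibble(
    beam_id = vapply(obj$beams, function(b) b$beam_id, numeric(1)),
    gantry_angle_deg = vapply(obj$beams, function(b) b$gantry_angle_deg, numeric(1)),
    snout_extension_mm = vapply(obj$beams, function(b) b$snout_extension_mm, numeric(1)))
  spots <- bind_rows(lapply(obj$beams, function(b) {
    bind_rows(lapply(b$layers, function(l) {
      tibble(spot_id = unlist(l$spot_id), beam_id = b$beam_id,
             layer = l$layer, energy_MeV = as.numeric(l$energy_MeV),
             x_mm = as.numeric(unlist(l$x_mm)),
             y_mm = as.numeric(unlist(l$y_mm)),
             mu = as.numeric(unlist(l$mu)))
    }))
  }))
  spots <- arrange(spots, .data$spot_id)
  apertures <- lapply(obj$beams, function(b) {
    list(mode = b$aperture_mode,
         polygons = lapply(b$aperture_polygons, function(p)
           cbind(as.numeric(unlist(p$x)), as.numeric(unlist(p$y)))))
  })
  structure(list(prescription_cGy = obj$prescription_cGy,
                 fractions = obj$fractions, target = obj$target,
                 beams = beams, spots = spots, apertures = apertures,
                 seed = obj$seed),
            class = "treatment_plan")
}

# aperture polygon applying to a given layer of a beam
aperture_polygon <- function(plan, beam_id, layer) {
  ap <- plan$apertures[[beam_id]]
  polys <- ap$polygons
  if (length(polys) == 1) return(polys[[1]])
  polys[[min(layer, length(polys))]]
}
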