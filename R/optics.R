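#' Pencil-beam optics model
#'
#' Parameterises the single-spot dose kernel of the analytic engine: a
#' power-law range-energy relation, an in-air lateral spot size anchored at
#' sigma of about 10 mm for a 150 MeV beam at isocenter (typical of compact
#' single-room systems), depth broadening, and a plateau-plus-Bragg-peak
#' depth-dose shape.
#'
#' @param range_alpha,range_p Coefficients of the range-energy power law
#'   \eqn{R(E) = \alpha E^p} with `R` in cm of water and `E` in MeV.
#'   Defaults 0.0022 and 1.77 reproduce clinical proton ranges to a few
#'   percent over 70-230 MeV.
#' @param sigma_ref_mm In-air lateral sigma at isocenter at `energy_ref_MeV`,
#'   in mm. Default 10 mm at 150 MeV.
#' @param energy_ref_MeV Reference energy for the lateral-sigma anchor.
#' @param sigma_energy_exp Exponent of the inverse power law
#'   \eqn{\sigma_{air}(E) = \sigma_{ref} (E_{ref}/E)^q}; spot size shrinks
#'   with energy.
#' @param depth_broadening Dimensionless coefficient `k` in
#'   \eqn{\sigma^2(E, d) = \sigma_{air}^2(E) + (k d)^2} (d = radiological
#'   depth, mm). Default 0.03 gives about 3 mm of extra sigma at 100 mm
#'   depth.
#' @param peak_plateau_ratio Ratio of the Bragg-peak term amplitude to the
#'   entrance plateau in the depth-dose curve.
#' @param peak_width_frac Proximal Bragg-peak Gaussian sigma as a fraction
#'   of range, plus a 1 mm floor: combines range straggling with the
#'   delivered beam's energy spread. Default 0.025.
#' @param distal_falloff_frac Distal-edge sigma as a fraction of the
#'   proximal peak sigma (< 1: the distal edge is steeper).
#' @param energy_range_MeV Two-element numeric, supported nominal energies.
#'
#' @return An object of class `spot_optics`.
#' @export
#' @examples
#' opt <- spot_optics()
#' proton_range_mm(opt, 150) # ~ 156 mm in water
spot_optics <- function(range_alpha = 0.0022, range_p = 1.77,
                        sigma_ref_mm = 10, energy_ref_MeV = 150,
                        sigma_energy_exp = 0.9,
                        depth_broadening = 0.03,
                        peak_plateau_ratio = 3,
                        peak_width_frac = 0.025,
                        distal_falloff_frac = 0.35,
                        energy_range_MeV = c(30, 250)) {
  stopifnot(range_alpha > 0, range_p > 0, sigma_ref_mm > 0,
            depth_broadening >= 0, peak_plateau_ratio > 0,
            peak_width_frac > 0, distal_falloff_frac > 0,
            distal_falloff_frac <= 1,
            length(energy_range_MeV) == 2,
            energy_range_MeV[1] < energy_range_MeV[2])
  structure(
    list(range_alpha = range_alpha, range_p = range_p,
         sigma_ref_mm = sigma_ref_mm, energy_ref_MeV = energy_ref_MeV,
         sigma_energy_exp = sigma_energy_exp,
         depth_broadening = depth_broadening,
         peak_plateau_ratio = peak_plateau_ratio,
         peak_width_frac = peak_width_frac,
         distal_falloff_frac = distal_falloff_frac,
         energy_range_MeV = energy_range_MeV),
    class = "spot_optics")
}

#' @export
print.spot_optics <- function(x, ...) {
  cat("<spot_optics>\n",
      sprintf("  R(E) = %.4g * E^%.3g cm;  R(150 MeV) = %.1f mm\n",
              x$range_alpha, x$range_p, proton_range_mm(x, 150)),
      sprintf("  sigma_air(%g MeV) = %.1f mm; depth broadening k = %.3g\n",
              x$energy_ref_MeV, x$sigma_ref_mm, x$depth_broadening),
      sprintf("  peak/plateau = %.2g; energies %g-%g MeV\n",
              x$peak_plateau_ratio, x$energy_range_MeV[1],
              x$energy_range_MeV[2]), sep = "")
  invisible(x)
}

#' Proton range in water
#'
#' @param optics A [spot_optics()] object.
#' @param energy_MeV Nominal beam energy (vectorised).
#' @return Range in mm of water.
#' @export
proton_range_mm <- function(optics, energy_MeV) {
  check_energy(optics, energy_MeV)
  10 * optics$range_alpha * energy_MeV^optics$range_p
}

#' Energy whose range equals a given water-equivalent depth
#'
#' Inverse of [proton_range_mm()]; used to pick energy layers covering a
#' target's depth extent.
#' @inheritParams proton_range_mm
#' @param range_mm Water-equivalent range in mm.
#' @return Energy in MeV.
#' @export
energy_for_range_mm <- function(optics, range_mm) {
  (range_mm / (10 * optics$range_alpha))^(1 / optics$range_p)
}

check_energy <- function(optics, energy_MeV) {
  bad <- energy_MeV < optics$energy_range_MeV[1] |
    energy_MeV > optics$energy_range_MeV[2]
  if (any(bad)) {
    abort(sprintf(
      "energy %.4g MeV outside the optics validity range [%g, %g] MeV",
      energy_MeV[which(bad)[1]], optics$energy_range_MeV[1],
      optics$energy_range_MeV[2]))
  }
  invisible(TRUE)
}

#' In-air lateral sigma at isocenter
#' @inheritParams proton_range_mm
#' @return Sigma in mm.
#' @export
sigma_air_mm <- function(optics, energy_MeV) {
  check_energy(optics, energy_MeV)
  optics$sigma_ref_mm * (optics$energy_ref_MeV / energy_MeV)^optics$sigma_energy_exp
}

# Bragg-peak Gaussian sigma (proximal side) for a given range in mm.
peak_sigma_mm <- function(optics, range_mm) {
  optics$peak_width_frac * range_mm + 1
}

# Lateral sigma at radiological depth d (mm): quadrature sum of the in-air
# component and a linearly growing in-medium component.
sigma_at_depth_mm <- function(optics, energy_MeV, depth_mm) {
  sqrt(sigma_air_mm(optics, energy_MeV)^2 +
         (optics$depth_broadening * depth_mm)^2)
}

#' Analytic depth-dose curve
#'
#' Relative dose per unit fluence versus radiological depth: an entrance
#' plateau that shuts off past the range plus a Gaussian Bragg-peak term
#' centred at the range, with a sharper distal than proximal edge. The
#' shape is deliberately simple; only relative dosimetry (peak position,
#' distal gradient, plateau-to-peak ratio) matters downstream.
#'
#' @inheritParams proton_range_mm
#' @param depth_mm Radiological depth(s), mm (vectorised).
#' @param energy_MeV Single nominal energy, MeV.
#' @return Relative dose (dimensionless), same length as `depth_mm`.
#' @export
depth_dose <- function(optics, depth_mm, energy_MeV) {
  stopifnot(length(energy_MeV) == 1)
  R <- proton_range_mm(optics, energy_MeV)
  sig_peak <- peak_sigma_mm(optics, R)
  sig_distal <- optics$distal_falloff_frac * sig_peak
  z <- depth_mm - R
  plateau <- 1 / (1 + exp(z / (0.3 * sig_peak)))
  peak_sig <- ifelse(z <= 0, sig_peak, sig_distal)
  peak <- optics$peak_plateau_ratio * exp(-z^2 / (2 * peak_sig^2))
  out <- plateau + peak
  out[depth_mm < 0] <- 0
  out
}

#' Depth of maximum dose (Bragg-peak depth)
#'
#' Located by dense sampling of [depth_dose()] followed by local refinement.
#' @inheritParams depth_dose
#' @param density_scale Uniform relative-stopping-power multiplier; the
#'   geometric peak depth scales as `1 / density_scale`.
#' @return Geometric depth of the dose maximum, mm.
#' @export
bragg_peak_depth_mm <- function(optics, energy_MeV, density_scale = 1) {
  stopifnot(density_scale > 0)
  R <- proton_range_mm(optics, energy_MeV)
  z <- seq(0, 1.2 * R, length.out = 4001)
  d <- depth_dose(optics, z, energy_MeV)
  i <- which.max(d)
  lo <- z[max(1, i - 1)]; hi <- z[min(length(z), i + 1)]
  o <- stats::optimize(function(zz) depth_dose(optics, zz, energy_MeV),
                       c(lo, hi), maximum = TRUE)
  o$maximum / density_scale
}
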