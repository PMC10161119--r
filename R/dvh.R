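## Cumulative DVH curves and scalar DVH indices.

# Dose to the hottest p% of relative volume, by fractional-voxel linear
# interpolation of the descending sorted dose profile.
dvh_index_dp <- function(doses, p) {
  stopifnot(length(doses) >= 1, p > 0, p <= 100)
  s <- sort(doses, decreasing = TRUE)
  n <- length(s)
  c_target <- p / 100 * n
  if (n == 1) return(s[1])
  stats::approx(seq_len(n), s, xout = min(max(c_target, 1), n))$y
}

# Dose to the hottest `cc` of absolute volume.
dvh_index_dcc <- function(doses, voxel_cc, cc) {
  n <- length(doses)
  if (cc > n * voxel_cc + 1e-9) {
    abort(sprintf("requested volume %.3g cc exceeds structure volume %.3g cc",
                  cc, n * voxel_cc))
  }
  s <- sort(doses, decreasing = TRUE)
  if (n == 1) return(s[1])
  stats::approx(seq_len(n), s, xout = min(max(cc / voxel_cc, 1), n))$y
}

# % of structure volume receiving at least dose d (direct counting).
dvh_index_vd <- function(doses, d) 100 * mean(doses >= d)

#' Scalar DVH indices
#'
#' `d_percent(doses, p)` is the dose received by the hottest `p`% of the
#' structure's relative volume (e.g. D99); `d_cc(doses, voxel_cc, cc)` the
#' dose to the hottest `cc` of absolute volume (e.g. D0.03cc, dose to
#' 950 cc); `v_dose(doses, d)` the percent volume receiving at least `d`.
#' D-type indices use fractional-voxel linear interpolation of the sorted
#' voxel-dose profile; V-type uses direct counting.
#'
#' @param doses Numeric vector of voxel doses within the structure,
#'   cGy(RBE).
#' @param p Relative volume, percent (0, 100].
#' @param voxel_cc Volume of one voxel, cc.
#' @param cc Absolute volume, cc; must not exceed the structure volume.
#' @param d Dose threshold, cGy(RBE).
#' @return A scalar: dose in cGy(RBE) for D-type, percent for V-type.
#' @export
d_percent <- function(doses, p) dvh_index_dp(doses, p)

#' @rdname d_percent
#' @export
d_cc <- function(doses, voxel_cc, cc) dvh_index_dcc(doses, voxel_cc, cc)

#' @rdname d_percent
#' @export
v_dose <- function(doses, d) dvh_index_vd(doses, d)

#' Percent of prescription
#'
#' @param value Dose index value, cGy(RBE).
#' @param prescription_cGy Prescription dose, > 0.
#' @return `100 * value / prescription`, rounded to one decimal.
#' @export
#' @examples
#' percent_of_prescription(2846, 3000) # 94.9
percent_of_prescription <- function(value, prescription_cGy) {
  stopifnot(prescription_cGy > 0)
  round(100 * value / prescription_cGy, 1)
}

#' Cumulative dose-volume histogram of a structure
#'
#' @param dose A `dose_grid` (or 3-D dose array).
#' @param mask Logical array of the same dimensions (structure mask); must
#'   be nonempty.
#' @param bin_width_cGy Dose bin width (default 1 cGy(RBE)).
#' @param structure Structure name carried on the curve.
#' @param max_dose_cGy Upper end of the dose axis; defaults to the maximum
#'   structure dose plus one bin. Supply a common value when curves from
#'   several scenarios must share a dose axis.
#' @return A `dvh_curve` tibble: `structure`, `dose_cGy` (bin edges),
#'   `volume_pct` (cumulative, non-increasing, 100% at zero dose), with
#'   the structure volume in cc as attribute `volume_cc`.
#' @export
compute_dvh <- function(dose, mask, bin_width_cGy = 1, structure = "structure",
                        max_dose_cGy = NULL) {
  dvec <- as.vector(unclass(dose))[as.vector(mask)]
  if (!length(dvec)) abort("empty structure mask")
  vox_cc <- attr(dose, "voxel_cc") %||% 1
  top <- max_dose_cGy %||% (max(dvec) + bin_width_cGy)
  edges <- seq(0, top, by = bin_width_cGy)
  if (edges[length(edges)] < top) edges <- c(edges, top)
  vol <- vapply(edges, function(e) 100 * mean(dvec >= e), numeric(1))
  out <- tibble(structure = structure, dose_cGy = edges, volume_pct = vol)
  base::structure(out, class = c("dvh_curve", class(out)),
                  volume_cc = length(dvec) * vox_cc)
}

#' Banded DVH: pointwise scenario envelopes
#'
#' Pointwise minimum and maximum of the per-scenario DVH curves per
#' structure, with nominal curves carried alongside (nominal curves may
#' lie outside the band: they are not part of the perturbed set).
#'
#' @param scenario_curves Tibble of per-scenario curves: columns
#'   `scenario`, `structure`, `dose_cGy`, `volume_pct`, all scenarios on a
#'   shared dose axis per structure.
#' @param nominal_curves Optional tibble of nominal curves (`structure`,
#'   `dose_cGy`, `volume_pct`).
#' @return A `banded_dvh` tibble: `structure`, `dose_cGy`, `vol_min`,
#'   `vol_max`, and `vol_nominal` when supplied.
#' @export
banded_dvh <- function(scenario_curves, nominal_curves = NULL) {
  n_axis <- scenario_curves %>%
    group_by(.data$structure, .data$scenario) %>%
    summarise(k = dplyr::n(), .groups = "drop") %>%
    group_by(.data$structure) %>%
    summarise(ok = length(unique(.data$k)) == 1, .groups = "drop")
  if (!all(n_axis$ok)) {
    abort("scenario curves do not share a dose axis within each structure")
  }
  band <- scenario_curves %>%
    group_by(.data$structure, .data$dose_cGy) %>%
    summarise(vol_min = min(.data$volume_pct),
              vol_max = max(.data$volume_pct), .groups = "drop")
  if (!is.null(nominal_curves)) {
    band <- left_join(band,
                      nominal_curves %>%
                        select("structure", "dose_cGy",
                               vol_nominal = "volume_pct"),
                      by = c("structure", "dose_cGy"))
  }
  structure(band, class = c("banded_dvh", class(band)))
}
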