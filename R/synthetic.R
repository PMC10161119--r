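#' Ground-truth spot delivery error model
#'
#' Defines the error structure the synthetic log-file generator injects:
#' systematic per-axis position offsets (constants, or functions of gantry
#' angle and nominal energy), Gaussian random per-spot position scatter,
#' multiplicative monitor-unit noise, and per-pulse positional jitter
#' around the spot's delivered position. Delivered-minus-planned position
#' errors on clinical systems are Gaussian with mean magnitude of order
#' 1 mm or less; the defaults sit in that regime.
#'
#' @param systematic_x_mm,systematic_y_mm Constant offsets (mm) or
#'   functions `f(gantry_angle_deg, nominal_energy_MeV)` returning mm.
#' @param random_sigma_x_mm,random_sigma_y_mm Gaussian SDs of the per-spot
#'   position error, mm; `>= 0`.
#' @param mu_noise_frac SD of the multiplicative MU error (fraction of the
#'   planned MU); must be `< 1`.
#' @param pulse_jitter_sigma_mm SD of the extra per-pulse scatter around
#'   the spot's delivered position, mm. The jitter is recentred within
#'   each spot so the MU-weighted pulse mean reproduces the delivered
#'   position exactly.
#' @param layer_shift_sigma_mm Optional SD of a shared per-layer offset
#'   (mm); default 0 treats spots as independent.
#' @return An object of class `error_truth`.
#' @export
#' @examples
#' error_truth(systematic_x_mm = 0.5, random_sigma_x_mm = 0.3,
#'             random_sigma_y_mm = 0.3)
error_truth <- function(systematic_x_mm = 0, systematic_y_mm = 0,
                        random_sigma_x_mm = 0.3, random_sigma_y_mm = 0.3,
                        mu_noise_frac = 0.01,
                        pulse_jitter_sigma_mm = 0.2,
                        layer_shift_sigma_mm = 0) {
  stopifnot(random_sigma_x_mm >= 0, random_sigma_y_mm >= 0,
            mu_noise_frac >= 0, mu_noise_frac < 1,
            pulse_jitter_sigma_mm >= 0, layer_shift_sigma_mm >= 0)
  for (f in list(systematic_x_mm, systematic_y_mm)) {
    stopifnot(is.function(f) || is_scalar_number(f))
  }
  structure(list(systematic_x_mm = systematic_x_mm,
                 systematic_y_mm = systematic_y_mm,
                 random_sigma_x_mm = random_sigma_x_mm,
                 random_sigma_y_mm = random_sigma_y_mm,
                 mu_noise_frac = mu_noise_frac,
                 pulse_jitter_sigma_mm = pulse_jitter_sigma_mm,
                 layer_shift_sigma_mm = layer_shift_sigma_mm),
            class = "error_truth")
}

#' Generate pulse-level machine log files for a plan
#'
#' The delivery system splits each spot into pulses and repeats pulses
#' until the spot's MU has been delivered. This generator emulates that
#' record: per spot it draws a delivered position (planned + systematic +
#' Gaussian random error) and a delivered MU (planned times a
#' multiplicative noise factor), splits the MU uniformly across pulses,
#' and scatters pulse positions around the delivered position with
#' recentred jitter so that the MU-weighted pulse mean equals the drawn
#' delivered position exactly.
#'
#' @param plan A `treatment_plan`.
#' @param truth An [error_truth()].
#' @param pulses_per_spot Integer `>= 1`; pulses recorded per spot.
#' @param seed Integer seed; output is bit-reproducible from
#'   `(plan, truth, pulses_per_spot, seed)`.
#' @param plan_id Identifier written into each log header.
#' @return A list of `proton_log` objects, one per beam, each with a
#'   `header` list and a `pulses` tibble (9 columns: pulse/spot indices,
#'   nominal energy, target and actual x/y at isocenter in mm, target and
#'   actual MU).
#' @export
generate_log_files <- function(plan, truth, pulses_per_spot = 3, seed = 1,
                               plan_id = "synthetic-plan") {
  stopifnot(inherits(plan, "treatment_plan"), inherits(truth, "error_truth"),
            pulses_per_spot >= 1)
  pulses_per_spot <- as.integer(pulses_per_spot)
  lapply(seq_len(nrow(plan$beams)), function(b) {
    sp <- plan$spots[plan$spots$beam_id == b, ]
    gantry <- plan$beams$gantry_angle_deg[b]
    snout <- plan$beams$snout_extension_mm[b]
    with_seed(derive_seed(seed, paste0("logfile-beam-", b)), {
      n <- nrow(sp)
      sys_x <- resolve_field(truth$systematic_x_mm, gantry, sp$energy_MeV)
      sys_y <- resolve_field(truth$systematic_y_mm, gantry, sp$energy_MeV)
      layer_dx <- layer_dy <- 0
      if (truth$layer_shift_sigma_mm > 0) {
        lays <- sort(unique(sp$layer))
        ldx <- rnorm(length(lays), 0, truth$layer_shift_sigma_mm)
        ldy <- rnorm(length(lays), 0, truth$layer_shift_sigma_mm)
        layer_dx <- ldx[match(sp$layer, lays)]
        layer_dy <- ldy[match(sp$layer, lays)]
      }
      del_x <- sp$x_mm + sys_x + layer_dx + rnorm(n, 0, truth$random_sigma_x_mm)
      del_y <- sp$y_mm + sys_y + layer_dy + rnorm(n, 0, truth$random_sigma_y_mm)
      del_mu <- sp$mu * pmax(1 + rnorm(n, 0, truth$mu_noise_frac), 1e-6)

      k <- pulses_per_spot
      idx <- rep(seq_len(n), each = k)
      tgt_mu_p <- sp$mu[idx] / k
      act_mu_p <- del_mu[idx] / k
      jx <- rnorm(n * k, 0, truth$pulse_jitter_sigma_mm)
      jy <- rnorm(n * k, 0, truth$pulse_jitter_sigma_mm)
      if (k > 1) {
        # recentre jitter (MU-weighted; weights equal within a spot)
        jx <- unname(jx - rep(tapply(jx, idx, mean), each = k))
        jy <- unname(jy - rep(tapply(jy, idx, mean), each = k))
      } else {
        jx[] <- 0; jy[] <- 0
      }
      pulses <- tibble(
        pulse_index = seq_len(n * k),
        spot_index = sp$spot_id[idx],
        nominal_energy_MeV = sp$energy_MeV[idx],
        target_x_mm = sp$x_mm[idx], target_y_mm = sp$y_mm[idx],
        actual_x_mm = del_x[idx] + jx, actual_y_mm = del_y[idx] + jy,
        target_MU = tgt_mu_p, actual_MU = act_mu_p)
      new_proton_log(
        header = list(date = "2026-01-01", plan_id = plan_id, beam_id = b,
                      gantry_angle_deg = gantry, snout_extension_mm = snout,
                      total_prescribed_MU = sum(sp$mu)),
        pulses = pulses)
    })
  })
}

#' Generate a QA spot-grid session
#'
#' Emulates a periodic QA measurement: an evenly spaced square spot
#' pattern (default 11 x 11) delivered at a gantry angle, with for each
#' spot a "recorded" position (the log-file value, drawn from the truth's
#' systematic + random error) and an independently noisy "measured"
#' position from a scintillation detector, quantized to the detector's
#' spatial resolution (default 0.5 mm).
#'
#' @param gantry_angle_deg Gantry angle of the session.
#' @param truth An [error_truth()].
#' @param n_side Odd grid dimension (default 11, i.e. 121 spots).
#' @param pitch_mm Grid pitch, mm.
#' @param detector_resolution_mm Quantization step of the measured
#'   positions; 0 disables quantization.
#' @param detector_noise_sigma_mm Gaussian SD of the detector position
#'   noise before quantization, mm (default 0.15 mm, well under typical
#'   recorded-vs-measured disagreements).
#' @param energy_MeV Nominal energy used to resolve energy-dependent
#'   systematic terms.
#' @param seed Integer seed.
#' @return A `qa_session`: tibble with nominal, recorded and measured x/y
#'   per spot, plus session attributes.
#' @export
generate_qa_grid <- function(gantry_angle_deg, truth,
                             n_side = 11, pitch_mm = 20,
                             detector_resolution_mm = 0.5,
                             detector_noise_sigma_mm = 0.15,
                             energy_MeV = 150, seed = 1) {
  stopifnot(inherits(truth, "error_truth"), n_side >= 1, n_side %% 2 == 1,
            pitch_mm > 0, detector_resolution_mm >= 0,
            detector_noise_sigma_mm >= 0)
  half <- (n_side - 1) / 2
  g <- expand.grid(nominal_x_mm = pitch_mm * (-half:half),
                   nominal_y_mm = pitch_mm * (-half:half))
  n <- nrow(g)
  with_seed(derive_seed(seed, paste0("qa-", gantry_angle_deg)), {
    sys_x <- resolve_field(truth$systematic_x_mm, gantry_angle_deg, energy_MeV)
    sys_y <- resolve_field(truth$systematic_y_mm, gantry_angle_deg, energy_MeV)
    rec_x <- g$nominal_x_mm + sys_x + rnorm(n, 0, truth$random_sigma_x_mm)
    rec_y <- g$nominal_y_mm + sys_y + rnorm(n, 0, truth$random_sigma_y_mm)
    mea_x <- rec_x + rnorm(n, 0, detector_noise_sigma_mm)
    mea_y <- rec_y + rnorm(n, 0, detector_noise_sigma_mm)
    if (detector_resolution_mm > 0) {
      mea_x <- round(mea_x / detector_resolution_mm) * detector_resolution_mm
      mea_y <- round(mea_y / detector_resolution_mm) * detector_resolution_mm
    }
    out <- tibble(spot = seq_len(n),
                  nominal_x_mm = g$nominal_x_mm, nominal_y_mm = g$nominal_y_mm,
                  recorded_x_mm = rec_x, recorded_y_mm = rec_y,
                  measured_x_mm = mea_x, measured_y_mm = mea_y)
    structure(out, class = c("qa_session", class(out)),
              gantry_angle_deg = gantry_angle_deg,
              detector_resolution_mm = detector_resolution_mm,
              pitch_mm = pitch_mm)
  })
}
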