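#' Scenario-set configuration for robustness evaluation
#'
#' The default ("isotropic_corners") interpretation of isotropic setup
#' shifts crosses the 8 simultaneous sign combinations of a +/- delta
#' shift on the right-left, inferior-superior and posterior-anterior axes
#' with the two density scales, giving 16 perturbed scenarios. An
#' "axis_aligned" mode (6 single-axis shifts x 2 density scales = 12) is
#' also provided. Typical shift magnitudes: 5 mm for a breast plan
#' evaluated with generous margins, 3 mm for an intracranial plan.
#'
#' @param shift_mm Setup shift magnitude delta, mm; `>= 0`.
#' @param density_frac Density (stopping-power) uncertainty fraction, in
#'   `[0, 0.2)`; default 0.035.
#' @param mode `"isotropic_corners"` or `"axis_aligned"`.
#' @param include_nominal Append the unperturbed scenario to the set
#'   (default `FALSE`; the nominal plan is usually evaluated separately).
#' @return A `scenario_config`.
#' @export
scenario_config <- function(shift_mm = 5, density_frac = 0.035,
                            mode = c("isotropic_corners", "axis_aligned"),
                            include_nominal = FALSE) {
  mode <- match.arg(mode)
  stopifnot(shift_mm >= 0, density_frac >= 0, density_frac < 0.2)
  structure(list(shift_mm = shift_mm, density_frac = density_frac,
                 mode = mode, include_nominal = include_nominal),
            class = "scenario_config")
}

#' Generate the perturbation scenario set
#'
#' @param config A [scenario_config()].
#' @return Tibble with one row per scenario: `label`, `shift_rl_mm`,
#'   `shift_is_mm`, `shift_pa_mm`, `density_scale`. With the defaults
#'   (corner mode, delta = 5 mm, 3.5% density) this is 16 scenarios. A
#'   degenerate config (delta = 0, density 0) collapses to a single
#'   nominal-equivalent scenario.
#' @export
generate_scenarios <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  d <- config$shift_mm; f <- config$density_frac
  shifts <- if (config$mode == "isotropic_corners") {
    as.matrix(expand.grid(x = c(-d, d), y = c(-d, d), z = c(-d, d)))
  } else {
    rbind(c(-d, 0, 0), c(d, 0, 0), c(0, -d, 0), c(0, d, 0),
          c(0, 0, -d), c(0, 0, d))
  }
  scales <- unique(c(1 - f, 1 + f))
  grid <- expand.grid(s = seq_len(nrow(shifts)), g = seq_along(scales))
  out <- tibble(
    shift_rl_mm = shifts[grid$s, 1],
    shift_is_mm = shifts[grid$s, 2],
    shift_pa_mm = shifts[grid$s, 3],
    density_scale = scales[grid$g])
  out <- unique(out)
  out <- mutate(out, label = sprintf(
    "shift(%+g,%+g,%+g)mm_rho%.3f", .data$shift_rl_mm, .data$shift_is_mm,
    .data$shift_pa_mm, .data$density_scale), .before = 1)
  if (config$include_nominal) {
    out <- bind_rows(tibble(label = "nominal", shift_rl_mm = 0,
                            shift_is_mm = 0, shift_pa_mm = 0,
                            density_scale = 1), out)
  }
  out
}

scenario_from_row <- function(row) {
  scenario(shift_mm = c(row$shift_rl_mm, row$shift_is_mm, row$shift_pa_mm),
           density_scale = row$density_scale, label = row$label)
}

#' Evaluate a plan under a scenario set
#'
#' Computes one dose distribution per scenario (plus the nominal), and per
#' structure the cumulative DVH on a shared dose axis and the raw
#' structure voxel doses (kept for exact index computation). Fully
#' deterministic.
#'
#' @param plan A normalized `treatment_plan` (the MU scaling is frozen; no
#'   re-normalization happens here).
#' @param phantom,optics Engine inputs.
#' @param structures Character vector of structure names; default all
#'   structures in the phantom.
#' @param scenarios Tibble from [generate_scenarios()].
#' @param bin_width_cGy DVH bin width.
#' @return A `robustness_eval`: `curves` (per-scenario DVH tibble),
#'   `nominal_curves`, `structure_doses` (nested list scenario ->
#'   structure -> voxel doses), `nominal_doses`, `voxel_cc`, `scenarios`,
#'   `prescription_cGy`.
#' @export
evaluate_scenarios <- function(plan, phantom, optics = spot_optics(),
                               structures = names(phantom$masks),
                               scenarios = generate_scenarios(),
                               bin_width_cGy = 1) {
  stopifnot(nrow(scenarios) >= 1, length(structures) >= 1)
  masks <- lapply(structures, function(s) as.vector(get_mask(phantom, s)))
  names(masks) <- structures
  # dose is only needed inside the evaluated structures: restrict the
  # engine to their voxel union
  union_idx <- which(Reduce(`|`, masks))
  local_idx <- lapply(masks, function(m) match(which(m), union_idx))

  pick <- function(dose_vec) lapply(local_idx, function(i) dose_vec[i])
  nominal_doses <- pick(compute_dose_at(plan, phantom, optics, scenario(),
                                        voxels = union_idx)$dose)
  scen_doses <- vector("list", nrow(scenarios))
  names(scen_doses) <- scenarios$label
  for (i in seq_len(nrow(scenarios))) {
    scen_doses[[i]] <- pick(compute_dose_at(
      plan, phantom, optics, scenario_from_row(scenarios[i, ]),
      voxels = union_idx)$dose)
  }
  top <- max(vapply(scen_doses, function(s) max(vapply(s, max, numeric(1))),
                    numeric(1)),
             vapply(nominal_doses, max, numeric(1))) + bin_width_cGy
  curve_of <- function(doses, label, str) {
    cv <- compute_dvh(doses, rep(TRUE, length(doses)),
                      bin_width_cGy = bin_width_cGy, structure = str,
                      max_dose_cGy = top)
    cv$scenario <- label
    as_tibble(cv)[c("scenario", "structure", "dose_cGy", "volume_pct")]
  }
  curves <- bind_rows(lapply(seq_len(nrow(scenarios)), function(i) {
    bind_rows(lapply(structures, function(s) {
      curve_of(scen_doses[[i]][[s]], scenarios$label[i], s)
    }))
  }))
  nominal_curves <- bind_rows(lapply(structures, function(s) {
    cv <- curve_of(nominal_doses[[s]], "nominal", s)
    cv$scenario <- NULL
    cv
  }))
  structure(list(curves = curves, nominal_curves = nominal_curves,
                 structure_doses = scen_doses, nominal_doses = nominal_doses,
                 voxel_cc = phantom$voxel_cc, scenarios = scenarios,
                 prescription_cGy = plan$prescription_cGy,
                 bin_width_cGy = bin_width_cGy),
            class = "robustness_eval")
}

#' @export
print.robustness_eval <- function(x, ...) {
  cat(sprintf("<robustness_eval> %d scenario(s) x %d structure(s); Rx %g cGy(RBE)\n",
              nrow(x$scenarios), length(x$nominal_doses), x$prescription_cGy))
  invisible(x)
}

#' Specify DVH indices for reporting
#'
#' @param index_id Short label (e.g. "D99", "D0.03cc", "V95Rx").
#' @param type One of `"d_percent"`, `"d_cc"`, `"v_dose"`.
#' @param arg The index argument: relative volume % for `d_percent`,
#'   absolute cc for `d_cc`, dose threshold in cGy(RBE) for `v_dose`.
#' @param structure Structure the index applies to.
#' @return One-row tibble; rows from several calls can be bound together.
#' @export
dvh_index_spec <- function(index_id, type, arg, structure) {
  stopifnot(type %in% c("d_percent", "d_cc", "v_dose"))
  tibble(index_id = index_id, type = type, arg = arg, structure = structure)
}

eval_index <- function(doses, voxel_cc, type, arg) {
  switch(type,
         d_percent = dvh_index_dp(doses, arg),
         d_cc = dvh_index_dcc(doses, voxel_cc, arg),
         v_dose = dvh_index_vd(doses, arg))
}

#' Per-scenario DVH index values
#'
#' Evaluates each requested index on the stored structure voxel doses of
#' every scenario (and the nominal). D_cc indices whose volume spans fewer
#' than 3 voxels are flagged resolution-limited.
#'
#' @param eval A `robustness_eval`.
#' @param index_specs Tibble from [dvh_index_spec()] rows.
#' @return Tibble: `scenario` ("nominal" included), `structure`,
#'   `index_id`, `value`, `resolution_limited`.
#' @export
scenario_indices <- function(eval, index_specs) {
  stopifnot(inherits(eval, "robustness_eval"))
  labs <- c("nominal", names(eval$structure_doses))
  bind_rows(lapply(labs, function(lab) {
    sd <- if (lab == "nominal") eval$nominal_doses else eval$structure_doses[[lab]]
    bind_rows(lapply(seq_len(nrow(index_specs)), function(j) {
      sp <- index_specs[j, ]
      doses <- sd[[sp$structure]]
      if (is.null(doses)) {
        abort(sprintf("structure '%s' was not evaluated", sp$structure))
      }
      tibble(scenario = lab, structure = sp$structure,
             index_id = sp$index_id,
             value = eval_index(doses, eval$voxel_cc, sp$type, sp$arg),
             resolution_limited = sp$type == "d_cc" &&
               sp$arg < 3 * eval$voxel_cc)
    }))
  }))
}

#' Worst-case DVH index table
#'
#' For every structure-index pair independently: the minimum and maximum
#' over perturbed scenarios, alongside the nominal value. The scenario
#' achieving the minimum for one structure need not be the one achieving
#' it for another.
#'
#' @param indices Tibble from [scenario_indices()].
#' @return Tibble: `structure`, `index_id`, `min`, `max`, `nominal`,
#'   `argmin_scenario`, `argmax_scenario`.
#' @export
worst_case_table <- function(indices) {
  pert <- indices[indices$scenario != "nominal", ]
  nom <- indices[indices$scenario == "nominal", ]
  out <- pert %>%
    group_by(.data$structure, .data$index_id) %>%
    summarise(min = min(.data$value), max = max(.data$value),
              argmin_scenario = .data$scenario[which.min(.data$value)],
              argmax_scenario = .data$scenario[which.max(.data$value)],
              .groups = "drop")
  left_join(out,
            nom %>% select("structure", "index_id", nominal = "value"),
            by = c("structure", "index_id")) %>%
    select("structure", "index_id", "min", "max", "nominal",
           "argmin_scenario", "argmax_scenario")
}

#' Signed differences between two worst-case tables
#'
#' Cell-wise `b - a` for matching structure/index rows (e.g. the
#' ML-predicted plan minus the clinical plan).
#'
#' @param report_a,report_b Tibbles from [worst_case_table()] with
#'   matching structure/index rows.
#' @return Tibble: `structure`, `index_id`, `diff_min`, `diff_max`,
#'   `diff_nominal`.
#' @export
compare_plans <- function(report_a, report_b) {
  j <- dplyr::inner_join(report_a, report_b,
                         by = c("structure", "index_id"),
                         suffix = c("_a", "_b"))
  if (nrow(j) != nrow(report_a) || nrow(j) != nrow(report_b)) {
    abort("reports do not share the same structure/index rows")
  }
  tibble(structure = j$structure, index_id = j$index_id,
         diff_min = j$min_b - j$min_a,
         diff_max = j$max_b - j$max_a,
         diff_nominal = j$nominal_b - j$nominal_a)
}

#' 95/95 robustness verdict
#'
#' A plan is robust if in every perturbed scenario at least 95% of the
#' target volume receives at least 95% of the prescription dose. The
#' threshold is inclusive: a worst-case V95 of exactly 95.0% passes.
#'
#' @param eval A `robustness_eval` whose structures include the target.
#' @param target Target structure name (default "CTV").
#' @param volume_threshold_pct,dose_threshold_frac The two 95s of the
#'   criterion.
#' @return List: `pass` (logical), `worst_v95_pct`, `per_scenario` tibble
#'   (scenario, v95_pct, pass), `failing_scenarios`.
#' @export
robustness_check <- function(eval, target = "CTV",
                             volume_threshold_pct = 95,
                             dose_threshold_frac = 0.95) {
  stopifnot(inherits(eval, "robustness_eval"))
  if (is.null(eval$nominal_doses[[target]])) {
    abort(sprintf("target structure '%s' missing from the evaluation", target))
  }
  d95 <- dose_threshold_frac * eval$prescription_cGy
  per <- bind_rows(lapply(names(eval$structure_doses), function(lab) {
    v <- dvh_index_vd(eval$structure_doses[[lab]][[target]], d95)
    tibble(scenario = lab, v95_pct = v, pass = v >= volume_threshold_pct)
  }))
  list(pass = all(per$pass), worst_v95_pct = min(per$v95_pct),
       per_scenario = per,
       failing_scenarios = per$scenario[!per$pass])
}
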