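## End-to-end pipeline orchestration over a workspace directory.
##
## Stage order: synth -> qa / train -> predict -> dose -> robust -> report.
## Every stage writes a JSON manifest (inputs hashed, seed, counts) so a
## rerun with the same config and seed is byte-reproducible; all
## randomness flows from the single global seed via named substreams.

STAGES <- c("synth", "qa", "train", "predict", "dose", "robust", "report")
STAGE_DEPS <- list(synth = character(0), qa = "synth", train = "synth",
                   predict = c("synth", "train"), dose = "predict",
                   robust = "dose", report = "robust")

#' Pipeline configuration
#'
#' Bundles every sub-configuration of the workflow plus the workspace path
#' and the single global seed all stages derive their randomness from.
#'
#' @param workspace Directory for stage outputs (created if missing).
#' @param seed Global integer seed.
#' @param phantom A [phantom_spec()].
#' @param plan A [plan_spec()].
#' @param truth An [error_truth()].
#' @param train A [train_config()] (its seed is overridden by the global
#'   seed's "train" substream).
#' @param optics A [spot_optics()].
#' @param scenarios A [scenario_config()].
#' @param pulses_per_spot Pulses per spot in the generated log files.
#' @param qa_gantry_angles_deg Gantry angles of the generated QA sessions.
#' @param target Target structure name.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(workspace, seed = 1,
                            phantom = phantom_spec(
                              structures = list(
                                struct_sphere("CTV", c(0, 0, 0), 15))),
                            plan = plan_spec(),
                            truth = error_truth(),
                            train = train_config(),
                            optics = spot_optics(),
                            scenarios = scenario_config(),
                            pulses_per_spot = 3,
                            qa_gantry_angles_deg = c(0, 90, 180),
                            target = "CTV") {
  stopifnot(is.character(workspace), length(workspace) == 1)
  train$seed <- derive_seed(seed, "train")
  structure(list(workspace = workspace, seed = seed, phantom = phantom,
                 plan = plan, truth = truth, train = train, optics = optics,
                 scenarios = scenarios, pulses_per_spot = pulses_per_spot,
                 qa_gantry_angles_deg = qa_gantry_angles_deg,
                 target = target),
            class = "pipeline_config")
}

ws_path <- function(config, ...) file.path(config$workspace, ...)

manifest_path <- function(config, stage) {
  ws_path(config, sprintf("manifest_%s.json", stage))
}

write_manifest <- function(config, stage, outputs, counts = list()) {
  files <- outputs[file.exists(outputs)]
  deps <- vapply(STAGE_DEPS[[stage]], function(s) manifest_path(config, s),
                 character(1))
  inputs <- if (length(deps)) {
    as.list(stats::setNames(as.character(tools::md5sum(deps)),
                            basename(deps)))
  } else {
    stats::setNames(list(), character(0))
  }
  jsonlite::write_json(
    list(stage = stage, seed = config$seed,
         package_version = as.character(utils::packageVersion("spotrobust")),
         inputs = inputs,
         outputs = as.list(stats::setNames(
           as.character(tools::md5sum(files)), basename(files))),
         counts = counts),
    manifest_path(config, stage), auto_unbox = TRUE, digits = NA)
}

check_upstream <- function(config, stage) {
  for (dep in STAGE_DEPS[[stage]]) {
    if (!file.exists(manifest_path(config, dep))) {
      abort(sprintf("stage '%s' requires stage '%s' to run first",
                    stage, dep))
    }
  }
}

#' Run one pipeline stage
#'
#' @param stage One of `"synth"`, `"qa"`, `"train"`, `"predict"`,
#'   `"dose"`, `"robust"`, `"report"`.
#' @param config A [pipeline_config()].
#' @return The stage's result object, invisibly; outputs and a manifest
#'   are written into the workspace.
#' @export
run_stage <- function(stage, config) {
  stage <- match.arg(stage, STAGES)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$workspace, showWarnings = FALSE, recursive = TRUE)
  check_upstream(config, stage)
  res <- switch(stage,
                synth = stage_synth(config),
                qa = stage_qa(config),
                train = stage_train(config),
                predict = stage_predict(config),
                dose = stage_dose(config),
                robust = stage_robust(config),
                report = make_report(config))
  invisible(res)
}

#' Run the whole pipeline
#'
#' @param config A [pipeline_config()].
#' @return Named list of all stage results.
#' @export
run_pipeline <- function(config) {
  stats::setNames(lapply(STAGES, function(s) run_stage(s, config)), STAGES)
}

# phantom and optics are cheap and deterministic: rebuilt from config
# rather than round-tripped through the grid container.
config_phantom <- function(config) generate_phantom(config$phantom)

stage_synth <- function(config) {
  phantom <- config_phantom(config)
  plan <- generate_plan(phantom, config$plan,
                        seed = derive_seed(config$seed, "synth"),
                        optics = config$optics)
  norm <- normalize_plan(plan, phantom, config$optics,
                         structure = config$target)
  logs <- generate_log_files(norm$plan, config$truth,
                             pulses_per_spot = config$pulses_per_spot,
                             seed = derive_seed(config$seed, "synth"))
  dir.create(ws_path(config, "logs"), showWarnings = FALSE, recursive = TRUE)
  log_paths <- vapply(seq_along(logs), function(b) {
    p <- ws_path(config, "logs", sprintf("beam-%02d.csv", b))
    write_log_file(logs[[b]], p)
    p
  }, character(1))
  plan_path <- ws_path(config, "plan_clinical.json")
  write_plan(norm$plan, plan_path)
  vol_path <- ws_path(config, "structure_volumes.csv")
  utils::write.csv(phantom$volumes, vol_path, row.names = FALSE)
  write_manifest(config, "synth", c(plan_path, vol_path, log_paths),
                 counts = list(n_spots = n_spots(norm$plan),
                               n_beams = nrow(norm$plan$beams),
                               normalization_factor = norm$factor))
  list(phantom = phantom, plan = norm$plan, factor = norm$factor,
       logs = logs)
}

stage_qa <- function(config) {
  sessions <- lapply(config$qa_gantry_angles_deg, function(g) {
    generate_qa_grid(g, config$truth,
                     seed = derive_seed(config$seed, "qa"))
  })
  tab <- qa_agreement_table(sessions)
  p <- ws_path(config, "qa_agreement.csv")
  utils::write.csv(tab, p, row.names = FALSE)
  write_manifest(config, "qa", p,
                 counts = list(n_sessions = length(sessions),
                               n_spots = sum(tab$n_spots)))
  list(sessions = sessions, table = tab)
}

stage_train <- function(config) {
  log_files <- sort(list.files(ws_path(config, "logs"), full.names = TRUE,
                               pattern = "\\.csv$"))
  logs <- lapply(log_files, parse_log_file)
  ds <- assemble_dataset(logs)
  model <- train_error_model(ds$features, ds$targets, config$train)
  mp <- ws_path(config, "model.json")
  save_error_model(model, mp)
  gp <- ws_path(config, "model_metrics.csv")
  utils::write.csv(glance(model), gp, row.names = FALSE)
  write_manifest(config, "train", c(mp, gp),
                 counts = list(n_spots = nrow(ds$features),
                               n_excluded_zero_mu = ds$n_excluded))
  list(model = model, dataset = ds)
}

stage_predict <- function(config) {
  plan <- read_plan(ws_path(config, "plan_clinical.json"))
  model <- load_error_model(ws_path(config, "model.json"))
  pred <- predict_plan(model, plan)
  dir.create(ws_path(config, "plf"), showWarnings = FALSE, recursive = TRUE)
  plf_paths <- vapply(plan$beams$beam_id, function(b) {
    p <- ws_path(config, "plf", sprintf("beam-%02d.csv", b))
    write_pseudo_log_file(plan, b, pred[pred$beam_id == b, ], p)
    p
  }, character(1))
  write_manifest(config, "predict", plf_paths,
                 counts = list(n_spots = nrow(pred)))
  list(predictions = pred)
}

stage_dose <- function(config) {
  phantom <- config_phantom(config)
  plan <- read_plan(ws_path(config, "plan_clinical.json"))
  plf_files <- sort(list.files(ws_path(config, "plf"), full.names = TRUE,
                               pattern = "\\.csv$"))
  delivered <- bind_rows(lapply(plf_files, function(p) {
    sp <- aggregate_pulses(parse_log_file(p))
    tibble(spot_id = sp$spot_index, x_mm = sp$delivered_x_mm,
           y_mm = sp$delivered_y_mm, mu = sp$delivered_mu)
  }))
  # the ML plan reuses the clinical MU scaling frozen at synth time:
  # predictions were made from the normalized plan, so no re-normalization
  plan_ml <- plan_with_spots(plan, delivered)
  write_plan(plan_ml, ws_path(config, "plan_ml.json"))
  dose_cl <- compute_dose(plan, phantom, config$optics)
  dose_ml <- compute_dose(plan_ml, phantom, config$optics)
  mask <- get_mask(phantom, config$target)
  summarise_one <- function(dose, label) {
    dvec <- as.vector(unclass(dose))[as.vector(mask)]
    tibble(plan = label,
           n_spots_deleted = nrow(attr(dose, "deleted_spots")),
           deleted_mu = sum(attr(dose, "deleted_spots")$mu),
           d99_cGy = dvh_index_dp(dvec, 99),
           d003cc_cGy = dvh_index_dcc(dvec, phantom$voxel_cc, 0.03))
  }
  summary <- bind_rows(summarise_one(dose_cl, "clinical"),
                       summarise_one(dose_ml, "ml_predicted"))
  sp <- ws_path(config, "dose_summary.csv")
  utils::write.csv(summary, sp, row.names = FALSE)
  write_manifest(config, "dose", c(sp, ws_path(config, "plan_ml.json")),
                 counts = list(
                   deleted_clinical = summary$n_spots_deleted[1],
                   deleted_ml = summary$n_spots_deleted[2]))
  list(plan_clinical = plan, plan_ml = plan_ml, summary = summary)
}

default_index_specs <- function(phantom, target) {
  specs <- bind_rows(
    dvh_index_spec("D99", "d_percent", 99, target),
    dvh_index_spec("D0.03cc", "d_cc", 0.03, target))
  for (s in setdiff(names(phantom$masks), target)) {
    vol <- phantom$volumes$volume_cc[phantom$volumes$structure == s]
    cc <- min(5, round(0.5 * vol, 2))
    specs <- bind_rows(specs,
                       dvh_index_spec(sprintf("D%gcc", cc), "d_cc", cc, s))
  }
  specs
}

stage_robust <- function(config) {
  phantom <- config_phantom(config)
  plan_cl <- read_plan(ws_path(config, "plan_clinical.json"))
  plan_ml <- read_plan(ws_path(config, "plan_ml.json"))
  scen <- generate_scenarios(config$scenarios)
  specs <- default_index_specs(phantom, config$target)
  out <- list()
  for (nm in c("clinical", "ml")) {
    plan <- if (nm == "clinical") plan_cl else plan_ml
    ev <- evaluate_scenarios(plan, phantom, config$optics,
                             scenarios = scen)
    idx <- scenario_indices(ev, specs)
    band <- banded_dvh(ev$curves, ev$nominal_curves)
    chk <- robustness_check(ev, target = config$target)
    utils::write.csv(idx, ws_path(config, sprintf("indices_%s.csv", nm)),
                     row.names = FALSE)
    utils::write.csv(band, ws_path(config, sprintf("banded_dvh_%s.csv", nm)),
                     row.names = FALSE)
    out[[nm]] <- list(eval = ev, indices = idx, band = band, check = chk)
  }
  wp <- ws_path(config, "worst_case_clinical.csv")
  utils::write.csv(worst_case_table(out$clinical$indices), wp,
                   row.names = FALSE)
  wp2 <- ws_path(config, "worst_case_ml.csv")
  utils::write.csv(worst_case_table(out$ml$indices), wp2, row.names = FALSE)
  jsonlite::write_json(
    lapply(out, function(o) list(pass = o$check$pass,
                                 worst_v95_pct = o$check$worst_v95_pct,
                                 failing = o$check$failing_scenarios)),
    ws_path(config, "robust_checks.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(config, "robust",
                 c(ws_path(config, c("indices_clinical.csv",
                                     "indices_ml.csv",
                                     "banded_dvh_clinical.csv",
                                     "banded_dvh_ml.csv")), wp, wp2),
                 counts = list(n_scenarios = nrow(scen),
                               pass_clinical = out$clinical$check$pass,
                               pass_ml = out$ml$check$pass))
  out
}

fmt_pct_cell <- function(value, rx) {
  sprintf("%.0f (%.1f%%)", value, percent_of_prescription(value, rx))
}

fmt_diff_cell <- function(value, diff) sprintf("%.0f (%+.0f)", value, diff)

#' Generate the report bundle from a completed workspace
#'
#' Formats the robustness results the way clinical summaries print them:
#' a target-coverage table with percent-of-prescription in parentheses
#' ("2988 (99.6%)"), an organ-at-risk worst-case table with signed
#' clinical-vs-predicted differences in parentheses ("2537 (+130)"), and
#' a plain-text 95/95 verdict per plan. Regeneration is idempotent.
#'
#' @param config A [pipeline_config()] whose robust stage has run.
#' @return List with the two formatted tables and the verdict lines.
#' @export
make_report <- function(config) {
  check_upstream(config, "report")
  idx_cl <- utils::read.csv(ws_path(config, "indices_clinical.csv"))
  idx_ml <- utils::read.csv(ws_path(config, "indices_ml.csv"))
  rx <- read_plan(ws_path(config, "plan_clinical.json"))$prescription_cGy
  wc_cl <- worst_case_table(as_tibble(idx_cl))
  wc_ml <- worst_case_table(as_tibble(idx_ml))
  target <- config$target

  ctv <- dplyr::inner_join(
    wc_cl[wc_cl$structure == target, c("structure", "index_id", "min",
                                       "max", "nominal")],
    wc_ml[wc_ml$structure == target, c("structure", "index_id", "min",
                                       "max", "nominal")],
    by = c("structure", "index_id"), suffix = c("_clinical", "_ml"))
  ctv_table <- tibble(
    index = ctv$index_id,
    clinical_min = fmt_pct_cell(ctv$min_clinical, rx),
    clinical_nominal = fmt_pct_cell(ctv$nominal_clinical, rx),
    clinical_max = fmt_pct_cell(ctv$max_clinical, rx),
    ml_min = fmt_pct_cell(ctv$min_ml, rx),
    ml_nominal = fmt_pct_cell(ctv$nominal_ml, rx),
    ml_max = fmt_pct_cell(ctv$max_ml, rx))

  oar_cl <- wc_cl[wc_cl$structure != target, ]
  oar_table <- NULL
  if (nrow(oar_cl)) {
    diffs <- compare_plans(oar_cl, wc_ml[wc_ml$structure != target, ])
    j <- dplyr::inner_join(
      dplyr::inner_join(oar_cl, wc_ml[wc_ml$structure != target, ],
                        by = c("structure", "index_id"),
                        suffix = c("_cl", "_ml")),
      diffs, by = c("structure", "index_id"))
    oar_table <- tibble(
      structure = j$structure, index = j$index_id,
      clinical_min = sprintf("%.0f", j$min_cl),
      clinical_nominal = sprintf("%.0f", j$nominal_cl),
      clinical_max = sprintf("%.0f", j$max_cl),
      ml_min = fmt_diff_cell(j$min_ml, j$diff_min),
      ml_nominal = sprintf("%.0f", j$nominal_ml),
      ml_max = fmt_diff_cell(j$max_ml, j$diff_max))
  }

  checks <- jsonlite::read_json(ws_path(config, "robust_checks.json"),
                                simplifyVector = TRUE)
  verdict <- vapply(c("clinical", "ml"), function(nm) {
    idx <- if (nm == "clinical") idx_cl else idx_ml
    d99_min <- min(idx$value[idx$structure == target &
                               idx$index_id == "D99" &
                               idx$scenario != "nominal"])
    sprintf(paste0("%s plan: 95/95 robustness %s (worst-case V95 = %.1f%%;",
                   " worst-case %s D99 = %.0f cGy(RBE), %.1f%% of Rx)"),
            nm, if (isTRUE(checks[[nm]]$pass)) "PASS" else "FAIL",
            checks[[nm]]$worst_v95_pct, target, d99_min,
            percent_of_prescription(d99_min, rx))
  }, character(1))

  utils::write.csv(ctv_table, ws_path(config, "report_ctv_coverage.csv"),
                   row.names = FALSE)
  if (!is.null(oar_table)) {
    utils::write.csv(oar_table, ws_path(config, "report_oar_doses.csv"),
                     row.names = FALSE)
  }
  writeLines(verdict, ws_path(config, "report_verdict.txt"))
  write_manifest(config, "report",
                 ws_path(config, c("report_ctv_coverage.csv",
                                   "report_oar_doses.csv",
                                   "report_verdict.txt")))
  list(ctv_table = ctv_table, oar_table = oar_table, verdict = verdict)
}
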