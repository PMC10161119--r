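## Log-file dialect, parsing, pulse aggregation, pseudo log files.
##
## Dialect "spotrobust-log-v1": UTF-8 CSV. Leading header lines of the form
## `# key=value` (first line must declare `# dialect=spotrobust-log-v1`),
## then one CSV header row and one row per pulse with the nine columns of
## `PulseRecord`: pulse_index, spot_index, nominal_energy_MeV, target_x_mm,
## target_y_mm, actual_x_mm, actual_y_mm, target_MU, actual_MU. Positions
## are beam's-eye-view coordinates at isocenter (x = crossplane,
## y = inplane), millimetres. All pulses of one spot are contiguous.
## Numerics are written with 17 significant digits so write -> parse is
## bit-exact.

LOG_DIALECT <- "spotrobust-log-v1"
LOG_COLUMNS <- c("pulse_index", "spot_index", "nominal_energy_MeV",
                 "target_x_mm", "target_y_mm", "actual_x_mm", "actual_y_mm",
                 "target_MU", "actual_MU")
HEADER_NUMERIC <- c("beam_id", "gantry_angle_deg", "snout_extension_mm",
                    "total_prescribed_MU")

new_proton_log <- function(header, pulses) {
  structure(list(header = header, pulses = pulses), class = "proton_log")
}

#' @export
print.proton_log <- function(x, ...) {
  cat(sprintf("<proton_log> beam %s, gantry %g deg: %d pulse(s), %d spot(s)\n",
              x$header$beam_id, x$header$gantry_angle_deg,
              nrow(x$pulses), length(unique(x$pulses$spot_index))))
  invisible(x)
}

#' Write a machine log file
#'
#' @param log A `proton_log` (e.g. from [generate_log_files()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_log_file <- function(log, path) {
  stopifnot(inherits(log, "proton_log"))
  hdr <- log$header
  con <- file(path, open = "wb")  # "\n" endings regardless of platform
  on.exit(close(con))
  lines <- c(
    sprintf("# dialect=%s", LOG_DIALECT),
    sprintf("# %s=%s", names(hdr),
            vapply(hdr, function(v)
              if (is.numeric(v)) fmt_full(v) else as.character(v),
              character(1))),
    paste(LOG_COLUMNS, collapse = ","))
  p <- log$pulses
  body <- paste(p$pulse_index, p$spot_index, fmt_full(p$nominal_energy_MeV),
                fmt_full(p$target_x_mm), fmt_full(p$target_y_mm),
                fmt_full(p$actual_x_mm), fmt_full(p$actual_y_mm),
                fmt_full(p$target_MU), fmt_full(p$actual_MU), sep = ",")
  writeLines(c(lines, body), con)
  invisible(path)
}

#' Parse a machine log file
#'
#' Validates the dialect declaration, types the header fields, checks the
#' nine-column body row by row and enforces the structural invariants:
#' non-negative MUs, finite coordinates, contiguous spot blocks, gantry
#' angle in `[0, 360)`. Violations raise an error naming the offending
#' line.
#'
#' @param path Path to a file in the `spotrobust-log-v1` dialect.
#' @return A `proton_log`.
#' @export
parse_log_file <- function(path) {
  if (!file.exists(path)) abort(sprintf("log file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !identical(lines[1], sprintf("# dialect=%s", LOG_DIALECT))) {
    abort(sprintf("line 1: file does not declare dialect '%s'", LOG_DIALECT))
  }
  is_hdr <- grepl("^# ", lines) & seq_along(lines) > 1
  hdr_end <- if (any(is_hdr)) max(which(is_hdr)) else 1L
  header <- list()
  for (i in setdiff(which(is_hdr), 1L)) {
    kv <- sub("^# ", "", lines[i])
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 1) abort(sprintf("line %d: malformed header line '%s'", i, lines[i]))
    key <- substr(kv, 1, eq - 1); val <- substr(kv, eq + 1, nchar(kv))
    if (key %in% HEADER_NUMERIC) {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) abort(sprintf("line %d: header field '%s' is not numeric", i, key))
      val <- num
    }
    header[[key]] <- val
  }
  ga <- header$gantry_angle_deg
  if (!is.null(ga) && (ga < 0 || ga >= 360)) {
    abort(sprintf("header gantry_angle_deg %g outside [0, 360)", ga))
  }
  col_line <- hdr_end + 1L
  if (col_line > length(lines)) abort("missing column header row")
  cols <- strsplit(lines[col_line], ",", fixed = TRUE)[[1]]
  missing <- setdiff(LOG_COLUMNS, cols)
  if (length(missing)) {
    abort(sprintf("line %d: missing column(s): %s", col_line,
                  paste(missing, collapse = ", ")))
  }
  body_lines <- lines[seq_len(length(lines)) > col_line]
  body_lines <- body_lines[nzchar(body_lines)]
  if (!length(body_lines)) {
    return(new_proton_log(header, tibble(
      pulse_index = integer(), spot_index = integer(),
      nominal_energy_MeV = numeric(), target_x_mm = numeric(),
      target_y_mm = numeric(), actual_x_mm = numeric(),
      actual_y_mm = numeric(), target_MU = numeric(), actual_MU = numeric())))
  }
  mat <- strsplit(body_lines, ",", fixed = TRUE)
  nf <- lengths(mat)
  if (any(nf != length(cols))) {
    bad <- which(nf != length(cols))[1]
    abort(sprintf("line %d: expected %d fields, found %d",
                  col_line + bad, length(cols), nf[bad]))
  }
  df <- as.data.frame(do.call(rbind, mat), stringsAsFactors = FALSE)
  names(df) <- cols
  df <- df[LOG_COLUMNS]
  num <- lapply(df, function(v) suppressWarnings(as.numeric(v)))
  for (j in seq_along(num)) {
    if (anyNA(num[[j]])) {
      bad <- which(is.na(num[[j]]))[1]
      abort(sprintf("line %d: non-numeric value in column '%s'",
                    col_line + bad, LOG_COLUMNS[j]))
    }
  }
  p <- as_tibble(num)
  p$pulse_index <- as.integer(p$pulse_index)
  p$spot_index <- as.integer(p$spot_index)
  for (cc in c("target_MU", "actual_MU")) {
    if (any(p[[cc]] < 0)) {
      bad <- which(p[[cc]] < 0)[1]
      abort(sprintf("line %d: negative %s", col_line + bad, cc))
    }
  }
  for (cc in c("target_x_mm", "target_y_mm", "actual_x_mm", "actual_y_mm")) {
    if (any(!is.finite(p[[cc]]))) {
      bad <- which(!is.finite(p[[cc]]))[1]
      abort(sprintf("line %d: non-finite %s", col_line + bad, cc))
    }
  }
  r <- rle(p$spot_index)
  if (anyDuplicated(r$values)) {
    dup <- r$values[duplicated(r$values)][1]
    abort(sprintf("non-contiguous pulse block for spot_index %d", dup))
  }
  new_proton_log(header, p)
}

#' Aggregate pulses into delivered spots
#'
#' One record per distinct spot: delivered MU is the sum of the pulses'
#' actual MUs and the delivered position is the actual-MU-weighted mean of
#' the pulse actual positions. Spots whose total actual MU is zero have an
#' undefined weighted mean; they are flagged (`zero_mu = TRUE`, delivered
#' position `NA`) and should be excluded from model training.
#'
#' @param log A `proton_log`.
#' @return Tibble of spot records: spot_index, nominal energy, planned
#'   (target) x/y/MU, delivered x/y/MU, `zero_mu` flag.
#' @export
aggregate_pulses <- function(log) {
  stopifnot(inherits(log, "proton_log"))
  p <- log$pulses
  out <- p %>%
    group_by(.data$spot_index) %>%
    summarise(
      nominal_energy_MeV = .data$nominal_energy_MeV[1],
      planned_x_mm = .data$target_x_mm[1],
      planned_y_mm = .data$target_y_mm[1],
      planned_mu = sum(.data$target_MU),
      delivered_mu = sum(.data$actual_MU),
      # a single-pulse spot inherits the pulse position exactly (the PLF
      # round-trip contract is bit-exact, and x*mu/mu is not)
      delivered_x_mm = if (dplyr::n() == 1) {
        if (.data$actual_MU[1] > 0) .data$actual_x_mm[1] else NA_real_
      } else if (sum(.data$actual_MU) > 0) {
        sum(.data$actual_x_mm * .data$actual_MU) / sum(.data$actual_MU)
      } else NA_real_,
      delivered_y_mm = if (dplyr::n() == 1) {
        if (.data$actual_MU[1] > 0) .data$actual_y_mm[1] else NA_real_
      } else if (sum(.data$actual_MU) > 0) {
        sum(.data$actual_y_mm * .data$actual_MU) / sum(.data$actual_MU)
      } else NA_real_,
      .groups = "drop") %>%
    mutate(zero_mu = .data$delivered_mu <= 0) %>%
    select("spot_index", "nominal_energy_MeV", "planned_x_mm", "planned_y_mm",
           "planned_mu", "delivered_x_mm", "delivered_y_mm", "delivered_mu",
           "zero_mu") %>%
    arrange(.data$spot_index)
  out
}

#' Write a pseudo log file (PLF) from model predictions
#'
#' Encodes predicted delivered spots in the standard log dialect so the
#' downstream dose pipeline can treat predictions exactly like a real
#' delivery record: one pulse per spot, pulse target = planned spot, pulse
#' actual = predicted delivered spot. Parsing and aggregating the PLF
#' reproduces the predictions bit-exactly.
#'
#' @param plan A `treatment_plan`.
#' @param beam_id Which beam to write.
#' @param predictions Tibble with one row per planned spot of the beam, in
#'   plan order, columns `x_mm`, `y_mm`, `mu` (predicted delivered values).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pseudo_log_file <- function(plan, beam_id, predictions, path) {
  sp <- plan$spots[plan$spots$beam_id == beam_id, ]
  if (nrow(predictions) != nrow(sp)) {
    abort(sprintf(
      "beam %d has %d planned spots but %d predictions were supplied",
      beam_id, nrow(sp), nrow(predictions)))
  }
  pulses <- tibble(
    pulse_index = seq_len(nrow(sp)),
    spot_index = sp$spot_id,
    nominal_energy_MeV = sp$energy_MeV,
    target_x_mm = sp$x_mm, target_y_mm = sp$y_mm,
    actual_x_mm = predictions$x_mm, actual_y_mm = predictions$y_mm,
    target_MU = sp$mu, actual_MU = predictions$mu)
  log <- new_proton_log(
    header = list(date = "2026-01-01", plan_id = "pseudo-log-file",
                  beam_id = beam_id,
                  gantry_angle_deg = plan$beams$gantry_angle_deg[beam_id],
                  snout_extension_mm = plan$beams$snout_extension_mm[beam_id],
                  total_prescribed_MU = sum(sp$mu)),
    pulses = pulses)
  write_log_file(log, path)
}

#' Extract per-spot planning features from a plan
#'
#' One row per spot in delivery order: target position and MU, gantry
#' angle, snout extension and nominal energy — the six predictors of the
#' delivery-error model. Row order equals `plan$spots` order, and the
#' (beam, layer, spot) indices are carried so rows map back losslessly.
#'
#' @param plan A `treatment_plan`.
#' @return Tibble with index columns (`spot_id`, `beam_id`, `layer`) and
#'   feature columns `target_x_mm`, `target_y_mm`, `target_mu`,
#'   `gantry_angle_deg`, `snout_extension_mm`, `nominal_energy_MeV`.
#' @export
extract_plan_features <- function(plan) {
  stopifnot(inherits(plan, "treatment_plan"))
  plan$spots %>%
    left_join(plan$beams, by = "beam_id") %>%
    transmute_features()
}

transmute_features <- function(df) {
  tibble(spot_id = df$spot_id, beam_id = df$beam_id, layer = df$layer,
         target_x_mm = df$x_mm, target_y_mm = df$y_mm, target_mu = df$mu,
         gantry_angle_deg = df$gantry_angle_deg,
         snout_extension_mm = df$snout_extension_mm,
         nominal_energy_MeV = df$energy_MeV)
}

FEATURE_NAMES <- c("target_x_mm", "target_y_mm", "target_mu",
                   "gantry_angle_deg", "snout_extension_mm",
                   "nominal_energy_MeV")
OUTPUT_NAMES <- c("delivered_x_mm", "delivered_y_mm", "delivered_mu")
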