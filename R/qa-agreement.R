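## Agreement between detector-measured and log-recorded spot positions.

#' Pair recorded spots with nominal grid points
#'
#' Each recorded spot is assigned to its nearest nominal grid point; pairs
#' whose distance exceeds the tolerance are flagged unmatched. Two
#' recorded spots claiming the same grid point is an ambiguity error.
#'
#' @param qa A `qa_session` from [generate_qa_grid()], or any tibble with
#'   `nominal_x_mm`/`nominal_y_mm`, `recorded_x_mm`/`recorded_y_mm` and
#'   `measured_x_mm`/`measured_y_mm` columns.
#' @param tolerance_mm Maximum pairing distance, mm.
#' @return Tibble of pairs with per-axis deltas
#'   (delta = recorded - measured, mm) and a `matched` flag.
#' @export
match_spots <- function(qa, tolerance_mm = 5) {
  stopifnot(tolerance_mm > 0)
  nom <- cbind(qa$nominal_x_mm, qa$nominal_y_mm)
  rec <- cbind(qa$recorded_x_mm, qa$recorded_y_mm)
  n <- nrow(rec)
  assigned <- integer(n)
  dist <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (nom[, 1] - rec[i, 1])^2 + (nom[, 2] - rec[i, 2])^2
    assigned[i] <- which.min(d2)
    dist[i] <- sqrt(min(d2))
  }
  matched <- dist <= tolerance_mm
  dup <- assigned[matched][duplicated(assigned[matched])]
  if (length(dup)) {
    abort(sprintf("ambiguous pairing: grid point %d claimed by multiple recorded spots",
                  dup[1]))
  }
  tibble(spot = seq_len(n), grid_point = assigned, pair_dist_mm = dist,
         matched = matched,
         delta_x_mm = qa$recorded_x_mm - qa$measured_x_mm,
         delta_y_mm = qa$recorded_y_mm - qa$measured_y_mm)
}

#' Per-axis statistics of recorded-minus-measured deltas
#'
#' @param pairs Output of [match_spots()]; unmatched pairs are dropped.
#' @return One-row tibble: `n_spots`, `mean_x`, `sd_x`, `mean_y`, `sd_y`
#'   (mm; sample SD, n - 1).
#' @export
delta_stats <- function(pairs) {
  p <- pairs[pairs$matched, ]
  if (!nrow(p)) abort("no matched spot pairs")
  tibble(n_spots = nrow(p),
         mean_x = mean(p$delta_x_mm),
         sd_x = if (nrow(p) > 1) sd(p$delta_x_mm) else 0,
         mean_y = mean(p$delta_y_mm),
         sd_y = if (nrow(p) > 1) sd(p$delta_y_mm) else 0)
}

#' Root-mean-square disagreement
#'
#' \eqn{RMS = \sqrt{(\Delta_1^2 + \cdots + \Delta_n^2)/n}}.
#'
#' @param deltas Numeric vector of per-spot position deltas, mm.
#' @return RMS in mm.
#' @export
#' @examples
#' rms(c(3, 4)) # sqrt(12.5)
rms <- function(deltas) {
  if (!length(deltas)) abort("rms of an empty vector is undefined")
  sqrt(mean(deltas^2))
}

#' Combined planar RMS from per-axis RMS values
#'
#' Quadrature identity: the RMS of the planar magnitudes
#' \eqn{\sqrt{\Delta x_i^2 + \Delta y_i^2}} equals
#' \eqn{\sqrt{RMS_x^2 + RMS_y^2}}.
#'
#' @param rms_x,rms_y Per-axis RMS disagreement, mm; non-negative.
#' @return Combined RMS, mm.
#' @export
#' @examples
#' rms_combined(0.277, 1.309) # ~1.338
rms_combined <- function(rms_x, rms_y) {
  if (any(rms_x < 0) || any(rms_y < 0)) abort("RMS inputs must be non-negative")
  sqrt(rms_x^2 + rms_y^2)
}

#' Descriptive Gaussianity summary of a delta sample
#'
#' Reports sample skewness, excess kurtosis and a normality-test p-value.
#' Purely descriptive: no pass/fail gate is applied. A constant sample is
#' degenerate and reported as non-testable.
#'
#' @param deltas Numeric vector, length >= 20.
#' @param method `"jarque_bera"` (omnibus moment test) or `"shapiro"`
#'   (Shapiro-Wilk; n limited to 5000 by the base implementation).
#' @return One-row tibble: `n`, `skewness`, `excess_kurtosis`, `p_value`,
#'   `method`, `testable`.
#' @export
gaussianity_summary <- function(deltas, method = c("jarque_bera", "shapiro")) {
  method <- match.arg(method)
  n <- length(deltas)
  if (n < 20) abort("need at least 20 values for a Gaussianity summary")
  s <- sd(deltas)
  if (s == 0) {
    return(tibble(n = n, skewness = NA_real_, excess_kurtosis = NA_real_,
                  p_value = NA_real_, method = method, testable = FALSE))
  }
  z <- (deltas - mean(deltas)) / s
  skew <- mean(z^3)
  exk <- mean(z^4) - 3
  p <- if (method == "jarque_bera") {
    jb <- n * (skew^2 / 6 + exk^2 / 24)
    pchisq(jb, df = 2, lower.tail = FALSE)
  } else {
    shapiro.test(if (n > 5000) sample(deltas, 5000) else deltas)$p.value
  }
  tibble(n = n, skewness = skew, excess_kurtosis = exk, p_value = p,
         method = method, testable = TRUE)
}

#' Agreement report for one or more QA sessions
#'
#' Builds the standard QA-report table: rows mean delta-x, mean delta-y,
#' RMS_x, RMS_y and RMS_xy, one column per gantry angle. The +/- values
#' attached to the means are sample SDs of the per-spot deltas (labelled
#' as such).
#'
#' @param sessions A list of `qa_session` objects.
#' @param tolerance_mm Pairing tolerance passed to [match_spots()].
#' @return Tibble with one row per session: gantry angle, n, per-axis mean
#'   and SD, RMS_x, RMS_y, RMS_xy (all mm).
#' @export
qa_agreement_table <- function(sessions, tolerance_mm = 5) {
  bind_rows(lapply(sessions, function(qa) {
    pairs <- match_spots(qa, tolerance_mm)
    st <- delta_stats(pairs)
    p <- pairs[pairs$matched, ]
    rx <- rms(p$delta_x_mm); ry <- rms(p$delta_y_mm)
    tibble(gantry_angle_deg = attr(qa, "gantry_angle_deg") %||% NA_real_,
           n_spots = st$n_spots,
           mean_dx_mm = st$mean_x, sd_dx_mm = st$sd_x,
           mean_dy_mm = st$mean_y, sd_dy_mm = st$sd_y,
           rms_x_mm = rx, rms_y_mm = ry, rms_xy_mm = rms_combined(rx, ry))
  }))
}
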