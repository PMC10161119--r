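make_logs <- function(seed = 1, pulses = 3) {
  ph <- tiny_phantom()
  plan <- tiny_plan(ph, seed = seed)
  list(plan = plan,
       logs = generate_log_files(plan, error_truth(), pulses_per_spot = pulses,
                                 seed = seed))
}

test_that("write/parse round-trips a generated log file bit-exactly", {
  x <- make_logs()
  path <- withr::local_tempfile(fileext = ".csv")
  write_log_file(x$logs[[1]], path)
  back <- parse_log_file(path)
  expect_identical(back$pulses, x$logs[[1]]$pulses)
  expect_equal(back$header$gantry_angle_deg,
               x$logs[[1]]$header$gantry_angle_deg)
  expect_equal(back$header$total_prescribed_MU,
               x$logs[[1]]$header$total_prescribed_MU)
})

test_that("malformed log files are rejected with the offending line", {
  x <- make_logs(pulses = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_log_file(x$logs[[1]], path)
  lines <- readLines(path)
  body_start <- which(grepl("^pulse_index", lines)) + 1

  # negative actual MU
  bad <- strsplit(lines[body_start + 2], ",")[[1]]
  bad[9] <- "-0.5"
  lines2 <- lines
  lines2[body_start + 2] <- paste(bad, collapse = ",")
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines2, p2)
  expect_error(parse_log_file(p2),
               sprintf("line %d.*negative actual_MU", body_start + 2))

  # missing column
  lines3 <- lines
  lines3[body_start - 1] <- sub("actual_MU", "other", lines3[body_start - 1])
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines3, p3)
  expect_error(parse_log_file(p3), "missing column.*actual_MU")

  # non-contiguous spot block: move the first pulse of spot 1 to the end
  lx <- make_logs(pulses = 2)
  p4 <- withr::local_tempfile(fileext = ".csv")
  write_log_file(lx$logs[[1]], p4)
  l4 <- readLines(p4)
  bs <- which(grepl("^pulse_index", l4)) + 1
  l4 <- c(l4[-bs], l4[bs])
  writeLines(l4, p4)
  expect_error(parse_log_file(p4), "non-contiguous")

  # missing dialect declaration
  p5 <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines[-1], p5)
  expect_error(parse_log_file(p5), "dialect")
})

test_that("an empty body parses to zero pulses and zero spots", {
  x <- make_logs(pulses = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_log_file(x$logs[[1]], path)
  lines <- readLines(path)
  hdr_end <- which(grepl("^pulse_index", lines))
  writeLines(lines[seq_len(hdr_end)], path)
  log <- parse_log_file(path)
  expect_equal(nrow(log$pulses), 0)
  expect_equal(nrow(aggregate_pulses(log)), 0)
})

test_that("pulse aggregation implements the MU-weighted mean", {
  one <- new_log_for_test(tibble::tibble(
    pulse_index = 1L, spot_index = 1L, nominal_energy_MeV = 100,
    target_x_mm = 0, target_y_mm = 0, actual_x_mm = 1, actual_y_mm = -2,
    target_MU = 0.5, actual_MU = 0.5))
  sp <- aggregate_pulses(one)
  expect_equal(sp$delivered_x_mm, 1)
  expect_equal(sp$delivered_y_mm, -2)
  expect_equal(sp$delivered_mu, 0.5)

  two <- new_log_for_test(tibble::tibble(
    pulse_index = 1:2, spot_index = c(1L, 1L), nominal_energy_MeV = 100,
    target_x_mm = 0, target_y_mm = 0, actual_x_mm = c(0, 3),
    actual_y_mm = 0, target_MU = 2, actual_MU = c(1, 3)))
  sp2 <- aggregate_pulses(two)
  expect_equal(sp2$delivered_x_mm, 2.25)
  expect_equal(sp2$delivered_mu, 4)
})

test_that("aggregation matches a brute-force oracle on random pulse sets", {
  set.seed(42)
  for (rep in 1:5) {
    n_spots <- 200
    k <- sample(1:4, n_spots, replace = TRUE)
    idx <- rep(seq_len(n_spots), k)
    pulses <- tibble::tibble(
      pulse_index = seq_along(idx), spot_index = idx,
      nominal_energy_MeV = 100,
      target_x_mm = rnorm(length(idx)), target_y_mm = rnorm(length(idx)),
      actual_x_mm = rnorm(length(idx), 0, 10),
      actual_y_mm = rnorm(length(idx), 0, 10),
      target_MU = runif(length(idx)), actual_MU = runif(length(idx), 0.01, 2))
    sp <- aggregate_pulses(new_log_for_test(pulses))
    oracle <- brute_aggregate(pulses)
    expect_equal(sp$delivered_x_mm, oracle$x, tolerance = 1e-12)
    expect_equal(sp$delivered_y_mm, oracle$y, tolerance = 1e-12)
    expect_equal(sp$delivered_mu, oracle$mu, tolerance = 1e-12)
  }
})

test_that("zero-MU spots are flagged with undefined delivered position", {
  pulses <- tibble::tibble(
    pulse_index = 1:2, spot_index = 1:2, nominal_energy_MeV = 100,
    target_x_mm = c(1, 2), target_y_mm = 0, actual_x_mm = c(1, 2),
    actual_y_mm = 0, target_MU = c(1, 1), actual_MU = c(1, 0))
  sp <- aggregate_pulses(new_log_for_test(pulses))
  expect_equal(sp$zero_mu, c(FALSE, TRUE))
  expect_true(is.na(sp$delivered_x_mm[2]))
})

test_that("per-beam MU conservation holds between pulses and spots", {
  x <- make_logs(pulses = 4)
  for (log in x$logs) {
    sp <- aggregate_pulses(log)
    expect_equal(sum(sp$delivered_mu), sum(log$pulses$actual_MU),
                 tolerance = 1e-9)
  }
})

test_that("PLF round-trip is the identity on predictions", {
  x <- make_logs()
  plan <- x$plan
  sp1 <- plan$spots[plan$spots$beam_id == 1, ]
  # identity predictions
  path <- withr::local_tempfile(fileext = ".csv")
  write_pseudo_log_file(plan, 1, sp1[c("x_mm", "y_mm", "mu")], path)
  agg <- aggregate_pulses(parse_log_file(path))
  expect_identical(agg$delivered_x_mm, sp1$x_mm)
  expect_identical(agg$delivered_y_mm, sp1$y_mm)
  expect_identical(agg$delivered_mu, sp1$mu)
  # arbitrary predictions round-trip bit-exactly
  pred <- tibble::tibble(x_mm = sp1$x_mm + rnorm(nrow(sp1)),
                         y_mm = sp1$y_mm + rnorm(nrow(sp1)),
                         mu = sp1$mu * runif(nrow(sp1), 0.9, 1.1))
  write_pseudo_log_file(plan, 1, pred, path)
  agg2 <- aggregate_pulses(parse_log_file(path))
  expect_identical(agg2$delivered_x_mm, pred$x_mm)
  expect_identical(agg2$delivered_y_mm, pred$y_mm)
  expect_identical(agg2$delivered_mu, pred$mu)
  # count mismatch is an error
  expect_error(write_pseudo_log_file(plan, 1, pred[-1, ], path),
               "planned spots")
})

test_that("plan feature extraction is row-aligned and lossless", {
  ph <- tiny_phantom()
  plan <- tiny_plan(ph)
  f <- extract_plan_features(plan)
  expect_equal(nrow(f), n_spots(plan))
  expect_true(all(vapply(f, function(col) all(is.finite(col)), logical(1))))
  for (b in plan$beams$beam_id) {
    expect_length(unique(f$gantry_angle_deg[f$beam_id == b]), 1)
  }
  # row -> (beam, layer, spot_id) maps back to the plan losslessly
  key_f <- paste(f$beam_id, f$layer, f$spot_id)
  key_p <- paste(plan$spots$beam_id, plan$spots$layer, plan$spots$spot_id)
  expect_identical(key_f, key_p)
  expect_identical(f$target_x_mm, plan$spots$x_mm)
})

test_that("plan JSON round-trips bit-exactly", {
  ph <- tiny_phantom()
  plan <- tiny_plan(ph)
  path <- withr::local_tempfile(fileext = ".json")
  write_plan(plan, path)
  back <- read_plan(path)
  expect_identical(back$spots$x_mm, plan$spots$x_mm)
  expect_identical(back$spots$mu, plan$spots$mu)
  expect_equal(back$beams, plan$beams)
  expect_equal(back$apertures[[1]]$polygons[[1]],
               plan$apertures[[1]]$polygons[[1]], tolerance = 0)
})
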