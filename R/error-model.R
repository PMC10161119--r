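#' Training configuration for the spot delivery-error model
#'
#' The model is a shallow feedforward network with one hidden layer of
#' five neurons (tanh activation, linear output), trained on 70% of the
#' data with 15% for validation-based early stopping and 15% held out for
#' testing, using Levenberg-Marquardt least squares by default.
#'
#' @param hidden_neurons Hidden layer width (default 5).
#' @param fractions Length-3 train/validation/test fractions summing to 1
#'   (default 0.70/0.15/0.15).
#' @param max_epochs Maximum optimizer iterations.
#' @param patience Early-stop patience: accepted iterations without
#'   validation improvement.
#' @param seed Integer seed for the split and the weight initialisation.
#' @param optimizer `"levenberg_marquardt"` (default) or `"quasi_newton"`
#'   (BFGS on the same least-squares objective).
#' @return An object of class `train_config`.
#' @export
train_config <- function(hidden_neurons = 5, fractions = c(0.70, 0.15, 0.15),
                         max_epochs = 200, patience = 20, seed = 1,
                         optimizer = c("levenberg_marquardt", "quasi_newton")) {
  optimizer <- match.arg(optimizer)
  stopifnot(hidden_neurons >= 1, length(fractions) == 3, all(fractions > 0),
            abs(sum(fractions) - 1) < 1e-8, max_epochs >= 1, patience >= 1)
  structure(list(hidden_neurons = as.integer(hidden_neurons),
                 fractions = fractions, max_epochs = max_epochs,
                 patience = patience, seed = seed, optimizer = optimizer),
            class = "train_config")
}

#' Assemble the training dataset from aggregated log files
#'
#' Joins each beam's aggregated spot records with its log header to build
#' row-aligned feature (6 columns: target x, target y, target MU, gantry
#' angle, snout extension, nominal energy) and target (3 columns:
#' delivered x, delivered y, delivered MU) tables. Spots flagged
#' `zero_mu` have an undefined delivered position and are excluded; the
#' count of exclusions is reported.
#'
#' @param logs A list of `proton_log` objects (real or generated).
#' @return A list: `features` tibble, `targets` tibble, `n_excluded`
#'   zero-MU spot count, and `index` tibble (beam_id, spot_index) mapping
#'   rows back to their source.
#' @export
assemble_dataset <- function(logs) {
  if (!length(logs)) abort("no log files supplied")
  rows <- lapply(logs, function(log) {
    spots <- aggregate_pulses(log)
    h <- log$header
    tibble(beam_id = h$beam_id %||% NA_real_,
           spot_index = spots$spot_index,
           target_x_mm = spots$planned_x_mm,
           target_y_mm = spots$planned_y_mm,
           target_mu = spots$planned_mu,
           gantry_angle_deg = h$gantry_angle_deg %||% NA_real_,
           snout_extension_mm = h$snout_extension_mm %||% NA_real_,
           nominal_energy_MeV = spots$nominal_energy_MeV,
           delivered_x_mm = spots$delivered_x_mm,
           delivered_y_mm = spots$delivered_y_mm,
           delivered_mu = spots$delivered_mu,
           zero_mu = spots$zero_mu)
  })
  all <- bind_rows(rows)
  n_excluded <- sum(all$zero_mu)
  keep <- all[!all$zero_mu, ]
  if (!nrow(keep)) abort("no usable spots after excluding zero-MU records")
  list(features = keep[FEATURE_NAMES],
       targets = keep[OUTPUT_NAMES],
       n_excluded = n_excluded,
       index = keep[c("beam_id", "spot_index")])
}

#' Split a dataset into disjoint train/validation/test index sets
#'
#' Random partition at the configured fractions, reproducible from the
#' config seed. Train and validation sizes are rounded; the test set takes
#' the remainder.
#'
#' @param n Number of rows (or a data frame whose rows are counted).
#' @param config A [train_config()].
#' @return List of integer vectors `train`, `val`, `test` forming a
#'   disjoint partition of `1:n`.
#' @export
split_dataset <- function(n, config = train_config()) {
  if (is.data.frame(n)) n <- nrow(n)
  if (n < 10) abort("need at least 10 rows to split")
  f <- config$fractions
  n_train <- round(n * f[1]); n_val <- round(n * f[2])
  with_seed(derive_seed(config$seed, "split"), {
    perm <- sample.int(n)
    list(train = sort(perm[seq_len(n_train)]),
         val = sort(perm[n_train + seq_len(n_val)]),
         test = sort(perm[(n_train + n_val + 1):n]))
  })
}

#' Train the planned-to-delivered spot mapping
#'
#' Standardizes features and targets (per-column mean/SD over the training
#' split), fits the network, and computes fit metrics on the held-out test
#' split only: MSE on the standardized-target scale, overall R-squared on
#' both raw and standardized scales, and per-output R-squared.
#'
#' @param features,targets Row-aligned tibbles from [assemble_dataset()].
#' @param config A [train_config()].
#' @return An object of class `spot_error_model`.
#' @export
train_error_model <- function(features, targets, config = train_config()) {
  stopifnot(nrow(features) == nrow(targets))
  features <- features[FEATURE_NAMES]   # canonical column order
  targets <- targets[OUTPUT_NAMES]
  X <- as.matrix(features); T <- as.matrix(targets)
  if (anyNA(X) || anyNA(T)) abort("features/targets contain missing values")
  idx <- split_dataset(nrow(X), config)

  x_center <- colMeans(X[idx$train, , drop = FALSE])
  x_scale <- apply(X[idx$train, , drop = FALSE], 2, sd)
  x_scale[x_scale <= 0 | !is.finite(x_scale)] <- 1
  y_center <- colMeans(T[idx$train, , drop = FALSE])
  y_scale <- apply(T[idx$train, , drop = FALSE], 2, sd)
  y_scale[y_scale <= 0 | !is.finite(y_scale)] <- 1
  Z <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  U <- sweep(sweep(T, 2, y_center), 2, y_scale, "/")

  w0 <- nn_init(ncol(Z), config$hidden_neurons, ncol(U),
                derive_seed(config$seed, "train-init"))
  fit <- if (config$optimizer == "levenberg_marquardt") {
    nn_train_lm(w0, Z[idx$train, , drop = FALSE], U[idx$train, , drop = FALSE],
                Z[idx$val, , drop = FALSE], U[idx$val, , drop = FALSE],
                max_epochs = config$max_epochs, patience = config$patience)
  } else {
    nn_train_bfgs(w0, Z[idx$train, , drop = FALSE], U[idx$train, , drop = FALSE],
                  Z[idx$val, , drop = FALSE], U[idx$val, , drop = FALSE],
                  max_epochs = config$max_epochs)
  }

  w <- fit$weights
  Zt <- Z[idx$test, , drop = FALSE]
  Ut <- U[idx$test, , drop = FALSE]
  pred_std <- nn_forward(w, Zt)$Y
  pred_raw <- sweep(sweep(pred_std, 2, y_scale, "*"), 2, y_center, "+")
  Traw <- T[idx$test, , drop = FALSE]
  r2 <- function(obs, prd) {
    ss_tot <- sum(sweep(obs, 2, colMeans(obs))^2)
    1 - sum((obs - prd)^2) / ss_tot
  }
  per_out <- vapply(seq_len(ncol(Traw)), function(k) {
    1 - sum((Traw[, k] - pred_raw[, k])^2) /
      sum((Traw[, k] - mean(Traw[, k]))^2)
  }, numeric(1))
  metrics <- list(
    mse_std = mean((Ut - pred_std)^2),
    r_squared_raw = r2(Traw, pred_raw),
    r_squared_std = r2(Ut, pred_std),
    per_output_r_squared = stats::setNames(per_out, OUTPUT_NAMES),
    n_train = length(idx$train), n_val = length(idx$val),
    n_test = length(idx$test), epochs = fit$epochs,
    val_sse = fit$val_sse)

  structure(list(weights = w,
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, y_scale = y_scale,
                 feature_names = FEATURE_NAMES, output_names = OUTPUT_NAMES,
                 feature_range = apply(X[idx$train, , drop = FALSE], 2, range),
                 metrics = metrics, config = config, split = idx),
            class = "spot_error_model")
}

#' @export
print.spot_error_model <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<spot_error_model> %d-%d-%d network (%s)\n",
              length(x$feature_names), nrow(x$weights$W1),
              length(x$output_names), x$config$optimizer),
      sprintf("  split %d/%d/%d; test MSE(std) %.4g; test R2 raw %.5f / std %.5f\n",
              m$n_train, m$n_val, m$n_test, m$mse_std,
              m$r_squared_raw, m$r_squared_std), sep = "")
  invisible(x)
}

#' Predict delivered spots for new feature rows
#'
#' @param object A `spot_error_model`.
#' @param newdata Tibble containing the model's six feature columns (extra
#'   columns are ignored). Rows outside the training feature ranges
#'   trigger an extrapolation warning, not an error.
#' @param ... Unused.
#' @return Matrix-free tibble: `delivered_x_mm`, `delivered_y_mm`,
#'   `delivered_mu`, one row per input row.
#' @export
predict.spot_error_model <- function(object, newdata, ...) {
  miss <- setdiff(object$feature_names, names(newdata))
  if (length(miss)) {
    abort(sprintf("newdata lacks feature column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  X <- as.matrix(newdata[object$feature_names])
  rng <- object$feature_range
  out_of_range <- vapply(seq_len(ncol(X)), function(j) {
    any(X[, j] < rng[1, j] - 1e-9 | X[, j] > rng[2, j] + 1e-9)
  }, logical(1))
  if (any(out_of_range)) {
    warn(sprintf("extrapolating outside the training range of: %s",
                 paste(object$feature_names[out_of_range], collapse = ", ")))
  }
  Z <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, "/")
  Ystd <- nn_forward(object$weights, Z)$Y
  Y <- sweep(sweep(Ystd, 2, object$y_scale, "*"), 2, object$y_center, "+")
  colnames(Y) <- object$output_names
  as_tibble(Y)
}

#' Predict the delivered spots of a whole treatment plan
#'
#' Runs [extract_plan_features()] and the model forward pass; output rows
#' are in plan (delivery) order.
#'
#' @param model A `spot_error_model`.
#' @param plan A `treatment_plan`.
#' @return Tibble: `spot_id`, `beam_id`, `layer`, predicted `x_mm`,
#'   `y_mm`, `mu`. Predicted MUs are floored at zero (a delivered MU
#'   cannot be negative, but an unconstrained regression output can be).
#' @export
predict_plan <- function(model, plan) {
  feats <- extract_plan_features(plan)
  pred <- predict(model, feats)
  tibble(spot_id = feats$spot_id, beam_id = feats$beam_id,
         layer = feats$layer,
         x_mm = pred$delivered_x_mm, y_mm = pred$delivered_y_mm,
         mu = pmax(pred$delivered_mu, 0))
}

#' @export
tidy.spot_error_model <- function(x, ...) {
  w <- x$weights
  bind_rows(
    tibble(layer = "hidden", parameter = "weight",
           from = rep(x$feature_names, each = nrow(w$W1)),
           to = rep(paste0("h", seq_len(nrow(w$W1))), ncol(w$W1)),
           estimate = as.vector(w$W1)),
    tibble(layer = "hidden", parameter = "bias", from = NA_character_,
           to = paste0("h", seq_len(nrow(w$W1))), estimate = w$b1),
    tibble(layer = "output", parameter = "weight",
           from = rep(paste0("h", seq_len(ncol(w$W2))), each = nrow(w$W2)),
           to = rep(x$output_names, ncol(w$W2)),
           estimate = as.vector(w$W2)),
    tibble(layer = "output", parameter = "bias", from = NA_character_,
           to = x$output_names, estimate = w$b2))
}

#' @export
glance.spot_error_model <- function(x, ...) {
  m <- x$metrics
  tibble(mse_std = m$mse_std, r_squared_raw = m$r_squared_raw,
         r_squared_std = m$r_squared_std,
         n_train = m$n_train, n_val = m$n_val, n_test = m$n_test,
         epochs = m$epochs, optimizer = x$config$optimizer,
         hidden_neurons = x$config$hidden_neurons)
}

#' Serialize / restore a trained model as JSON
#'
#' Weights and normalization statistics are written as 17-significant-digit
#' strings so a reloaded model yields bit-identical predictions.
#'
#' @param model A `spot_error_model`.
#' @param path File path.
#' @return `save_error_model` returns `path` invisibly; `load_error_model`
#'   the model.
#' @export
save_error_model <- function(model, path) {
  stopifnot(inherits(model, "spot_error_model"))
  w <- model$weights
  obj <- list(
    format = "spotrobust-model-v1",
    architecture = c(length(model$feature_names), nrow(w$W1),
                     length(model$output_names)),
    feature_names = model$feature_names, output_names = model$output_names,
    W1 = fmt_full(as.vector(w$W1)), b1 = fmt_full(w$b1),
    W2 = fmt_full(as.vector(w$W2)), b2 = fmt_full(w$b2),
    x_center = fmt_full(model$x_center), x_scale = fmt_full(model$x_scale),
    y_center = fmt_full(model$y_center), y_scale = fmt_full(model$y_scale),
    feature_range = fmt_full(as.vector(model$feature_range)),
    metrics = model$metrics, config = unclass(model$config))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_error_model
#' @export
load_error_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(o$format, "spotrobust-model-v1")) {
    abort("not a spotrobust model file")
  }
  arch <- as.integer(o$architecture)
  w <- list(W1 = matrix(as.numeric(o$W1), arch[2], arch[1]),
            b1 = as.numeric(o$b1),
            W2 = matrix(as.numeric(o$W2), arch[3], arch[2]),
            b2 = as.numeric(o$b2))
  fr <- matrix(as.numeric(o$feature_range), 2, arch[1])
  colnames(fr) <- o$feature_names
  cfg <- o$config
  structure(list(weights = w,
                 x_center = stats::setNames(as.numeric(o$x_center), o$feature_names),
                 x_scale = stats::setNames(as.numeric(o$x_scale), o$feature_names),
                 y_center = stats::setNames(as.numeric(o$y_center), o$output_names),
                 y_scale = stats::setNames(as.numeric(o$y_scale), o$output_names),
                 feature_names = o$feature_names, output_names = o$output_names,
                 feature_range = fr, metrics = o$metrics,
                 config = train_config(
                   hidden_neurons = cfg$hidden_neurons,
                   fractions = as.numeric(cfg$fractions),
                   max_epochs = cfg$max_epochs, patience = cfg$patience,
                   seed = cfg$seed, optimizer = cfg$optimizer),
                 split = NULL),
            class = "spot_error_model")
}
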