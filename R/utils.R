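## Internal helpers shared across modules.

# Deterministic sub-seed derivation: every source of randomness in the
# package draws from a named substream of one global seed, so a pipeline
# run is reproducible from a single integer. Values stay below 2^31 - 1.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stream))
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 2147480000
  as.integer((as.numeric(seed) * 10007 + h) %% 2147480000 + 1)
}

# Evaluate expr with a locally-set RNG state; restores the caller's state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Full-precision numeric formatting for text round-trips: %.17g guarantees
# that as.numeric(format(x)) == x bit-for-bit for doubles.
fmt_full <- function(x) sprintf("%.17g", x)

# A scalar constant-or-function field: resolve against (gantry, energy).
resolve_field <- function(f, gantry_angle_deg, nominal_energy_MeV) {
  if (is.function(f)) f(gantry_angle_deg, nominal_energy_MeV) else f
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
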