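# Internal helpers shared across modules.

# Derive a reproducible sub-seed for component `index` of a run seeded with
# `seed`. All module-level randomness flows through this so that simulator
# outputs are reproducible piecewise (stream order is documented in each
# simulator). Constants are Lehmer/Park-Miller multipliers; result is kept
# strictly inside the 32-bit signed range R's RNG seeds require.
derive_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) * 48271 + (as.double(index) + 1) * 16807
  as.integer(s %% 2147483629) + 1L
}

abort_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

assert_count <- function(x, name) {
  abort_if(!is_count(x), "`", name, "` must be a positive integer, got ",
           deparse(substitute(x)))
}

assert_fraction <- function(x, name, open_left = TRUE) {
  ok <- length(x) == 1L && is.numeric(x) && is.finite(x) &&
    (if (open_left) x > 0 else x >= 0) && x <= 1
  abort_if(!ok, "`", name, "` must be a fraction in ",
           if (open_left) "(0, 1]" else "[0, 1]")
}

# Numeric sample columns of a count/score data.frame (everything that is not
# an annotation column).
sample_columns <- function(df) {
  ann <- c("guide_id", "target_id", "gene_symbol")
  setdiff(names(df), ann)
}
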