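# Internal helpers shared across modules.

# Round half away from zero.  Edge counts k = round(s * n(n-1)/2) must agree
# across platforms; IEC 60559 round-half-even would make k depend on the
# binary representation of the grid point.
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Derive a child seed from a master seed and a small offset, staying within
# the 32-bit integer range R requires of set.seed().
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %% .Machine$integer.max)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stop_config <- function(msg) {
  abort(msg, class = "connectopath_config_error")
}

stop_validation <- function(msg) {
  abort(msg, class = "connectopath_validation_error")
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

is_scalar_num <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x)
}

# Symmetry deviation of a square matrix.
asymmetry <- function(m) {
  max(abs(m - t(m)))
}
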