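
# single place for the stop() style used across the package: classed condition
# with a short machine-readable class so tests can assert on failures precisely
ls_abort <- function(msg, class) {
  abort(msg, class = paste0("lobulescreen_", class))
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == as.integer(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# deterministic derived seed for a sub-stage; keeps within 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)
}
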