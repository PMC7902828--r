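# internal helpers shared across modules

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a child RNG seed from a root seed and a stream index.
# Streams are fixed per operation (documented in synthetic_config) so that
# regenerating any single product with the same root seed is bit-identical.
# Kept strictly below .Machine$integer.max (R seeds are 32-bit).
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  (abs(as.numeric(seed)) * 101L + 7L * stream) %% 2147483647
}

stop_af <- function(fmt, ..., class = "amazonfire_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error")))
}

assert_years <- function(years) {
  if (length(years) < 1L || anyNA(years) || any(diff(years) <= 0))
    stop_af("`years` must be strictly increasing with no NA")
  as.integer(years)
}
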