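# internal helpers shared across modules

# Deterministic seed derivation: every stochastic component draws from a seed
# obtained as derive_seed(base, counter).  The scheme is a fixed affine hash
# modulo the Mersenne prime 2^31 - 1 so any single cell/restart is
# reproducible in isolation without consuming a shared RNG stream.
derive_seed <- function(base, counter) {
  stopifnot(is.numeric(base), length(base) == 1L, is.numeric(counter))
  as.integer((as.double(base) %% 2147483647 * 1000003 + as.double(counter)) %% 2147483647)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stop_input <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "golgiatlas_error")
}

# significance stars at the conventional 0.05/0.01/0.001/0.0001 levels
signif_stars <- function(p) {
  stopifnot(is.numeric(p))
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 1e-4 ~ "****",
    p < 1e-3 ~ "***",
    p < 1e-2 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}
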