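# shared internal helpers

# round half away from zero (printed percentages follow this convention,
# unlike base round()'s round-half-even)
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x == floor(x)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && is.finite(x)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
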