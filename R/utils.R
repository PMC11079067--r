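#' @keywords internal
"_PACKAGE"

## Canonical indicator set: absolute latencies I-V (ms), interpeak latencies
## (ms), amplitudes of waves I and V (uV).
BAEP_WAVES <- c("la_i", "la_ii", "la_iii", "la_iv", "la_v")
BAEP_INTERPEAKS <- c("la_i_iii", "la_iii_v", "la_i_v")
BAEP_AMPLITUDES <- c("am_i", "am_v")

#' Names of the BAEP indicators handled by the package
#'
#' Absolute latencies of waves I-V (ms), the I-III, III-V and I-V interpeak
#' latencies (ms), and the peak-to-trough amplitudes of waves I and V (uV).
#'
#' @return Character vector of the ten indicator column names.
#' @export
baep_indicators <- function() {
  c(BAEP_WAVES, BAEP_INTERPEAKS, BAEP_AMPLITUDES)
}

## Half-up rounding to `digits` decimals (the rounding used for printed
## percentages; base round() rounds half to even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

## Add interpeak latencies from the wave latencies already in `df`.
add_interpeaks <- function(df) {
  df$la_i_iii <- df$la_iii - df$la_i
  df$la_iii_v <- df$la_v - df$la_iii
  df$la_i_v <- df$la_v - df$la_i
  df
}

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
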