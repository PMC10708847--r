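#' ADC conversion constants for the headset front end
#'
#' The single-channel headset digitizes the Fp1-to-ear voltage with an
#' amplifier gain of 2000, a 4096-step ADC and a 1.8 V input range. One raw
#' unit therefore corresponds to `1.8 / 4096 / 2000` volts, about 0.22 uV.
#'
#' @param input_voltage ADC input range in volts.
#' @param value_range Number of ADC steps.
#' @param gain Amplifier gain (dimensionless).
#'
#' @return A list of class `conversion_constants` with fields
#'   `input_voltage`, `value_range`, `gain` and the derived `uv_per_unit`.
#' @examples
#' conversion_constants()$uv_per_unit
#' @export
conversion_constants <- function(input_voltage = 1.8, value_range = 4096,
                                 gain = 2000) {
  stopifnot(input_voltage > 0, value_range > 0, gain > 0)
  structure(
    list(
      input_voltage = input_voltage,
      value_range = value_range,
      gain = gain,
      uv_per_unit = input_voltage / value_range / gain * 1e6
    ),
    class = "conversion_constants"
  )
}

#' Convert raw vendor units to volts or microvolts
#'
#' `raw_to_volts()` applies `volts = raw * (input_voltage / value_range) / gain`
#' elementwise; `raw_to_uv()` returns the same quantity in microvolts, and
#' `uv_to_raw()` inverts it, rounding to the nearest integer unit and clipping
#' to the signed vendor range `[-value_range/2, value_range/2 - 1]`.
#'
#' @param raw Numeric vector of vendor-unit samples.
#' @param uv Numeric vector of amplitudes in microvolts.
#' @param constants A [conversion_constants()] object.
#'
#' @return Numeric vector (`raw_to_volts`, `raw_to_uv`) or integer vector
#'   (`uv_to_raw`). `uv_to_raw()` carries an attribute `n_clipped` with the
#'   number of samples that hit the vendor range.
#' @examples
#' raw_to_volts(2048) # 4.5e-4 V = 450 uV
#' raw_to_uv(uv_to_raw(12.3))
#' @export
raw_to_volts <- function(raw, constants = conversion_constants()) {
  raw * (constants$input_voltage / constants$value_range) / constants$gain
}

#' @rdname raw_to_volts
#' @export
raw_to_uv <- function(raw, constants = conversion_constants()) {
  raw_to_volts(raw, constants) * 1e6
}

#' @rdname raw_to_volts
#' @export
uv_to_raw <- function(uv, constants = conversion_constants()) {
  units <- round(uv / constants$uv_per_unit)
  lo <- -constants$value_range / 2
  hi <- constants$value_range / 2 - 1
  n_clipped <- sum(units < lo | units > hi)
  out <- as.integer(pmin(pmax(units, lo), hi))
  attr(out, "n_clipped") <- n_clipped
  out
}
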