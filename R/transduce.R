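#' Simulate the conditioning circuit and ADC
#'
#' Applies the current-mirror transduction model to a force recording: the
#' mirror replicates the FSR current in the gain resistor, so
#' `V = R_G * V_CC * (conductance_offset + sensitivity * force)`, linear in
#' force up to the saturation force, clamped to the `[0, V_CC]` supply range
#' and quantized to `adc_bits` levels over that range.
#'
#' @param rec an [fsr_recording()] in kilograms.
#' @param calib an [fsr_calibration()] with one entry per channel.
#' @param acq an [acquisition_config()].
#' @return Numeric matrix of quantized voltages, samples x channels.
#' @export
transduce <- function(rec, calib = default_fsr_calibration(acq),
                      acq = acquisition_config()) {
  if (length(calib$sensitivity) != ncol(rec$forces)) {
    stop("calibration channel count does not match the recording")
  }
  force <- pmin(rec$forces,
                matrix(calib$saturation_force, nrow(rec$forces),
                       ncol(rec$forces), byrow = TRUE))
  conduct <- sweep(sweep(force, 2, calib$sensitivity, `*`),
                   2, calib$conductance_offset, `+`)
  volts <- sweep(conduct, 2, acq$gain_resistances * acq$v_cc, `*`)
  volts <- pmin(pmax(volts, 0), acq$v_cc)
  step <- acq$v_cc / (2^acq$adc_bits - 1)
  round(volts / step) * step
}

#' Invert the transduction back to forces
#'
#' Inverts the affine force-to-voltage map below saturation. Saturated
#' samples (voltage at the supply rail, or force beyond the calibration's
#' saturation force) cannot be inverted and are returned as `NA`.
#'
#' @param voltages matrix of voltages as produced by [transduce()].
#' @param calib the [fsr_calibration()] used for transduction.
#' @param acq the [acquisition_config()] used for transduction.
#' @return Numeric matrix of forces in kg; `NA` where saturated. The
#'   round-trip error for unsaturated samples is at most one ADC step
#'   divided by the volts-per-kg slope.
#' @export
inverse_calibrate <- function(voltages, calib = default_fsr_calibration(acq),
                              acq = acquisition_config()) {
  voltages <- as.matrix(voltages)
  if (length(calib$sensitivity) != ncol(voltages)) {
    stop("calibration channel count does not match the voltage trace")
  }
  if (any(voltages < 0 | voltages > acq$v_cc)) {
    stop("voltages must lie within [0, v_cc]")
  }
  step <- acq$v_cc / (2^acq$adc_bits - 1)
  conduct <- sweep(voltages, 2, acq$gain_resistances * acq$v_cc, `/`)
  force <- sweep(sweep(conduct, 2, calib$conductance_offset, `-`),
                 2, calib$sensitivity, `/`)
  sat_force <- matrix(calib$saturation_force, nrow(force), ncol(force),
                      byrow = TRUE)
  rail <- voltages >= acq$v_cc - step / 2
  force[rail | force > sat_force] <- NA_real_
  force
}
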