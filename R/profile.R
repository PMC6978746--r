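#' Acquisition configuration
#'
#' Sampling and conditioning-circuit constants of the armband front end: each
#' FSR drives a current mirror whose output voltage is read by an ADC.
#'
#' @param sampling_rate sampling frequency in Hz. Default 1000.
#' @param adc_bits ADC resolution in bits. Default 12.
#' @param v_cc supply voltage in volts. Default 5.
#' @param gain_resistances per-channel gain resistor values in ohms.
#'   Defaults 850, 790 and 960 ohms, chosen per channel to equalize the three
#'   volts-per-kilogram gains.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(sampling_rate = 1000, adc_bits = 12L,
                               v_cc = 5, gain_resistances = c(850, 790, 960)) {
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  if (adc_bits < 1) stop("adc_bits must be >= 1")
  if (length(gain_resistances) != 3 || any(gain_resistances <= 0)) {
    stop("gain_resistances must be three positive values")
  }
  structure(
    list(sampling_rate = sampling_rate, adc_bits = as.integer(adc_bits),
         v_cc = v_cc, gain_resistances = gain_resistances),
    class = "acquisition_config"
  )
}

#' Static FSR calibration
#'
#' Affine force-to-conductance model per channel. The conditioning circuit
#' mirrors the FSR current into the gain resistor, so the output voltage is
#' `V = R_G * V_CC * (conductance_offset + sensitivity * force)` up to the
#' saturation force, then clamps at the supply rail.
#'
#' @param conductance_offset rest conductance per channel, siemens.
#' @param sensitivity conductance gain per channel, siemens per kg; all > 0.
#' @param saturation_force force beyond which the sensor saturates, kg.
#' @return An object of class `fsr_calibration`.
#' @export
fsr_calibration <- function(conductance_offset, sensitivity,
                            saturation_force = 3) {
  if (length(conductance_offset) != length(sensitivity)) {
    stop("conductance_offset and sensitivity must have equal length")
  }
  if (any(sensitivity <= 0)) stop("sensitivity must be > 0")
  structure(
    list(conductance_offset = conductance_offset, sensitivity = sensitivity,
         saturation_force = rep_len(saturation_force,
                                    length(conductance_offset))),
    class = "fsr_calibration"
  )
}

#' Default FSR calibration for a given acquisition configuration
#'
#' No tabulated calibration curves are published for the sensors, so the
#' defaults fix only the conventions the circuit model implies: sensitivities
#' are chosen inversely proportional to the gain resistors so all channels
#' share one volts-per-kg slope (2 V/kg, putting a ~1 kg plateau at mid-range
#' of the 5 V ADC span), and the rest conductance puts the zero-force
#' baseline at 0.5 V.
#'
#' @param acq an [acquisition_config()].
#' @param volts_per_kg common channel gain, volts per kilogram.
#' @param baseline_volts zero-force output voltage.
#' @return An `fsr_calibration` with one entry per channel.
#' @export
default_fsr_calibration <- function(acq = acquisition_config(),
                                    volts_per_kg = 2, baseline_volts = 0.5) {
  rg <- acq$gain_resistances
  fsr_calibration(
    conductance_offset = baseline_volts / (acq$v_cc * rg),
    sensitivity = volts_per_kg / (acq$v_cc * rg),
    saturation_force = 3
  )
}

#' Muscle activation profile of the gesture protocol
#'
#' Describes the force each sensor sees while a gesture is held: a 3 x 8
#' plateau matrix (channel x gesture, kg), trapezoidal burst timing, the
#' armband fastening preload, sensor noise, and the per-subject scale/offset
#' perturbation that models armband re-donning and anatomical differences.
#'
#' @param plateau_force 3 x 8 numeric matrix of plateau forces in kg; column
#'   names must be the gesture labels and the rest column must be zero.
#' @param rise_time,hold_time,fall_time,rest_gap burst timing in seconds.
#'   Gestures are held for about two seconds; the transition into and out of
#'   a posture is brisk (0.1 s), matching the near-rectangular contraction
#'   bursts seen on real recordings -- slow transitions would leak ramp
#'   samples into the above-threshold segment and inflate the mean-vs-median
#'   deviation well beyond the ~2% level the held postures actually show.
#' @param preload armband fastening force at rest, kg (default 0.1).
#' @param noise_sd additive Gaussian sensor noise, kg.
#' @param rep_jitter_sd lognormal sdlog of the per-repetition, per-channel
#'   amplitude factor: a subject does not reproduce a contraction force
#'   exactly from one repetition to the next, so each burst's plateau is
#'   scaled by an independent factor (default 5% spread).
#' @param subject_scale per-channel multiplicative factor (default 1).
#' @param subject_offset per-channel additive offset in kg (default 0).
#' @return An object of class `activation_profile`.
#' @export
activation_profile <- function(plateau_force,
                               rise_time = 0.1, hold_time = 2,
                               fall_time = 0.1, rest_gap = 3,
                               preload = 0.1, noise_sd = 0.02,
                               rep_jitter_sd = 0.05,
                               subject_scale = rep(1, 3),
                               subject_offset = rep(0, 3)) {
  stopifnot(is.matrix(plateau_force), nrow(plateau_force) == 3,
            ncol(plateau_force) == 8)
  if (is.null(colnames(plateau_force))) {
    colnames(plateau_force) <- gesture_labels()
  }
  if (!identical(colnames(plateau_force), gesture_labels())) {
    stop("plateau_force columns must follow the protocol gesture order")
  }
  if (any(plateau_force[, "rest"] != 0)) {
    stop("the rest column of plateau_force must be zero")
  }
  if (preload < 0 || noise_sd < 0) stop("preload and noise_sd must be >= 0")
  if (rep_jitter_sd < 0) stop("rep_jitter_sd must be >= 0")
  if (any(c(rise_time, hold_time, fall_time, rest_gap) < 0)) {
    stop("timing parameters must be >= 0")
  }
  structure(
    list(plateau_force = plateau_force, rise_time = rise_time,
         hold_time = hold_time, fall_time = fall_time, rest_gap = rest_gap,
         preload = preload, noise_sd = noise_sd,
         rep_jitter_sd = rep_jitter_sd,
         subject_scale = rep_len(subject_scale, 3),
         subject_offset = rep_len(subject_offset, 3)),
    class = "activation_profile"
  )
}

#' Default activation profile
#'
#' Plateau forces encode the functional anatomy of the three monitored
#' muscles: flexor carpi ulnaris (channel 1) drives wrist flexion and
#' adduction, flexor carpi radialis (channel 2) wrist flexion and abduction,
#' and extensor digitorum (channel 3) wrist/finger extension and finger
#' abduction. Gesture patterns are mutually distant (pairwise Euclidean
#' separation well above six noise SDs) so that, as observed on real
#' recordings, gesture clusters in feature space do not overlap.
#'
#' @inheritParams activation_profile
#' @return An `activation_profile` with the default plateau matrix.
#' @export
#' @examples
#' p <- default_activation_profile()
#' p$plateau_force[, "wrist_extension"]  # extensor digitorum dominates
default_activation_profile <- function(noise_sd = 0.02, preload = 0.1) {
  plateau <- cbind(
    rest              = c(0,    0,    0),
    wrist_flexion     = c(0.80, 0.70, 0.10),
    wrist_extension   = c(0.10, 0.10, 0.90),
    wrist_adduction   = c(0.70, 0.15, 0.20),
    wrist_abduction   = c(0.15, 0.75, 0.15),
    wrist_rotation    = c(0.30, 0.45, 0.35),
    fingers_abduction = c(0.20, 0.25, 0.75),
    clenched_fist     = c(0.90, 0.85, 1.00)
  )
  rownames(plateau) <- sensor_channels()$muscle
  activation_profile(plateau, noise_sd = noise_sd, preload = preload)
}

#' Draw subject-specific armband variability
#'
#' Models inter-subject differences and armband re-donning as a fixed
#' per-channel multiplicative gain (lognormal, sdlog 0.25) plus an additive
#' offset (uniform on +/- 0.05 kg). Applying this to a common profile yields
#' distinct but internally consistent subjects, which is what degrades a
#' classifier trained on the pooled multi-subject database relative to
#' per-subject training.
#'
#' @param profile an [activation_profile()] to perturb.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @param sdlog lognormal sdlog of the channel gains.
#' @param offset_range half-width of the uniform channel offset, kg.
#' @return The profile with `subject_scale` and `subject_offset` replaced by
#'   a fresh draw.
#' @export
draw_subject_profile <- function(profile, seed, sdlog = 0.25,
                                 offset_range = 0.05) {
  with_seed(seed, {
    profile$subject_scale <- stats::rlnorm(3, meanlog = 0, sdlog = sdlog)
    profile$subject_offset <- stats::runif(3, -offset_range, offset_range)
  })
  profile
}
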