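#' Construct a raw armband recording
#'
#' @param forces numeric matrix, samples x 3 channels, in kilograms.
#' @param sampling_rate Hz.
#' @param timeline optional data.frame with columns `start_sample`,
#'   `end_sample` (0-based, half-open) and `label`, giving the ground-truth
#'   held-posture intervals.
#' @param subject_id identifier string.
#' @return An object of class `fsr_recording`.
#' @export
fsr_recording <- function(forces, sampling_rate, timeline = NULL,
                          subject_id = "anonymous") {
  forces <- as.matrix(forces)
  if (ncol(forces) != 3) stop("a recording must have exactly 3 channels")
  if (!all(is.finite(forces))) stop("all force samples must be finite")
  dimnames(forces) <- list(NULL, paste0("fsr", 1:3))
  if (!is.null(timeline)) {
    stopifnot(all(c("start_sample", "end_sample", "label") %in%
                    names(timeline)))
    if (nrow(timeline)) {
      o <- order(timeline$start_sample)
      timeline <- timeline[o, , drop = FALSE]
      rownames(timeline) <- NULL
      if (any(timeline$start_sample >= timeline$end_sample)) {
        stop("timeline intervals must be non-empty")
      }
      if (any(timeline$start_sample < 0) ||
          any(timeline$end_sample > nrow(forces))) {
        stop("timeline intervals must lie within the recording")
      }
      if (nrow(timeline) > 1 &&
          any(timeline$start_sample[-1] <
              timeline$end_sample[-nrow(timeline)])) {
        stop("timeline intervals must not overlap")
      }
    }
  }
  structure(
    list(forces = forces, sampling_rate = sampling_rate,
         timeline = timeline, subject_id = subject_id),
    class = "fsr_recording"
  )
}

#' @export
print.fsr_recording <- function(x, ...) {
  n <- nrow(x$forces)
  cat(sprintf("<fsr_recording> subject '%s': %d samples x 3 channels @ %g Hz (%.1f s)\n",
              x$subject_id, n, x$sampling_rate, n / x$sampling_rate))
  if (!is.null(x$timeline)) {
    cat(sprintf("  timeline: %d held-posture intervals\n", nrow(x$timeline)))
  }
  invisible(x)
}

# Slice the samples of a half-open 0-based interval out of a force matrix.
interval_rows <- function(start_sample, end_sample) {
  seq.int(start_sample + 1L, end_sample)
}

#' Generate one synthetic armband trial
#'
#' Simulates the acquisition protocol: each listed gesture is performed
#' `repetitions` times in a row, each repetition being a trapezoidal
#' contraction burst (linear rise, held plateau, linear fall) followed by a
#' rest gap; a leading rest gap precedes the first burst. The force seen by
#' channel `c` during gesture `g` is
#' `preload + subject_offset[c] + subject_scale[c] * jitter[r, c] *
#' envelope(t) * plateau_force[c, g]` plus i.i.d. Gaussian noise, clamped at
#' zero (an FSR cannot report a negative force); `jitter[r, c]` is the
#' lognormal per-repetition amplitude factor modelling imperfect force
#' reproduction across repetitions. The ground-truth timeline records each
#' held plateau with its label, rest repetitions included.
#'
#' @param profile an [activation_profile()].
#' @param acq an [acquisition_config()]; only the sampling rate is used here.
#' @param repetitions number of consecutive repetitions per gesture, >= 1.
#' @param gestures character vector of gesture labels, performed in order.
#' @param seed integer seed; equal seeds give bit-identical recordings.
#' @param subject_id identifier stored on the recording.
#' @return An [fsr_recording()] with a ground-truth timeline.
#' @export
#' @examples
#' rec <- generate_trial(default_activation_profile(), acquisition_config(),
#'                       repetitions = 2, gestures = "clenched_fist", seed = 1)
#' nrow(rec$timeline)  # 2 plateau intervals
generate_trial <- function(profile, acq = acquisition_config(),
                           repetitions, gestures, seed,
                           subject_id = "anonymous") {
  if (length(repetitions) != 1 || is.na(repetitions) || repetitions < 1) {
    stop("repetitions must be a single integer >= 1")
  }
  repetitions <- as.integer(repetitions)
  if (length(gestures) == 0) stop("gestures must be non-empty")
  gesture_code(gestures)  # validates names
  fs <- acq$sampling_rate
  n_rise <- round(profile$rise_time * fs)
  n_hold <- round(profile$hold_time * fs)
  n_fall <- round(profile$fall_time * fs)
  n_gap <- round(profile$rest_gap * fs)
  if (n_hold < 1) stop("hold_time must span at least one sample")

  burst_env <- c(seq_len(n_rise) / (n_rise + 1),
                 rep(1, n_hold),
                 rev(seq_len(n_fall) / (n_fall + 1)),
                 rep(0, n_gap))
  n_burst <- length(burst_env)
  n_total <- n_gap + n_burst * repetitions * length(gestures)

  envelope <- numeric(n_total)
  gesture_idx <- rep(1L, n_total)  # column index into the plateau matrix
  burst_idx <- rep(1L, n_total)    # row index into the jitter matrix
  starts <- integer(0)
  labels <- character(0)
  pos <- n_gap  # 0-based start of the next burst
  burst <- 0L
  for (g in gestures) {
    col <- gesture_code(g) + 1L
    for (r in seq_len(repetitions)) {
      burst <- burst + 1L
      rows <- interval_rows(pos, pos + n_burst)
      envelope[rows] <- burst_env
      gesture_idx[rows] <- col
      burst_idx[rows] <- burst
      starts <- c(starts, pos + n_rise)
      labels <- c(labels, g)
      pos <- pos + n_burst
    }
  }
  n_bursts <- burst
  timeline <- data.frame(start_sample = as.integer(starts),
                         end_sample = as.integer(starts + n_hold),
                         label = labels, stringsAsFactors = FALSE)

  plateau_t <- t(profile$plateau_force)  # gesture x channel
  noisy <- with_seed(seed, {
    jitter <- matrix(stats::rlnorm(n_bursts * 3, meanlog = 0,
                                   sdlog = profile$rep_jitter_sd),
                     n_bursts, 3)
    clean <- envelope * plateau_t[gesture_idx, , drop = FALSE] *
      jitter[burst_idx, , drop = FALSE]
    clean <- sweep(clean, 2, profile$subject_scale, `*`)
    clean <- sweep(clean, 2, profile$subject_offset + profile$preload, `+`)
    clean + matrix(stats::rnorm(length(clean), sd = profile$noise_sd),
                   nrow = nrow(clean))
  })
  noisy[noisy < 0] <- 0
  fsr_recording(noisy, fs, timeline, subject_id)
}

#' Generate a full calibration session for one subject
#'
#' Runs the whole protocol -- every gesture class in protocol order, each as
#' its own recording block of `repetitions` consecutive repetitions -- the
#' way a calibration session is acquired (one recording per gesture class,
#' with rests in between). Block seeds are derived from `seed`, so the whole
#' session is reproducible from one integer.
#'
#' @inheritParams generate_trial
#' @param gestures gesture classes to record; defaults to the full protocol.
#' @return A named list of [fsr_recording()] blocks, one per gesture class,
#'   with class `fsr_session`.
#' @export
generate_session <- function(profile, acq = acquisition_config(),
                             repetitions = 10, seed = 0,
                             subject_id = "anonymous",
                             gestures = gesture_labels()) {
  blocks <- lapply(seq_along(gestures), function(i) {
    generate_trial(profile, acq, repetitions, gestures[i],
                   seed = derive_seed(seed, i), subject_id = subject_id)
  })
  names(blocks) <- gestures
  structure(blocks, class = c("fsr_session", "list"))
}

#' Generate a randomized mixed-gesture trial
#'
#' Emulates the video-guided second session used to test day-to-day
#' reproducibility: `n_gestures` single repetitions of randomly chosen
#' gestures, separated by the rest condition.
#'
#' @inheritParams generate_trial
#' @param n_gestures number of gesture instances (default 50).
#' @param include_rest should rest be among the candidate gestures?
#' @return An [fsr_recording()] with a ground-truth timeline.
#' @export
generate_random_sequence <- function(profile, acq = acquisition_config(),
                                     n_gestures = 50, seed = 0,
                                     subject_id = "anonymous",
                                     include_rest = TRUE) {
  pool <- gesture_labels()
  if (!include_rest) pool <- setdiff(pool, "rest")
  seq_labels <- with_seed(derive_seed(seed, 977L), {
    sample(pool, n_gestures, replace = TRUE)
  })
  generate_trial(profile, acq, repetitions = 1, gestures = seq_labels,
                 seed = derive_seed(seed, 978L), subject_id = subject_id)
}
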