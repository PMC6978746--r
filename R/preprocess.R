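#' Segmentation configuration
#'
#' @param threshold_fraction fraction of the selected channel's peak-to-peak
#'   amplitude at which the threshold is set (default 0.40, which reliably
#'   isolates every held posture while discarding rise/fall transients).
#' @param min_segment_duration shortest accepted segment, seconds; rejects
#'   noise spikes.
#' @param merge_gap two above-threshold runs closer than this (seconds) are
#'   merged into one segment.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(threshold_fraction = 0.40,
                                min_segment_duration = 0.5,
                                merge_gap = 0.1) {
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    stop("threshold_fraction must lie strictly between 0 and 1")
  }
  if (min_segment_duration < 0 || merge_gap < 0) {
    stop("durations must be >= 0")
  }
  structure(
    list(threshold_fraction = threshold_fraction,
         min_segment_duration = min_segment_duration,
         merge_gap = merge_gap),
    class = "segmentation_config"
  )
}

#' Rest-offset subtraction and amplitude normalization
#'
#' Subtracts, per channel, the minimum value observed over the rest
#' reference (the offset due to the armband fastening pressure), then
#' normalizes all channels jointly by the global maximum absolute value so
#' the preprocessed recording peaks at exactly 1. A precomputed `scale` may
#' be supplied so several recording blocks of one session share a common
#' normalization.
#'
#' @param rec an [fsr_recording()].
#' @param rest_reference either an [fsr_recording()] of the rest condition,
#'   or a length-2 integer vector `c(start_sample, end_sample)` (0-based,
#'   half-open) naming a rest interval inside `rec`.
#' @param scale optional positive normalization divisor; if `NULL`, the
#'   global max absolute value after offset subtraction is used.
#' @return The preprocessed `fsr_recording`, with fields `offsets` (kg per
#'   channel) and `scale` (kg) recording the applied transform.
#' @export
preprocess <- function(rec, rest_reference = rec, scale = NULL) {
  if (inherits(rest_reference, "fsr_recording")) {
    rest <- rest_reference$forces
  } else {
    if (length(rest_reference) != 2 ||
        rest_reference[1] >= rest_reference[2]) {
      stop("rest_reference interval must be a half-open c(start, end)")
    }
    rest <- rec$forces[interval_rows(rest_reference[1], rest_reference[2]), ,
                       drop = FALSE]
  }
  if (nrow(rest) == 0) stop("rest reference is empty")
  offsets <- apply(rest, 2, min)
  centred <- sweep(rec$forces, 2, offsets, `-`)
  if (is.null(scale)) {
    scale <- max(abs(centred))
    if (scale == 0) {
      stop("degenerate recording: all zero after offset removal, ",
           "normalization undefined")
    }
  }
  if (scale <= 0) stop("scale must be > 0")
  out <- fsr_recording(centred / scale, rec$sampling_rate, rec$timeline,
                       rec$subject_id)
  out$offsets <- offsets
  out$scale <- scale
  out
}

#' Preprocess all blocks of a session with one shared transform
#'
#' Offsets come from the session's rest block; the normalization scale is the
#' global maximum absolute value across all offset-subtracted blocks, so
#' features are comparable across gesture classes.
#'
#' @param session an `fsr_session` (list of blocks) from
#'   [generate_session()], containing a `rest` block.
#' @return A list of preprocessed blocks with attributes `offsets` and
#'   `scale`.
#' @export
preprocess_session <- function(session) {
  if (!"rest" %in% names(session)) {
    stop("session must contain a 'rest' block to serve as rest reference")
  }
  offsets <- apply(session$rest$forces, 2, min)
  scale <- max(vapply(session, function(b) {
    max(abs(sweep(b$forces, 2, offsets, `-`)))
  }, numeric(1)))
  if (scale == 0) stop("degenerate session: all blocks flat at rest level")
  out <- lapply(session, function(b) {
    p <- preprocess(b, rest_reference = session$rest, scale = scale)
    p
  })
  attr(out, "offsets") <- offsets
  attr(out, "scale") <- scale
  class(out) <- c("fsr_session", "list")
  out
}

#' Select the channel used for threshold segmentation
#'
#' Returns the channel with the largest variation (peak-to-peak amplitude);
#' ties go to the lowest channel index.
#'
#' @param rec an [fsr_recording()].
#' @return Integer channel index in 1..3.
#' @export
select_segmentation_channel <- function(rec) {
  p2p <- apply(rec$forces, 2, function(x) max(x) - min(x))
  # which.max takes the first maximum: lowest-index tie-break
  unname(which.max(p2p))
}

#' Threshold segmentation of held postures
#'
#' On the selected channel `x`, the threshold is
#' `min(x) + threshold_fraction * (max(x) - min(x))`; segments are the
#' maximal runs of samples at or above the threshold, after merging runs
#' separated by less than `merge_gap` and dropping runs shorter than
#' `min_segment_duration`. Because the threshold sits at 40% of the
#' peak-to-peak amplitude, rise and fall transients are excluded by
#' construction. A flat signal yields no segments.
#'
#' @param rec a preprocessed [fsr_recording()] (any offset-referenced
#'   recording works: the threshold is relative, so segmentation is
#'   invariant under positive affine transforms of the channel).
#' @param cfg a [segmentation_config()].
#' @param channel channel index to threshold; default auto-selected with
#'   [select_segmentation_channel()].
#' @return A data.frame with columns `start_sample`, `end_sample` (0-based,
#'   half-open), `channel`, `label` (`NA` until labelled), sorted and
#'   disjoint.
#' @export
segment_recording <- function(rec, cfg = segmentation_config(),
                              channel = NULL) {
  if (is.null(channel)) channel <- select_segmentation_channel(rec)
  x <- rec$forces[, channel]
  lo <- min(x); hi <- max(x)
  empty <- data.frame(start_sample = integer(0), end_sample = integer(0),
                      channel = integer(0), label = character(0),
                      stringsAsFactors = FALSE)
  if (hi == lo) return(empty)
  threshold <- lo + cfg$threshold_fraction * (hi - lo)
  fs <- rec$sampling_rate
  above <- x >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)          # 1-based inclusive run ends
  starts <- ends - r$lengths + 1L
  run_start <- starts[r$values] - 1L # 0-based half-open
  run_end <- ends[r$values]
  if (length(run_start) == 0) return(empty)

  gap_samples <- round(cfg$merge_gap * fs)
  if (length(run_start) > 1) {
    gap <- run_start[-1] - run_end[-length(run_end)]
    grp <- cumsum(c(1L, as.integer(gap >= gap_samples)))
    first <- !duplicated(grp)
    last <- !duplicated(grp, fromLast = TRUE)
    run_start <- run_start[first]  # grp is non-decreasing, so first/last of
    run_end <- run_end[last]       # each group bound the merged span
  }
  keep <- (run_end - run_start) >= round(cfg$min_segment_duration * fs)
  run_start <- run_start[keep]; run_end <- run_end[keep]
  data.frame(start_sample = as.integer(run_start),
             end_sample = as.integer(run_end),
             channel = rep(as.integer(channel), length(run_start)),
             label = rep(NA_character_, length(run_start)),
             stringsAsFactors = FALSE)
}

#' Assign ground-truth labels to segments
#'
#' Each segment receives the label of the timeline interval it overlaps
#' most; segments overlapping no interval stay `NA` (unlabeled).
#'
#' @param segments a segment data.frame from [segment_recording()].
#' @param timeline a timeline data.frame (`start_sample`, `end_sample`,
#'   `label`).
#' @return The segments with the `label` column filled in.
#' @export
label_segments <- function(segments, timeline) {
  if (is.null(timeline)) stop("no timeline available for labelling")
  if (nrow(segments) == 0) return(segments)
  segments$label <- vapply(seq_len(nrow(segments)), function(i) {
    ov <- pmin(segments$end_sample[i], timeline$end_sample) -
      pmax(segments$start_sample[i], timeline$start_sample)
    if (all(ov <= 0)) NA_character_ else timeline$label[which.max(ov)]
  }, character(1))
  segments
}

#' Sample rest windows from below-threshold stretches
#'
#' Rest produces no threshold crossing, so to let the rest condition
#' participate as a class, fixed-length windows are sampled from the
#' stretches between detected segments (or tiled evenly across the recording
#' when it contains no segments at all, as in a rest-only block).
#'
#' @param rec an [fsr_recording()].
#' @param segments detected segments in `rec` (possibly empty).
#' @param n number of rest windows wanted.
#' @param window_seconds window length in seconds (defaults to the typical
#'   gesture hold duration, 2 s, so rest rows match gesture rows in support).
#' @return A segment data.frame of `n` windows with `channel = NA`.
#' @export
rest_windows <- function(rec, segments, n, window_seconds = 2) {
  w <- round(window_seconds * rec$sampling_rate)
  total <- nrow(rec$forces)
  if (w < 1 || w > total) stop("rest window does not fit the recording")
  if (nrow(segments) == 0) {
    if (n * w > total) stop("recording too short for ", n, " rest windows")
    starts <- floor(seq(0, total - w, length.out = n))
  } else {
    gap_start <- c(0L, segments$end_sample)
    gap_end <- c(segments$start_sample, total)
    len <- gap_end - gap_start
    ok <- len >= w
    if (sum(ok) < 1) stop("no between-segment gap can hold a rest window")
    cand <- floor(gap_start[ok] + (len[ok] - w) / 2)  # centred in each gap
    if (length(cand) < n) {
      stop("only ", length(cand), " gaps can hold a rest window, need ", n)
    }
    starts <- cand[floor(seq_len(n) * length(cand) / n)]
  }
  data.frame(start_sample = as.integer(starts),
             end_sample = as.integer(starts + w),
             channel = rep(NA_integer_, n),
             label = rep("rest", n),
             stringsAsFactors = FALSE)
}
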