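#' Per-segment mean/SD feature extraction
#'
#' For every segment, computes the mean and standard deviation of each of
#' the three channels over the segment's samples, yielding one row of six
#' features plus the gesture label. SDs use the sample (n-1) convention;
#' segments are hundreds of samples long so the choice is numerically
#' immaterial, but it is fixed for reproducibility.
#'
#' @param rec an [fsr_recording()] (normally preprocessed).
#' @param segments a labelled segment data.frame.
#' @param subject_id overrides the recording's subject id if given.
#' @return A `gesture_db` data.frame with columns `fsr1_mean..fsr3_mean`,
#'   `fsr1_sd..fsr3_sd`, `label`, `subject_id` and attribute `sensor_mask`.
#' @export
extract_features <- function(rec, segments, subject_id = rec$subject_id) {
  feats <- t(vapply(seq_len(nrow(segments)), function(i) {
    seg <- rec$forces[interval_rows(segments$start_sample[i],
                                    segments$end_sample[i]), , drop = FALSE]
    c(colMeans(seg), apply(seg, 2, stats::sd))
  }, numeric(6)))
  if (nrow(segments) == 0) feats <- matrix(numeric(0), 0, 6)
  colnames(feats) <- c(paste0("fsr", 1:3, "_mean"), paste0("fsr", 1:3, "_sd"))
  db <- data.frame(feats,
                   label = segments$label,
                   subject_id = rep(subject_id, nrow(segments)),
                   stringsAsFactors = FALSE)
  gesture_db(db, sensor_mask = 1:3)
}

#' Mark a data.frame as a gesture feature database
#'
#' @param db data.frame of feature rows (means then SDs per active sensor,
#'   plus `label` and `subject_id`).
#' @param sensor_mask integer subset of 1:3 naming the sensors whose
#'   features are present.
#' @return `db` with class `gesture_db` and the mask attribute.
#' @export
gesture_db <- function(db, sensor_mask = 1:3) {
  stopifnot(all(c("label", "subject_id") %in% names(db)))
  attr(db, "sensor_mask") <- as.integer(sensor_mask)
  class(db) <- unique(c("gesture_db", class(db)))
  db
}

#' Feature columns of a gesture database
#' @param db a `gesture_db`.
#' @return Numeric matrix of the feature columns, in database order.
#' @export
db_features <- function(db) {
  cols <- setdiff(names(db), c("label", "subject_id"))
  as.matrix(db[, cols, drop = FALSE])
}

#' Mean-vs-median deviation per segment
#'
#' The held-posture signal is stationary but its sample distribution is not
#' exactly Gaussian, so the median is a candidate alternative to the mean.
#' This computes, per segment, the percentage deviation
#' `100 * |mean - median| / mean` on one channel. Under symmetric noise the
#' deviation stays well below 2%, which is why the cheaper mean is used as
#' the feature.
#'
#' @param rec an [fsr_recording()].
#' @param segments segment data.frame.
#' @param channel channel to assess; default the segmentation channel.
#' @return Numeric vector of percent deviations, `NA` where a segment mean
#'   is zero (deviation undefined).
#' @export
median_check <- function(rec, segments, channel = NULL) {
  if (is.null(channel)) channel <- select_segmentation_channel(rec)
  vapply(seq_len(nrow(segments)), function(i) {
    x <- rec$forces[interval_rows(segments$start_sample[i],
                                  segments$end_sample[i]), channel]
    m <- mean(x)
    if (m == 0) return(NA_real_)
    100 * abs(m - stats::median(x)) / abs(m)
  }, numeric(1))
}

#' Concatenate per-subject databases
#'
#' @param dbs list of `gesture_db` objects with identical feature columns.
#' @return One `gesture_db` with all rows; per-row `subject_id` provenance
#'   is retained.
#' @export
combine_databases <- function(dbs) {
  if (length(dbs) == 0) {
    return(gesture_db(data.frame(label = character(0),
                                 subject_id = character(0),
                                 stringsAsFactors = FALSE),
                      sensor_mask = integer(0)))
  }
  masks <- lapply(dbs, attr, "sensor_mask")
  if (length(unique(masks)) != 1) {
    stop("databases must share one sensor mask to be combined")
  }
  out <- do.call(rbind, lapply(dbs, as.data.frame))
  rownames(out) <- NULL
  gesture_db(out, sensor_mask = masks[[1]])
}

#' Restrict a database to a sensor subset
#'
#' Keeps the mean and SD columns of the masked sensors: a pair keeps four
#' features, a single sensor two.
#'
#' @param db a `gesture_db`.
#' @param mask integer subset of the database's active sensors.
#' @return The projected `gesture_db`.
#' @export
project_sensors <- function(db, mask) {
  mask <- sort(as.integer(mask))
  if (length(mask) == 0 || !all(mask %in% attr(db, "sensor_mask"))) {
    stop("mask must be a non-empty subset of the database's sensors")
  }
  keep <- c(paste0("fsr", mask, "_mean"), paste0("fsr", mask, "_sd"),
            "label", "subject_id")
  gesture_db(db[, keep, drop = FALSE], sensor_mask = mask)
}

#' Build the gesture database of one calibration session
#'
#' The full batch pipeline: preprocess all blocks with the session-wide
#' transform, segment each gesture block on its own best channel, label the
#' segments from the ground-truth timeline, represent each rest repetition
#' by a fixed-length window between (or, in the rest block, tiled across)
#' the below-threshold stretches, and extract mean/SD features. A full
#' 10-repetition protocol yields an 80-row database (10 repetitions x 8
#' gestures, 6 features + label).
#'
#' @param session an `fsr_session` from [generate_session()].
#' @param cfg a [segmentation_config()].
#' @param rest_window_seconds rest window length, seconds; by default the
#'   median duration of the detected gesture segments, so rest rows have
#'   the same sample support as gesture rows.
#' @return A `gesture_db`; also carries attributes `offsets` and `scale`
#'   (the preprocessing transform) for reuse by a streaming decoder.
#' @export
build_database <- function(session, cfg = segmentation_config(),
                           rest_window_seconds = NULL) {
  pre <- preprocess_session(session)
  gesture_blocks <- setdiff(names(pre), "rest")
  seg_list <- lapply(gesture_blocks, function(g) {
    label_segments(segment_recording(pre[[g]], cfg), pre[[g]]$timeline)
  })
  names(seg_list) <- gesture_blocks
  if (is.null(rest_window_seconds)) {
    durs <- unlist(lapply(seg_list, function(s) s$end_sample - s$start_sample))
    if (length(durs) == 0) stop("no gesture segments found in the session")
    rest_window_seconds <- stats::median(durs) / pre$rest$sampling_rate
  }
  dbs <- lapply(names(pre), function(g) {
    block <- pre[[g]]
    if (g == "rest") {
      # a rest block has no contraction to threshold (the signal is noise
      # around the offset level), so its repetitions are represented by
      # fixed-length windows tiled across the block
      segs <- rest_windows(block, seg_list[[1]][0, ],
                           nrow(block$timeline), rest_window_seconds)
    } else {
      segs <- seg_list[[g]]
      if (nrow(segs) == 0) {
        segs <- rest_windows(block, segs, nrow(block$timeline),
                             rest_window_seconds)
      }
    }
    extract_features(block, segs)
  })
  db <- combine_databases(dbs)
  attr(db, "offsets") <- attr(pre, "offsets")
  attr(db, "scale") <- attr(pre, "scale")
  db
}

#' Build a database from a mixed-sequence recording via its timeline
#'
#' A randomized gesture sequence activates different channels at different
#' times, so a single-channel threshold cannot recover every instance; as in
#' a video-guided session where the prescribed sequence is known, the
#' ground-truth timeline provides the held-posture windows directly.
#'
#' @param rec a mixed-sequence [fsr_recording()] with a timeline.
#' @param offsets,scale the preprocessing transform to apply; by default the
#'   recording is preprocessed against itself (offsets from the leading rest
#'   stretch before the first posture, scale from its own global maximum),
#'   as a stand-alone session would be.
#' @return A labelled `gesture_db`, one row per timeline interval.
#' @export
timeline_database <- function(rec, offsets = NULL, scale = NULL) {
  if (is.null(rec$timeline)) stop("recording has no timeline")
  if (is.null(offsets)) {
    lead <- max(rec$timeline$start_sample[1], 1L)
    offsets <- apply(rec$forces[interval_rows(0L, lead), , drop = FALSE],
                     2, min)
  }
  if (is.null(scale)) {
    scale <- max(abs(sweep(rec$forces, 2, offsets, `-`)))
    if (scale == 0) stop("degenerate recording: flat at rest level")
  }
  centred <- sweep(rec$forces, 2, offsets, `-`)
  pre <- fsr_recording(centred / scale, rec$sampling_rate, rec$timeline,
                       rec$subject_id)
  segs <- data.frame(start_sample = rec$timeline$start_sample,
                     end_sample = rec$timeline$end_sample,
                     channel = NA_integer_,
                     label = rec$timeline$label,
                     stringsAsFactors = FALSE)
  extract_features(pre, segs)
}
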