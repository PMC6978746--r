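#' Streaming decoder configuration
#'
#' Defaults mirror the embedded implementation: features are computed every
#' 100 ms and one classification byte is emitted at 10 Hz, so windows are
#' non-overlapping (`window_length * output_rate = 1`).
#'
#' @param window_length feature window, seconds.
#' @param output_rate decisions per second, Hz.
#' @param sampling_rate input sampling rate, Hz;
#'   `sampling_rate * window_length` must be a whole number of samples.
#' @return An object of class `stream_config`.
#' @export
stream_config <- function(window_length = 0.1, output_rate = 10,
                          sampling_rate = 1000) {
  if (abs(window_length * output_rate - 1) > 1e-9) {
    stop("window_length * output_rate must equal 1 (non-overlapping windows)")
  }
  ws <- sampling_rate * window_length
  if (abs(ws - round(ws)) > 1e-9) {
    stop("sampling_rate * window_length must be an integer sample count")
  }
  structure(
    list(window_length = window_length, output_rate = output_rate,
         sampling_rate = sampling_rate, window_samples = as.integer(round(ws))),
    class = "stream_config"
  )
}

#' Calibrate a streaming decoder from a protocol session
#'
#' Runs the batch pipeline (preprocess, segment, extract features) on a full
#' calibration session and trains the requested classifier, exactly as the
#' offline path would; the returned decoder bundles the trained model with
#' the session's preprocessing transform so that streamed windows are
#' normalized identically.
#'
#' @param session an `fsr_session` covering all eight gesture classes.
#' @param trainer a trainer function, e.g. `function(d) train_linear_svm(d)`.
#' @param cfg a [segmentation_config()].
#' @return An object of class `armsense_decoder`: `model`, `offsets`,
#'   `scale`.
#' @export
calibration_session <- function(session, trainer,
                                cfg = segmentation_config()) {
  db <- build_database(session, cfg)
  missing <- setdiff(gesture_labels(), unique(db$label))
  if (length(missing)) {
    stop("calibration session is missing gesture class(es): ",
         paste(missing, collapse = ", "))
  }
  structure(
    list(model = trainer(db), offsets = attr(db, "offsets"),
         scale = attr(db, "scale")),
    class = "armsense_decoder"
  )
}

#' Decode a sample stream into fixed-rate gesture decisions
#'
#' Consumes samples in acquisition order, and for every completed
#' non-overlapping window computes the per-channel mean and SD (on the
#' decoder's normalized scale), classifies, and emits one decision carrying
#' the gesture's one-byte code. A finite source of `d` seconds yields
#' exactly `floor(d * output_rate)` decisions; a trailing partial window is
#' dropped.
#'
#' @param source an [fsr_recording()] or a samples-by-3 force matrix (kg).
#' @param decoder an `armsense_decoder` from [calibration_session()], or a
#'   bare `armsense_model` (then `offsets`/`scale` must be given).
#' @param cfg a [stream_config()]; its sampling rate must match the source.
#' @param offsets,scale preprocessing transform when `decoder` is a bare
#'   model.
#' @return A data.frame with one row per decision: `window_index` (0-based),
#'   `label`, `byte_code`.
#' @export
stream_decode <- function(source, decoder, cfg = stream_config(),
                          offsets = NULL, scale = NULL) {
  if (inherits(source, "fsr_recording")) {
    if (abs(source$sampling_rate - cfg$sampling_rate) > 1e-9) {
      stop("stream_config sampling rate does not match the recording")
    }
    forces <- source$forces
  } else {
    forces <- as.matrix(source)
  }
  if (inherits(decoder, "armsense_decoder")) {
    model <- decoder$model
    offsets <- decoder$offsets
    scale <- decoder$scale
  } else {
    model <- decoder
    if (is.null(offsets) || is.null(scale)) {
      stop("a bare model needs explicit offsets and scale")
    }
  }
  x <- sweep(forces, 2, offsets, `-`) / scale
  ws <- cfg$window_samples
  n_win <- nrow(x) %/% ws
  if (n_win * ws < nrow(x)) {
    message("dropping trailing partial window of ",
            nrow(x) - n_win * ws, " samples")
  }
  if (n_win == 0) {
    return(data.frame(window_index = integer(0), label = character(0),
                      byte_code = integer(0), stringsAsFactors = FALSE))
  }
  feats <- t(vapply(seq_len(n_win), function(i) {
    win <- x[interval_rows((i - 1L) * ws, i * ws), , drop = FALSE]
    c(colMeans(win), apply(win, 2, stats::sd))
  }, numeric(6)))
  colnames(feats) <- c(paste0("fsr", 1:3, "_mean"), paste0("fsr", 1:3, "_sd"))
  labels <- predict(model, feats)
  data.frame(window_index = seq_len(n_win) - 1L,
             label = labels,
             byte_code = gesture_code(labels),
             stringsAsFactors = FALSE)
}

#' Write gesture decisions as a one-byte-per-decision stream
#'
#' @param decisions decision data.frame from [stream_decode()].
#' @param path file path or writable binary connection.
#' @return Invisibly, the raw vector written.
#' @export
write_decision_stream <- function(decisions, path) {
  bytes <- as.raw(decisions$byte_code)
  writeBin(bytes, path)
  invisible(bytes)
}

#' Read a one-byte-per-decision gesture stream
#'
#' Inverse of [write_decision_stream()].
#'
#' @param path file path or readable binary connection.
#' @param n maximum number of decisions to read.
#' @return A decision data.frame (`window_index`, `label`, `byte_code`).
#' @export
read_decision_stream <- function(path, n = 1e6) {
  bytes <- if (is.character(path)) {
    readBin(path, "raw", n = n)
  } else {
    readBin(path, "raw", n = n)
  }
  codes <- as.integer(bytes)
  data.frame(window_index = seq_along(codes) - 1L,
             label = gesture_from_code(codes),
             byte_code = codes,
             stringsAsFactors = FALSE)
}

#' Majority decision per ground-truth plateau
#'
#' Tallies streamed decisions against a recording's ground-truth timeline:
#' for each held plateau, the majority label over the decision windows whose
#' centre falls inside the plateau. This is the per-gesture-attempt view of
#' streaming accuracy (the per-window view is just
#' `mean(decisions$label == truth)` over labelled windows).
#'
#' @param decisions decision data.frame from [stream_decode()].
#' @param timeline ground-truth timeline of the streamed recording.
#' @param cfg the [stream_config()] used to decode.
#' @return data.frame with one row per plateau: `label`, `decoded`,
#'   `correct`.
#' @export
majority_per_plateau <- function(decisions, timeline, cfg = stream_config()) {
  ws <- cfg$window_samples
  centre <- decisions$window_index * ws + ws / 2
  out <- lapply(seq_len(nrow(timeline)), function(i) {
    inside <- centre >= timeline$start_sample[i] &
      centre < timeline$end_sample[i]
    if (!any(inside)) return(NULL)
    tab <- table(decisions$label[inside])
    decoded <- names(tab)[which.max(tab)]
    data.frame(label = timeline$label[i], decoded = decoded,
               correct = decoded == timeline$label[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}
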