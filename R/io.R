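recording_header <- c("time_s", "fsr1_kg", "fsr2_kg", "fsr3_kg")

#' Write / read a recording as CSV (+ optional timeline JSON sidecar)
#'
#' The CSV has header `time_s,fsr1_kg,fsr2_kg,fsr3_kg`, one row per sample;
#' the optional sidecar is a JSON list of
#' `{start_sample, end_sample, label}` ground-truth intervals. Numeric
#' fields survive the round trip to full double precision.
#'
#' @param rec an [fsr_recording()].
#' @param path CSV output path.
#' @param timeline_path optional JSON sidecar path.
#' @return Invisibly, `path`.
#' @export
write_recording <- function(rec, path, timeline_path = NULL) {
  n <- nrow(rec$forces)
  num <- cbind((seq_len(n) - 1) / rec$sampling_rate, rec$forces)
  txt <- matrix(sprintf("%.17g", num), nrow = n)  # exact double round-trip
  writeLines(c(paste(recording_header, collapse = ","),
               apply(txt, 1, paste, collapse = ",")), path)
  if (!is.null(timeline_path)) {
    if (is.null(rec$timeline)) stop("recording has no timeline to write")
    jsonlite::write_json(rec$timeline, timeline_path, auto_unbox = FALSE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_recording
#' @param sampling_rate sampling rate of the stored recording; if `NULL` it
#'   is inferred from the `time_s` column.
#' @param subject_id subject id to attach.
#' @return `read_recording()` returns the [fsr_recording()].
#' @export
read_recording <- function(path, timeline_path = NULL, sampling_rate = NULL,
                           subject_id = "anonymous") {
  header <- strsplit(readLines(path, n = 1), ",", fixed = TRUE)[[1]]
  if (!identical(trimws(header), recording_header)) {
    stop("malformed recording header at ", path, " line 1: expected '",
         paste(recording_header, collapse = ","), "', got '",
         paste(header, collapse = ","), "'")
  }
  df <- utils::read.csv(path)
  if (ncol(df) != 4) {
    stop("recording must have 4 columns (time + 3 channels), found ",
         ncol(df))
  }
  if (is.null(sampling_rate)) {
    dt <- diff(df$time_s)
    if (length(dt) == 0) stop("recording has fewer than 2 samples")
    sampling_rate <- 1 / stats::median(dt)
  }
  timeline <- NULL
  if (!is.null(timeline_path)) {
    timeline <- as.data.frame(jsonlite::read_json(timeline_path,
                                                  simplifyVector = TRUE))
    timeline$start_sample <- as.integer(timeline$start_sample)
    timeline$end_sample <- as.integer(timeline$end_sample)
  }
  fsr_recording(as.matrix(df[, 2:4]), sampling_rate, timeline, subject_id)
}

#' Write / read a gesture feature database as CSV
#'
#' Columns are the active sensors' mean features, then their SD features,
#' then `label` and `subject_id`. The sensor mask is recovered from the
#' header on read.
#'
#' @param db a `gesture_db`.
#' @param path CSV path.
#' @return Invisibly `path`; `read_database()` returns the `gesture_db`.
#' @export
write_database <- function(db, path) {
  out <- as.data.frame(db)
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_database
#' @export
read_database <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("label", "subject_id") %in% names(df))) {
    stop("database must have 'label' and 'subject_id' columns")
  }
  mean_cols <- grep("^fsr[1-3]_mean$", names(df), value = TRUE)
  mask <- sort(as.integer(sub("^fsr([1-3])_mean$", "\\1", mean_cols)))
  expected <- c(paste0("fsr", mask, "_mean"), paste0("fsr", mask, "_sd"))
  if (!all(expected %in% names(df))) {
    stop("database feature columns are incomplete for sensors ",
         paste(mask, collapse = ","))
  }
  gesture_db(df[, c(expected, "label", "subject_id")], sensor_mask = mask)
}

#' Serialize / deserialize a trained model as JSON
#'
#' All classifier kinds round-trip losslessly: the deserialized model
#' classifies identically to the in-memory one.
#'
#' @param model an `armsense_model`.
#' @param path JSON path.
#' @return Invisibly `path`; `read_model()` returns the model.
#' @export
write_model <- function(model, path) {
  payload <- list(kind = model$kind, classes = model$classes,
                  features = model$features)
  payload <- switch(
    model$kind,
    lda = c(payload, list(means = model$means, cov_inv = model$cov_inv,
                          pooled_cov = model$pooled_cov,
                          log_priors = model$log_priors)),
    qda = c(payload, list(
      log_priors = model$log_priors,
      class_fits = lapply(model$class_fits, function(f) {
        list(mu = f$mu, cov_inv = f$cov_inv, log_det = f$log_det)
      }))),
    linear_svm = c(payload, list(
      C = model$C,
      pairs = list(
        class_pos = vapply(model$pairs, `[[`, character(1), "class_pos"),
        class_neg = vapply(model$pairs, `[[`, character(1), "class_neg"),
        b = vapply(model$pairs, `[[`, numeric(1), "b"),
        objective = vapply(model$pairs, `[[`, numeric(1), "objective"),
        w = t(vapply(model$pairs, `[[`,
                     numeric(length(model$features)), "w"))))),
    knn = c(payload, list(k = model$k, train_x = model$train_x,
                          train_y = model$train_y)),
    stop("unsupported model kind: ", model$kind)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  feats <- p$features
  reshape <- function(m) {
    m <- as.matrix(m)
    colnames(m) <- feats
    m
  }
  switch(
    p$kind,
    lda = structure(
      list(kind = "lda", classes = p$classes, features = feats,
           means = reshape(p$means), cov_inv = as.matrix(p$cov_inv),
           pooled_cov = as.matrix(p$pooled_cov),
           log_priors = as.numeric(p$log_priors)),
      class = c("armsense_lda", "armsense_model")),
    qda = structure(
      list(kind = "qda", classes = p$classes, features = feats,
           class_fits = lapply(p$class_fits, function(f) {
             list(mu = as.numeric(f$mu), cov_inv = as.matrix(f$cov_inv),
                  log_det = as.numeric(f$log_det))
           }),
           log_priors = as.numeric(p$log_priors)),
      class = c("armsense_qda", "armsense_model")),
    linear_svm = structure(
      list(kind = "linear_svm", classes = p$classes, features = feats,
           C = p$C,
           pairs = {
             W <- matrix(as.numeric(p$pairs$w), ncol = length(feats))
             lapply(seq_along(p$pairs$class_pos), function(i) {
               list(class_pos = p$pairs$class_pos[i],
                    class_neg = p$pairs$class_neg[i],
                    w = W[i, ], b = p$pairs$b[i],
                    objective = p$pairs$objective[i])
             })
           }),
      class = c("armsense_svm", "armsense_model")),
    knn = structure(
      list(kind = "knn", classes = p$classes, features = feats,
           k = as.integer(p$k), train_x = reshape(p$train_x),
           train_y = p$train_y),
      class = c("armsense_knn", "armsense_model")),
    stop("unsupported model kind in ", path)
  )
}
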