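# Compressed-timescale fixtures for fast unit tests: same burst structure
# as the defaults, 200 Hz sampling and sub-second bursts. Statistical
# behaviour (separation in units of noise SD, threshold geometry) matches
# the full-scale defaults.

tiny_acq <- function() acquisition_config(sampling_rate = 200)

tiny_profile <- function(noise_sd = 0.02) {
  p <- default_activation_profile(noise_sd = noise_sd)
  p$rise_time <- 0.05
  p$hold_time <- 0.4
  p$fall_time <- 0.05
  p$rest_gap <- 0.5
  p
}

tiny_seg_cfg <- function() {
  segmentation_config(threshold_fraction = 0.4,
                      min_segment_duration = 0.1, merge_gap = 0.05)
}

tiny_session <- function(seed = 0, repetitions = 3, noise_sd = 0.02,
                         subject_id = "T1", profile = NULL) {
  if (is.null(profile)) profile <- tiny_profile(noise_sd)
  generate_session(profile, tiny_acq(), repetitions = repetitions,
                   seed = seed, subject_id = subject_id)
}

tiny_database <- function(seed = 0, repetitions = 3, noise_sd = 0.02,
                          subject_id = "T1", profile = NULL) {
  build_database(tiny_session(seed, repetitions, noise_sd, subject_id,
                              profile),
                 tiny_seg_cfg())
}

# A full-scale default-conditions database (1 kHz, 10 reps, 8 gestures),
# built once per test run and reused by the feature and acceptance tests.
default_db_cache <- new.env(parent = emptyenv())

cached_default_database <- function(subject = 1, seed_base = 0) {
  cached_default_cohort(seed_base)[[subject]]
}

# The full default-conditions cohort (10 subjects, built once per run).
cached_default_cohort <- function(seed_base = 0) {
  key <- paste0("cohort_", seed_base)
  if (is.null(default_db_cache[[key]])) {
    cfg <- cohort_config(seed = seed_base, subjects = 10)
    default_db_cache[[key]] <- cohort_databases(cfg)
  }
  default_db_cache[[key]]
}

# Per-subject 10-fold CV results on the default cohort, cached per trainer.
cached_cohort_evals <- function(trainer_name, seed_base = 0) {
  key <- paste0("evals_", trainer_name, "_", seed_base)
  if (is.null(default_db_cache[[key]])) {
    trainer <- switch(trainer_name,
                      linear_svm = function(d) train_linear_svm(d),
                      lda = train_lda)
    default_db_cache[[key]] <- lapply(cached_default_cohort(seed_base),
                                      cross_validate, trainer = trainer,
                                      scheme = cv_kfold(10, seed = 42))
  }
  default_db_cache[[key]]
}

# Deterministic toy feature databases for classifier unit tests.
toy_db <- function(n_per_class = 10, classes = c("a", "b"), d = 2,
                   sep = 3, noise = 1, seed = 1) {
  set.seed(seed)
  centers <- matrix(seq(0, sep * (length(classes) - 1), by = sep),
                    nrow = length(classes), ncol = d)
  rows <- do.call(rbind, lapply(seq_along(classes), function(k) {
    matrix(rnorm(n_per_class * d, sd = noise), n_per_class, d) +
      matrix(centers[k, ], n_per_class, d, byrow = TRUE)
  }))
  df <- as.data.frame(rows)
  names(df) <- paste0("f", seq_len(d))
  df$label <- rep(classes, each = n_per_class)
  df$subject_id <- "toy"
  gesture_db(df, sensor_mask = integer(0))
}
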