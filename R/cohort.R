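#' Cohort experiment configuration
#'
#' One object from which a whole synthetic-cohort run is reproducible: the
#' root seed drives named sub-seeds for subject variability, signal
#' generation, fold shuffling and the second-session re-donning draw.
#'
#' @param seed root integer seed.
#' @param subjects number of synthetic subjects.
#' @param repetitions repetitions per gesture class.
#' @param classifiers character subset of
#'   `c("linear_svm", "lda", "qda", "knn")` to evaluate per subject.
#' @param profile the common [activation_profile()] the cohort perturbs.
#' @param acq an [acquisition_config()].
#' @param seg a [segmentation_config()].
#' @param fold_seed seed of the stratified k-fold shuffle.
#' @param cv_k number of cross-validation folds (default 10).
#' @param run_loo also run leave-one-out cross-validation?
#' @param run_ablation run the sensor-subset ablation (linear SVM + LDA)?
#' @param run_reproducibility run the two-session reproducibility test?
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(seed = 0, subjects = 10, repetitions = 10,
                          classifiers = c("linear_svm", "lda", "qda", "knn"),
                          profile = default_activation_profile(),
                          acq = acquisition_config(),
                          seg = segmentation_config(),
                          fold_seed = 42, cv_k = 10, run_loo = TRUE,
                          run_ablation = TRUE, run_reproducibility = TRUE) {
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  structure(
    list(seed = as.integer(seed), subjects = as.integer(subjects),
         repetitions = as.integer(repetitions), classifiers = classifiers,
         profile = profile, acq = acq, seg = seg,
         fold_seed = as.integer(fold_seed), cv_k = as.integer(cv_k),
         run_loo = run_loo,
         run_ablation = run_ablation,
         run_reproducibility = run_reproducibility),
    class = "cohort_config"
  )
}

cohort_trainer <- function(name) {
  switch(name,
         linear_svm = function(d) train_linear_svm(d),
         lda = train_lda,
         qda = train_qda,
         knn = function(d) train_knn(d, k = 1),
         stop("unknown classifier: ", name))
}

#' Generate the gesture databases of a synthetic cohort
#'
#' Each subject is the common activation profile perturbed by a fixed
#' per-subject gain/offset draw; each runs the full calibration protocol and
#' the batch pipeline down to an 80-row feature database.
#'
#' @param cfg a [cohort_config()].
#' @return List of per-subject `gesture_db` objects, named `S1..Sn`.
#' @export
cohort_databases <- function(cfg = cohort_config()) {
  lapply(seq_len(cfg$subjects), function(i) {
    sp <- draw_subject_profile(cfg$profile, seed = derive_seed(cfg$seed,
                                                               100L + i))
    session <- generate_session(sp, cfg$acq, cfg$repetitions,
                                seed = derive_seed(cfg$seed, 200L + i),
                                subject_id = paste0("S", i))
    build_database(session, cfg$seg)
  })
}

#' Run the full synthetic-cohort experiment
#'
#' Generates the cohort and reproduces the study's result structure on it:
#' per-subject accuracies for every requested classifier under stratified
#' 10-fold (and optionally leave-one-out) cross-validation, per-class
#' accuracy tables and pooled confusion matrices for linear SVM and LDA,
#' the sensor-subset ablation, the combined-database (cross-subject)
#' evaluation, and the two-session reproducibility test in which each
#' subject's second, randomized session is recorded after re-donning the
#' armband (a fresh gain/offset draw) and classified by the first session's
#' model without retraining.
#'
#' @param cfg a [cohort_config()].
#' @param out_dir optional directory; when given, every table is also
#'   written as CSV.
#' @return A list of result tables; see the element names.
#' @export
run_cohort_experiment <- function(cfg = cohort_config(), out_dir = NULL) {
  dbs <- cohort_databases(cfg)
  subj <- vapply(dbs, function(d) d$subject_id[1], character(1))
  kfold <- cv_kfold(cfg$cv_k, seed = cfg$fold_seed)
  report <- list(config = cfg)

  # per-subject accuracy table (10-fold and LOO), one row per subject
  evals <- list()
  acc <- data.frame(subject = subj, stringsAsFactors = FALSE)
  for (cl in cfg$classifiers) {
    trainer <- cohort_trainer(cl)
    ev10 <- lapply(dbs, cross_validate, trainer = trainer, scheme = kfold)
    evals[[cl]] <- ev10
    acc[[paste0(cl, "_cv10")]] <- vapply(ev10, `[[`, numeric(1), "accuracy")
    if (cfg$run_loo) {
      acc[[paste0(cl, "_loo")]] <- vapply(
        dbs, function(d) cross_validate(d, trainer, cv_loo())$accuracy,
        numeric(1))
    }
  }
  report$per_subject_accuracy <- acc

  # per-class accuracies and pooled confusion for the two headline models
  for (cl in intersect(c("linear_svm", "lda"), cfg$classifiers)) {
    per_class <- vapply(evals[[cl]], `[[`, numeric(8), "per_class_accuracy")
    colnames(per_class) <- subj
    report[[paste0("per_class_", cl)]] <-
      data.frame(gesture = rownames(per_class), per_class,
                 row.names = NULL, check.names = FALSE)
    cms <- lapply(evals[[cl]], `[[`, "confusion")
    report[[paste0("confusion_", cl)]] <- Reduce(`+`, cms)
  }

  if (cfg$run_ablation) {
    trainers <- lapply(intersect(c("linear_svm", "lda"), cfg$classifiers),
                       cohort_trainer)
    names(trainers) <- intersect(c("linear_svm", "lda"), cfg$classifiers)
    report$ablation <- ablation_study(dbs, trainers, kfold)
  }

  # combined database: cross-subject classification without calibration
  combined <- combine_databases(dbs)
  comb <- data.frame(trainer = cfg$classifiers, accuracy = NA_real_,
                     stringsAsFactors = FALSE)
  for (i in seq_along(cfg$classifiers)) {
    comb$accuracy[i] <- cross_validate(combined,
                                       cohort_trainer(cfg$classifiers[i]),
                                       kfold)$accuracy
  }
  report$combined_accuracy <- comb

  if (cfg$run_reproducibility) {
    rep_cls <- intersect(c("linear_svm", "lda"), cfg$classifiers)
    rep_tab <- data.frame(subject = subj, stringsAsFactors = FALSE)
    second <- lapply(seq_len(cfg$subjects), function(i) {
      sp <- draw_subject_profile(cfg$profile,
                                 seed = derive_seed(cfg$seed, 100L + i))
      # re-donning: a fresh variability draw on top of the subject's own
      sp2 <- draw_subject_profile(sp, seed = derive_seed(cfg$seed, 300L + i))
      sp2$subject_scale <- sp$subject_scale * sp2$subject_scale
      sp2$subject_offset <- sp$subject_offset + sp2$subject_offset
      rec <- generate_random_sequence(sp2, cfg$acq, n_gestures = 50,
                                      seed = derive_seed(cfg$seed, 400L + i),
                                      subject_id = paste0("S", i))
      timeline_database(rec)
    })
    for (cl in rep_cls) {
      trainer <- cohort_trainer(cl)
      rep_tab[[paste0(cl, "_second_session")]] <-
        vapply(seq_along(dbs), function(i) {
          reproducibility_eval(trainer(dbs[[i]]), second[[i]])$accuracy
        }, numeric(1))
    }
    report$reproducibility <- rep_tab
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in setdiff(names(report), "config")) {
      obj <- report[[nm]]
      if (is.matrix(obj)) obj <- as.data.frame.matrix(obj)
      utils::write.csv(obj, file.path(out_dir, paste0(nm, ".csv")),
                       row.names = is.matrix(report[[nm]]))
    }
  }
  report
}
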