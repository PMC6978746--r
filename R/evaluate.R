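#' Cross-validation schemes
#'
#' `cv_kfold()` describes stratified k-fold cross-validation: within every
#' class, rows are shuffled with the given seed and dealt cyclically into
#' `k` folds, so fold class balance mirrors the database. If some class has
#' fewer rows than `k`, folding falls back to unstratified with a warning.
#' `cv_loo()` is leave-one-out: n folds of size one, deterministic given the
#' database.
#'
#' @param k number of folds.
#' @param seed integer seed for the fold shuffle.
#' @name cv_scheme
#' @return A cross-validation scheme object for [cross_validate()].
#' @export
cv_kfold <- function(k = 10, seed = 42) {
  if (k < 2) stop("k must be >= 2")
  structure(list(kind = "kfold", k = as.integer(k), seed = as.integer(seed)),
            class = "cv_scheme")
}

#' @rdname cv_scheme
#' @export
cv_loo <- function() {
  structure(list(kind = "loo"), class = "cv_scheme")
}

# Fold assignment vector (1..k) for the rows of db under a scheme.
assign_folds <- function(db, scheme) {
  n <- nrow(db)
  if (scheme$kind == "loo") return(seq_len(n))
  k <- scheme$k
  if (k > n) stop("k = ", k, " folds exceed the ", n, " database rows")
  folds <- integer(n)
  tab <- table(db$label)
  with_seed(scheme$seed, {
    if (any(tab < k)) {
      warning("some class has fewer than ", k,
              " rows; falling back to unstratified folds")
      folds[sample.int(n)] <- rep_len(seq_len(k), n)
    } else {
      for (cl in names(tab)) {
        idx <- which(db$label == cl)
        folds[idx[sample.int(length(idx))]] <-
          rep_len(seq_len(k), length(idx))
      }
    }
  })
  folds
}

# Confusion matrix with rows = true classes, columns = predicted.
confusion_matrix <- function(truth, pred, classes) {
  table(factor(truth, levels = classes), factor(pred, levels = classes),
        dnn = c("true", "predicted"))
}

eval_result <- function(truth, pred, classes, fold_accuracies = NULL) {
  cm <- confusion_matrix(truth, pred, classes)
  per_class <- 100 * diag(cm) / pmax(rowSums(cm), 1)
  per_class[rowSums(cm) == 0] <- NA_real_
  pooled <- 100 * sum(diag(cm)) / length(truth)
  structure(
    list(accuracy = if (is.null(fold_accuracies)) pooled
         else mean(fold_accuracies),
         pooled_accuracy = pooled,
         fold_accuracies = fold_accuracies,
         per_class_accuracy = per_class,
         confusion = cm),
    class = "armsense_eval"
  )
}

#' @export
print.armsense_eval <- function(x, ...) {
  cat(sprintf("<armsense_eval> accuracy %.2f%% (pooled %.2f%%)\n",
              x$accuracy, x$pooled_accuracy))
  cat("per-class accuracy (%):\n")
  print(round(x$per_class_accuracy, 2))
  invisible(x)
}

#' Cross-validate a classifier on a gesture database
#'
#' Trains on all but one fold and tests on the held-out fold, for every
#' fold. The headline accuracy is the mean of the per-fold accuracies (the
#' usual convention for this protocol); the pooled accuracy over all
#' held-out predictions is also reported, and the confusion matrix is
#' accumulated across folds (rows = true gestures, columns = predicted).
#'
#' @param db a `gesture_db`.
#' @param trainer a function `db -> TrainedModel`, e.g. [train_lda()] or
#'   `function(d) train_linear_svm(d, C = 1)`.
#' @param scheme a [cv_kfold()] or [cv_loo()] scheme.
#' @return An `armsense_eval` result.
#' @export
cross_validate <- function(db, trainer, scheme = cv_kfold()) {
  folds <- assign_folds(db, scheme)
  classes <- order_classes(db$label)
  truth <- character(0); pred <- character(0); fold_acc <- numeric(0)
  for (f in sort(unique(folds))) {
    test <- folds == f
    model <- trainer(db[!test, , drop = FALSE])
    p <- predict(model, db[test, , drop = FALSE])
    truth <- c(truth, db$label[test])
    pred <- c(pred, p)
    fold_acc <- c(fold_acc, 100 * mean(p == db$label[test]))
  }
  eval_result(truth, pred, classes, fold_accuracies = fold_acc)
}

#' Sensor-subset ablation study
#'
#' Evaluates every non-empty sensor subset (three singles, three pairs, the
#' full triple) for every requested classifier on every subject's database
#' via stratified 10-fold cross-validation, and summarizes per-subset
#' mean and SD accuracy across subjects.
#'
#' @param dbs list of per-subject `gesture_db` objects.
#' @param trainers named list of trainer functions.
#' @param scheme the cross-validation scheme applied per subject.
#' @return A data.frame with one row per (sensor subset, trainer):
#'   `sensors`, `trainer`, `mean_accuracy`, `sd_accuracy`, plus one
#'   `acc_<subject>` column per subject.
#' @export
ablation_study <- function(dbs, trainers, scheme = cv_kfold()) {
  masks <- list(1L, 2L, 3L, c(1L, 2L), c(1L, 3L), c(2L, 3L), 1:3)
  subj <- vapply(dbs, function(d) d$subject_id[1], character(1))
  rows <- list()
  for (mask in masks) {
    for (tn in names(trainers)) {
      accs <- vapply(dbs, function(d) {
        cross_validate(project_sensors(d, mask), trainers[[tn]],
                       scheme)$accuracy
      }, numeric(1))
      row <- data.frame(sensors = paste(paste0("fsr", mask), collapse = "+"),
                        trainer = tn,
                        mean_accuracy = mean(accs),
                        sd_accuracy = stats::sd(accs),
                        stringsAsFactors = FALSE)
      row[paste0("acc_", subj)] <- as.list(accs)
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Evaluate a previously trained model on a second session
#'
#' Straight held-out classification with no retraining: the model from a
#' first (calibration) session classifies the feature rows of a later
#' session by the same subject. Accuracy drops relative to within-session
#' cross-validation when the armband has been re-donned, which is why a
#' fresh calibration before each use is advisable.
#'
#' @param model a `TrainedModel` from the first session.
#' @param second_session a labelled `gesture_db` from the later session.
#' @return An `armsense_eval` result over the union of model and session
#'   classes.
#' @export
reproducibility_eval <- function(model, second_session) {
  pred <- predict(model, second_session)
  classes <- union(order_classes(second_session$label), model$classes)
  eval_result(second_session$label, pred, classes)
}
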