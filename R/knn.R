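#' Train a k-nearest-neighbour classifier
#'
#' Instance-based classifier: stores the training rows and predicts by
#' majority vote among the `k` nearest neighbours under the Euclidean
#' metric. Vote ties are broken by the lowest gesture code; distance ties by
#' training-row order. The default `k = 1` is the usual instance-learner
#' default for this kind of small, well-separated database.
#'
#' @param db a `gesture_db`.
#' @param k neighbourhood size, `1 <= k <= nrow(db)`.
#' @return A `TrainedModel` of class `c("armsense_knn", "armsense_model")`.
#' @export
train_knn <- function(db, k = 1L) {
  X <- db_features(db); y <- db$label
  check_trainable(X, y, min_per_class = 1)
  k <- as.integer(k)
  if (k < 1 || k > nrow(X)) stop("k must lie in 1..nrow(db)")
  structure(
    list(kind = "knn", classes = order_classes(y), features = colnames(X),
         k = k, train_x = X, train_y = y),
    class = c("armsense_knn", "armsense_model")
  )
}

#' @export
predict.armsense_knn <- function(object, newdata, ...) {
  X <- as_feature_matrix(newdata, object$features)
  Tr <- object$train_x
  # squared Euclidean distances, query x training
  d2 <- outer(rowSums(X^2), rowSums(Tr^2), `+`) - 2 * tcrossprod(X, Tr)
  vapply(seq_len(nrow(X)), function(i) {
    nn <- order(d2[i, ])[seq_len(object$k)]
    votes <- table(factor(object$train_y[nn], levels = object$classes))
    object$classes[which.max(votes)]  # first max: lowest-code tie-break
  }, character(1))
}
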