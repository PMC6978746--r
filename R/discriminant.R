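# Classes ordered by protocol code when the labels are gestures, otherwise
# alphabetically; the first class wins ties everywhere downstream.
order_classes <- function(labels) {
  u <- unique(labels)
  if (all(u %in% gesture_labels())) {
    intersect(gesture_labels(), u)
  } else {
    sort(u)
  }
}

# Ridge-regularize a covariance matrix by eps * tr(S)/d on the diagonal when
# it is ill-conditioned (or whenever force = TRUE adds the minimal ridge).
regularize_cov <- function(S, eps = 1e-8) {
  d <- ncol(S)
  rc <- tryCatch(rcond(S), error = function(e) 0)
  if (!is.finite(rc) || rc < 1e-10) {
    tr <- sum(diag(S))
    if (tr <= 0) tr <- d  # flat features: fall back to the identity scale
    S <- S + diag(eps * tr / d, d)
    # keep inflating until numerically invertible
    while (tryCatch(rcond(S), error = function(e) 0) < 1e-10) {
      S <- S + diag(eps * tr / d, d)
      eps <- eps * 10
    }
  }
  S
}

check_trainable <- function(X, y, min_per_class = 2) {
  if (!all(is.finite(X))) stop("non-finite feature values in training data")
  tab <- table(y)
  if (length(tab) < 2) stop("training needs at least 2 classes")
  if (any(tab < min_per_class)) {
    stop("every class needs at least ", min_per_class, " training rows")
  }
}

#' Train a linear discriminant classifier
#'
#' Closed-form Gaussian discriminant with a shared covariance: per-class
#' means, pooled within-class covariance `S` (divisor `n - K`), priors from
#' class frequencies. The discriminant score of class `k` is
#' `x' S^-1 mu_k - mu_k' S^-1 mu_k / 2 + log pi_k`; prediction is the
#' argmax, ties going to the lowest gesture code. The pooled covariance is
#' ridge-regularized on the diagonal when ill-conditioned.
#'
#' @param db a `gesture_db`.
#' @return A `TrainedModel` of class `c("armsense_lda", "armsense_model")`.
#' @export
train_lda <- function(db) {
  X <- db_features(db); y <- db$label
  check_trainable(X, y)
  classes <- order_classes(y)
  K <- length(classes); d <- ncol(X); n <- nrow(X)
  mu <- do.call(rbind, lapply(classes, function(k) {
    colMeans(X[y == k, , drop = FALSE])
  }))
  rownames(mu) <- classes
  Sw <- matrix(0, d, d)
  for (k in classes) {
    Xk <- X[y == k, , drop = FALSE]
    Sw <- Sw + crossprod(sweep(Xk, 2, colMeans(Xk)))
  }
  S <- regularize_cov(Sw / (n - K))
  Sinv <- solve(S)
  priors <- as.numeric(table(factor(y, levels = classes))) / n
  structure(
    list(kind = "lda", classes = classes, features = colnames(X),
         means = mu, cov_inv = Sinv, pooled_cov = S, log_priors = log(priors)),
    class = c("armsense_lda", "armsense_model")
  )
}

#' Train a quadratic discriminant classifier
#'
#' Like [train_lda()] but with a per-class covariance, giving the quadratic
#' score `-log det S_k / 2 - (x - mu_k)' S_k^-1 (x - mu_k) / 2 + log pi_k`.
#' Each class covariance is ridge-regularized when ill-conditioned.
#'
#' @param db a `gesture_db`.
#' @return A `TrainedModel` of class `c("armsense_qda", "armsense_model")`.
#' @export
train_qda <- function(db) {
  X <- db_features(db); y <- db$label
  check_trainable(X, y)
  classes <- order_classes(y)
  d <- ncol(X); n <- nrow(X)
  fit <- lapply(classes, function(k) {
    Xk <- X[y == k, , drop = FALSE]
    mu <- colMeans(Xk)
    S <- regularize_cov(crossprod(sweep(Xk, 2, mu)) / (nrow(Xk) - 1))
    list(mu = mu, cov_inv = solve(S), log_det = determinant(S)$modulus[1])
  })
  priors <- as.numeric(table(factor(y, levels = classes))) / n
  structure(
    list(kind = "qda", classes = classes, features = colnames(X),
         class_fits = stats::setNames(fit, classes),
         log_priors = log(priors)),
    class = c("armsense_qda", "armsense_model")
  )
}

#' @export
predict.armsense_lda <- function(object, newdata, ...) {
  X <- as_feature_matrix(newdata, object$features)
  scores <- X %*% object$cov_inv %*% t(object$means)
  scores <- sweep(scores, 2,
                  0.5 * rowSums((object$means %*% object$cov_inv) *
                                  object$means) - object$log_priors, `-`)
  object$classes[max.col(scores, ties.method = "first")]
}

#' @export
predict.armsense_qda <- function(object, newdata, ...) {
  X <- as_feature_matrix(newdata, object$features)
  scores <- vapply(seq_along(object$classes), function(k) {
    f <- object$class_fits[[k]]
    dx <- sweep(X, 2, f$mu)
    -0.5 * f$log_det - 0.5 * rowSums((dx %*% f$cov_inv) * dx) +
      object$log_priors[k]
  }, numeric(nrow(X)))
  scores <- matrix(scores, nrow = nrow(X))
  object$classes[max.col(scores, ties.method = "first")]
}

# Accept a gesture_db, data.frame or matrix; reorder columns to the model's
# feature order.
as_feature_matrix <- function(newdata, features) {
  X <- if (inherits(newdata, "gesture_db") || is.data.frame(newdata)) {
    nd <- newdata
    missing <- setdiff(features, colnames(nd))
    if (length(missing)) {
      stop("newdata lacks feature column(s): ", paste(missing, collapse = ", "))
    }
    as.matrix(nd[, features, drop = FALSE])
  } else {
    X <- as.matrix(newdata)
    if (ncol(X) != length(features)) {
      stop("newdata must have ", length(features), " feature columns")
    }
    colnames(X) <- features
    X
  }
  storage.mode(X) <- "double"
  X
}
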