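# Sequential minimal optimization for the soft-margin linear SVM dual:
#   min_a  a' Q a / 2 - e' a   s.t.  y' a = 0,  0 <= a <= C,
# with Q = (y y') * (X X'). Working pairs are chosen by the maximal-violating
# -pair rule; iteration stops when the KKT violation gap falls below `eps`.
# Returns the primal weight vector, bias, dual coefficients and objective.
smo_linear_svm <- function(X, y, C = 1, eps = 1e-6, max_iter = 100000L) {
  n <- nrow(X)
  K <- tcrossprod(X)
  alpha <- numeric(n)
  grad <- rep(-1, n)  # gradient of the dual objective at alpha = 0
  iter <- 0L
  repeat {
    vals <- -y * grad
    up <- (y > 0 & alpha < C) | (y < 0 & alpha > 0)
    low <- (y > 0 & alpha > 0) | (y < 0 & alpha < C)
    if (!any(up) || !any(low)) break
    i <- which(up)[which.max(vals[up])]
    j <- which(low)[which.min(vals[low])]
    if (vals[i] - vals[j] < eps || iter >= max_iter) break
    quad <- K[i, i] + K[j, j] - 2 * K[i, j]
    if (quad <= 0) quad <- 1e-12
    ai <- alpha[i]; aj <- alpha[j]
    if (y[i] != y[j]) {
      delta <- (-grad[i] - grad[j]) / quad
      diffv <- ai - aj
      ai <- ai + delta; aj <- aj + delta
      if (diffv > 0) {
        if (aj < 0) { aj <- 0; ai <- diffv }
      } else {
        if (ai < 0) { ai <- 0; aj <- -diffv }
      }
      if (diffv > 0) {
        if (ai > C) { ai <- C; aj <- C - diffv }
      } else {
        if (aj > C) { aj <- C; ai <- C + diffv }
      }
    } else {
      delta <- (grad[i] - grad[j]) / quad
      sumv <- ai + aj
      ai <- ai - delta; aj <- aj + delta
      if (sumv > C) {
        if (ai > C) { ai <- C; aj <- sumv - C }
      } else {
        if (aj < 0) { aj <- 0; ai <- sumv }
      }
      if (sumv > C) {
        if (aj > C) { aj <- C; ai <- sumv - C }
      } else {
        if (ai < 0) { ai <- 0; aj <- sumv }
      }
    }
    dai <- ai - alpha[i]; daj <- aj - alpha[j]
    alpha[i] <- ai; alpha[j] <- aj
    grad <- grad + (y * y[i] * K[, i]) * dai + (y * y[j] * K[, j]) * daj
    iter <- iter + 1L
  }
  w <- drop(crossprod(X, alpha * y))
  vals <- y - drop(X %*% w)  # = y_i - w.x_i; equals b on free support vectors
  free <- alpha > 1e-8 & alpha < C - 1e-8
  b <- if (any(free)) {
    mean(vals[free])
  } else {
    up <- (y > 0 & alpha < C) | (y < 0 & alpha > 0)
    low <- (y > 0 & alpha > 0) | (y < 0 & alpha < C)
    (max(vals[up]) + min(vals[low])) / 2
  }
  margin <- y * (drop(X %*% w) + b)
  objective <- 0.5 * sum(w^2) + C * sum(pmax(0, 1 - margin))
  list(w = w, b = b, alpha = alpha, objective = objective, iterations = iter)
}

#' Train a multiclass linear SVM (one-vs-one)
#'
#' Fits a soft-margin linear SVM hyperplane for every unordered pair of
#' classes via sequential minimal optimization of the dual, then predicts by
#' majority vote over the pairwise decisions; vote ties are broken by the
#' summed signed decision values. The default penalty `C = 1` matches the
#' usual multiclass SMO toolchain default.
#'
#' @param db a `gesture_db`.
#' @param C soft-margin penalty, > 0.
#' @param eps KKT stopping tolerance of the dual solver.
#' @return A `TrainedModel` of class `c("armsense_svm", "armsense_model")`;
#'   `$pairs` holds one `(class_pos, class_neg, w, b, objective)` entry per
#'   class pair.
#' @export
train_linear_svm <- function(db, C = 1, eps = 1e-6) {
  X <- db_features(db); y <- db$label
  check_trainable(X, y, min_per_class = 1)
  if (C <= 0) stop("C must be > 0")
  classes <- order_classes(y)
  pairs <- list()
  for (a in seq_len(length(classes) - 1)) {
    for (b in (a + 1):length(classes)) {
      sel <- y %in% classes[c(a, b)]
      Xp <- X[sel, , drop = FALSE]
      yp <- ifelse(y[sel] == classes[a], 1, -1)
      fit <- smo_linear_svm(Xp, yp, C = C, eps = eps)
      pairs[[length(pairs) + 1L]] <-
        list(class_pos = classes[a], class_neg = classes[b],
             w = fit$w, b = fit$b, objective = fit$objective)
    }
  }
  structure(
    list(kind = "linear_svm", classes = classes, features = colnames(X),
         C = C, pairs = pairs),
    class = c("armsense_svm", "armsense_model")
  )
}

#' @export
predict.armsense_svm <- function(object, newdata, ...) {
  X <- as_feature_matrix(newdata, object$features)
  K <- length(object$classes)
  votes <- matrix(0, nrow(X), K, dimnames = list(NULL, object$classes))
  scores <- votes
  for (p in object$pairs) {
    f <- drop(X %*% p$w) + p$b
    pos <- f > 0
    votes[, p$class_pos] <- votes[, p$class_pos] + as.numeric(pos)
    votes[, p$class_neg] <- votes[, p$class_neg] + as.numeric(!pos)
    scores[, p$class_pos] <- scores[, p$class_pos] + f
    scores[, p$class_neg] <- scores[, p$class_neg] - f
  }
  # majority vote; ties resolved by the summed decision values, then by the
  # lowest class code
  best <- vapply(seq_len(nrow(X)), function(i) {
    v <- votes[i, ]
    tied <- which(v == max(v))
    if (length(tied) > 1) tied <- tied[which.max(scores[i, tied])]
    tied[1]
  }, integer(1))
  object$classes[best]
}
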