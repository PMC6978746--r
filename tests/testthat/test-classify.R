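test_that("LDA with symmetric classes decides by the perpendicular bisector", {
  # two classes with identical covariance and means at +/- m: the boundary
  # is the hyperplane through the origin orthogonal to m
  set.seed(5)
  m <- c(1, 1)
  a_rows <- sweep(matrix(rnorm(100, sd = 0.5), 50, 2), 2, m, `+`)
  # class b is the exact reflection, so empirical means are +/- mu and the
  # pooled covariance is shared exactly
  df <- data.frame(rbind(a_rows, -a_rows))
  names(df) <- c("f1", "f2")
  df$label <- rep(c("a", "b"), each = 50)
  df$subject_id <- "toy"
  model <- train_lda(gesture_db(df, integer(0)))
  probe <- matrix(c(0.4, 0.4, -0.4, -0.4, 2, 1, -1, -2), 4, 2, byrow = TRUE)
  expect_equal(predict(model, probe), c("a", "b", "a", "b"))
  # points exactly on the bisector go to the first class only by tie-break;
  # just off it they flip sides
  eps <- 1e-6
  expect_equal(predict(model, matrix(c(eps, eps, -eps, -eps), 2, 2,
                                     byrow = TRUE)),
               c("a", "b"))
})

test_that("QDA reduces to LDA when class covariances are equal by construction",
{
  db <- toy_db(n_per_class = 40, classes = c("a", "b", "c"), d = 3,
               sep = 4, noise = 1, seed = 8)
  X <- db_features(db)
  grid <- matrix(rnorm(300, sd = 4), 100, 3)
  lda_pred <- predict(train_lda(db), grid)
  qda_pred <- predict(train_qda(db), grid)
  # same spherical class covariances: the two rules agree except very close
  # to the boundary, where finite-sample covariance differences matter
  expect_gt(mean(lda_pred == qda_pred), 0.95)
})

test_that("1-NN scores 100% on its own distinct training rows", {
  db <- toy_db(n_per_class = 15, classes = c("a", "b", "c"), d = 4, seed = 3)
  model <- train_knn(db, k = 1)
  expect_equal(predict(model, db), db$label)
  expect_error(train_knn(db, k = 0), "k must")
  expect_error(train_knn(db, k = 100), "k must")
})

test_that("the linear SVM separates a printed 4-point toy exactly", {
  df <- data.frame(f1 = c(0, 0, 2, 2), f2 = c(0, 1, 2, 3),
                   label = c("a", "a", "b", "b"), subject_id = "toy")
  model <- train_linear_svm(gesture_db(df, integer(0)), C = 1)
  expect_equal(predict(model, df), df$label)
  expect_equal(length(model$pairs), 1)
})

test_that("SMO pairwise objectives match the libsvm oracle on a seeded database",
{
  skip_if_not_installed("e1071")
  db <- tiny_database(seed = 40, repetitions = 5, noise_sd = 0.06)
  model <- train_linear_svm(db, C = 1)
  X <- db_features(db); y <- db$label
  for (p in model$pairs[c(1, 5, 12, 20, 28)]) {
    sel <- y %in% c(p$class_pos, p$class_neg)
    Xp <- X[sel, , drop = FALSE]
    yp <- ifelse(y[sel] == p$class_pos, 1, -1)
    sv <- e1071::svm(Xp, factor(yp), kernel = "linear", cost = 1,
                     scale = FALSE)
    w <- drop(t(sv$coefs) %*% sv$SV)
    b <- -sv$rho
    obj_oracle <- 0.5 * sum(w^2) + sum(pmax(0, 1 - yp * (Xp %*% w + b)))
    expect_equal(p$objective, obj_oracle, tolerance = 1e-3)
  }
})

test_that("separable SVM boundary direction survives feature rescaling", {
  df <- data.frame(f1 = c(0, 0.2, 3, 3.2), f2 = c(0, 0.5, 3, 3.5),
                   label = c("a", "a", "b", "b"), subject_id = "toy")
  m1 <- train_linear_svm(gesture_db(df, integer(0)), C = 1)
  df10 <- df
  df10$f1 <- df$f1 * 10; df10$f2 <- df$f2 * 10
  m2 <- train_linear_svm(gesture_db(df10, integer(0)), C = 1 / 100)
  w1 <- m1$pairs[[1]]$w / sqrt(sum(m1$pairs[[1]]$w^2))
  w2 <- m2$pairs[[1]]$w / sqrt(sum(m2$pairs[[1]]$w^2))
  expect_equal(w1, w2, tolerance = 1e-4)
})

test_that("from-scratch classifiers track established implementations", {
  skip_if_not_installed("MASS")
  skip_if_not_installed("e1071")
  skip_if_not_installed("class")
  agree <- c(lda = 0, qda = 0, svm = 0, knn = 0)
  n_rows <- 0
  for (seed in 1:20) {
    db <- tiny_database(seed = seed, repetitions = 8, noise_sd = 0.06,
                        subject_id = paste0("O", seed))
    X <- db_features(db); y <- factor(db$label)
    n_rows <- n_rows + nrow(db)
    agree["lda"] <- agree["lda"] +
      sum(predict(train_lda(db), db) ==
            as.character(predict(MASS::lda(X, y), X)$class))
    agree["qda"] <- agree["qda"] +
      sum(predict(train_qda(db), db) ==
            as.character(predict(MASS::qda(X, y), X)$class))
    agree["svm"] <- agree["svm"] +
      sum(predict(train_linear_svm(db), db) ==
            as.character(predict(e1071::svm(X, y, kernel = "linear",
                                            cost = 1, scale = FALSE), X)))
    agree["knn"] <- agree["knn"] +
      sum(predict(train_knn(db, 1), db) ==
            as.character(class::knn(X, X, y, k = 1)))
  }
  expect_true(all(agree / n_rows >= 0.99))
})

test_that("training errors on degenerate input are explicit", {
  db <- toy_db(n_per_class = 5, classes = c("a", "b"))
  one_class <- db[db$label == "a", ]
  expect_error(train_lda(one_class), "2 classes")
  tiny <- db[c(1, 6, 7), ]  # class a has a single row
  expect_error(train_lda(tiny), "at least 2")
  bad <- db
  bad$f1[1] <- NA
  expect_error(train_linear_svm(bad), "non-finite")
})

test_that("cross-validation accounting identities hold", {
  db <- tiny_database(seed = 50, repetitions = 4)
  # a label-leak feature makes any classifier perfect under both schemes
  leak <- db
  leak$f_leak <- as.numeric(factor(leak$label))
  leak <- gesture_db(leak[, c("f_leak", "label", "subject_id")], integer(0))
  ev10 <- cross_validate(leak, train_lda, cv_kfold(4, seed = 1))
  evloo <- cross_validate(leak, train_lda, cv_loo())
  expect_equal(ev10$accuracy, 100)
  expect_equal(evloo$accuracy, 100)
  # LOO runs exactly n folds of size one
  expect_equal(length(evloo$fold_accuracies), nrow(leak))
  expect_true(all(evloo$fold_accuracies %in% c(0, 100)))
  # confusion rows sum to the true class counts; pooled accuracy is the
  # count-weighted mean of per-class accuracies
  ev <- cross_validate(db, train_lda, cv_kfold(4, seed = 2))
  cm <- ev$confusion
  expect_equal(unname(rowSums(cm)), unname(table(db$label)[rownames(cm)]),
               ignore_attr = TRUE)
  expect_equal(ev$pooled_accuracy,
               sum(ev$per_class_accuracy * rowSums(cm)) / sum(cm))
  expect_error(cross_validate(db, train_lda, cv_kfold(99, seed = 1)),
               "exceed")
})

test_that("stratified folds are deterministic given the seed", {
  db <- tiny_database(seed = 51, repetitions = 4)
  ev1 <- cross_validate(db, function(d) train_linear_svm(d),
                        cv_kfold(4, seed = 9))
  ev2 <- cross_validate(db, function(d) train_linear_svm(d),
                        cv_kfold(4, seed = 9))
  expect_identical(ev1$fold_accuracies, ev2$fold_accuracies)
  expect_identical(ev1$confusion, ev2$confusion)
})

test_that("10-fold accuracy matches an oracle harness on exported folds", {
  skip_if_not_installed("MASS")
  db <- tiny_database(seed = 52, repetitions = 5, noise_sd = 0.08)
  scheme <- cv_kfold(5, seed = 3)
  folds <- armsense:::assign_folds(db, scheme)
  X <- db_features(db); y <- db$label
  oracle_acc <- vapply(sort(unique(folds)), function(f) {
    fit <- MASS::lda(X[folds != f, , drop = FALSE],
                     factor(y[folds != f]))
    100 * mean(as.character(
      predict(fit, X[folds == f, , drop = FALSE])$class) == y[folds == f])
  }, numeric(1))
  ev <- cross_validate(db, train_lda, scheme)
  expect_equal(ev$accuracy, mean(oracle_acc), tolerance = 1e-8)
})

test_that("sensor ablation preserves the more-sensors-is-better ordering", {
  dbs <- lapply(1:3, function(i) {
    tiny_database(seed = 60 + i, repetitions = 5, noise_sd = 0.05,
                  subject_id = paste0("S", i))
  })
  tab <- ablation_study(dbs, list(lda = train_lda), cv_kfold(5, seed = 1))
  expect_equal(nrow(tab), 7)
  full <- tab$mean_accuracy[tab$sensors == "fsr1+fsr2+fsr3"]
  pairs <- tab$mean_accuracy[tab$sensors %in%
                               c("fsr1+fsr2", "fsr1+fsr3", "fsr2+fsr3")]
  singles <- tab$mean_accuracy[tab$sensors %in% c("fsr1", "fsr2", "fsr3")]
  expect_gte(full, max(pairs))
  expect_gte(max(pairs), max(singles))
  # repeated run with the same fold seed is identical
  tab2 <- ablation_study(dbs, list(lda = train_lda), cv_kfold(5, seed = 1))
  expect_identical(tab, tab2)
})

test_that("reproducibility evaluation is held-out classification", {
  db1 <- tiny_database(seed = 70, repetitions = 5)
  model <- train_lda(db1)
  # identical subject parameters: second session classifies at the
  # within-session level
  db2 <- tiny_database(seed = 71, repetitions = 5)
  ev_same <- reproducibility_eval(model, db2)
  expect_gte(ev_same$accuracy,
             cross_validate(db1, train_lda, cv_kfold(5, 1))$accuracy - 5)
  # disjoint class vocabularies: everything is wrong
  toy <- toy_db(n_per_class = 5, classes = c("x", "y"), d = 6, seed = 2)
  names(toy)[1:6] <- names(db1)[1:6]
  ev_disjoint <- reproducibility_eval(model, gesture_db(toy, 1:3))
  expect_equal(ev_disjoint$accuracy, 0)
})

test_that("re-donning the armband degrades second-session accuracy on average",
{
  base <- tiny_profile(noise_sd = 0.02)
  acc_same <- numeric(20); acc_shift <- numeric(20)
  for (s in 1:20) {
    subj <- draw_subject_profile(base, seed = 500 + s)
    db1 <- tiny_database(seed = s, repetitions = 4, profile = subj)
    model <- train_lda(db1)
    db_same <- tiny_database(seed = 1000 + s, repetitions = 4,
                             profile = subj)
    redon <- draw_subject_profile(base, seed = 2000 + s)
    subj2 <- subj
    subj2$subject_scale <- subj$subject_scale * redon$subject_scale
    subj2$subject_offset <- subj$subject_offset + redon$subject_offset
    db_shift <- tiny_database(seed = 1000 + s, repetitions = 4,
                              profile = subj2)
    acc_same[s] <- reproducibility_eval(model, db_same)$accuracy
    acc_shift[s] <- reproducibility_eval(model, db_shift)$accuracy
  }
  expect_lt(mean(acc_shift), mean(acc_same))
})
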