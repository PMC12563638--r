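test_that("all six classifiers separate well-separated blobs", {
  blobs <- make_blobs(30, sep = 8, seed = 71)
  test <- make_blobs(10, sep = 8, seed = 72)
  for (id in classifier_specs()$id) {
    pred <- train_predict(id, blobs$X, blobs$y, test$X)
    expect_equal(pred, test$y, info = id)
  }
})

test_that("classifier codes map C1..C6 and unknown ids fail", {
  expect_equal(classifier_code("lda"), "C6")
  expect_equal(train_predict("C6", make_blobs(10)$X, make_blobs(10)$y,
                             make_blobs(10)$X),
               train_predict("lda", make_blobs(10)$X, make_blobs(10)$y,
                             make_blobs(10)$X))
  expect_error(train_predict("tree", diag(4), c(0, 1, 0, 1), diag(4)),
               "unknown classifier")
  expect_error(train_predict("lda", diag(4), rep(1, 4), diag(4)),
               "single class")
})

test_that("kNN-3 takes the majority of the three nearest neighbours", {
  Z_train <- rbind(c(0, 0), c(0.1, 0), c(0, 0.1), c(9, 9), c(9.1, 9))
  y_train <- c(1, 1, 0, 0, 0)
  expect_equal(train_predict("knn3", Z_train, y_train, rbind(c(0.02, 0.02))),
               1L)
})

test_that("LDA with identical class means predicts near chance", {
  accs <- vapply(1:50, function(s) {
    set.seed(s)
    X <- matrix(rnorm(60 * 4), ncol = 4)
    y <- rep(0:1, 30)
    Xt <- matrix(rnorm(40 * 4), ncol = 4)
    yt <- rep(0:1, 10)
    mean(train_predict("lda", X, y, Xt) == yt) * 100
  }, numeric(1))
  expect_gt(mean(accs), 35)
  expect_lt(mean(accs), 65)
})

test_that("accuracy follows the confusion-count definition", {
  expect_equal(accuracy(list(tp = 20, tn = 20, fp = 5, fn = 5)), 80)
  expect_equal(accuracy(list(tp = 25, tn = 25, fp = 0, fn = 0)), 100)
  expect_equal(accuracy(list(tp = 0, tn = 0, fp = 25, fn = 25)), 0)
  expect_error(accuracy(list(tp = 0, tn = 0, fp = 0, fn = 0)), "no evaluated")
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(cc, list(tp = 1L, tn = 1L, fp = 1L, fn = 1L))
})

test_that("LOOCV tests each trial exactly once", {
  blobs <- make_blobs(10, sep = 8, seed = 73)
  fm <- fm_from_matrix(blobs$X, blobs$y)
  res <- run_loocv(fm, "knn3")
  expect_equal(res$n_folds, 20)
  expect_equal(sort(res$predictions$index), 1:20)
  expect_equal(res$accuracy, 100)
  expect_equal(res$accuracy,
               accuracy(confusion_counts(res$predictions$truth,
                                         res$predictions$pred)))
})

test_that("stratified 10-fold folds are balanced and seed-reproducible", {
  blobs <- make_blobs(25, sep = 8, seed = 74)
  fm <- fm_from_matrix(blobs$X, blobs$y)
  r1 <- run_kfold(fm, "knn3", seed = 5)
  r2 <- run_kfold(fm, "knn3", seed = 5)
  expect_identical(r1$predictions$fold, r2$predictions$fold)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_equal(r1$accuracy, 100)
  sizes <- table(r1$predictions$fold)
  expect_true(all(sizes == 5))
  per_fold_balance <- tapply(r1$predictions$truth, r1$predictions$fold, mean)
  expect_true(all(abs(per_fold_balance - 0.5) < 0.3))
  r3 <- run_kfold(fm, "knn3", seed = 6)
  expect_false(identical(r1$predictions$fold, r3$predictions$fold))
})

test_that("LOSOCV holds out whole subjects without leakage", {
  set.seed(75)
  fms <- lapply(1:6, function(s) {
    blobs <- make_blobs(8, sep = 6, seed = 80 + s)
    fm_from_matrix(blobs$X, blobs$y, subject_id = paste0("S", s))
  })
  res <- run_losocv(fms, "knn3")
  expect_equal(res$n_folds, 6)
  expect_equal(sort(res$per_subject$subject_id), paste0("S", 1:6))
  # each subject's rows appear in exactly one fold
  per_fold <- split(res$predictions$subject_id, res$predictions$fold)
  expect_true(all(vapply(per_fold, function(x) length(unique(x)) == 1,
                         logical(1))))
  expect_equal(res$mean_accuracy, mean(res$per_subject$accuracy))
})

test_that("subject-specific offsets hurt LOSOCV more than LOOCV", {
  wins <- 0
  for (s in 1:10) {
    set.seed(200 + s)
    fms <- lapply(1:5, function(su) {
      offset <- rnorm(1, sd = 4) # subject-level shift of the class boundary
      X <- rbind(matrix(rnorm(10 * 3, mean = offset), ncol = 3),
                 matrix(rnorm(10 * 3, mean = offset + 2.5), ncol = 3))
      fm_from_matrix(X, rep(0:1, each = 10), paste0("S", su))
    })
    loocv <- mean(vapply(fms, function(f) run_loocv(f, "lda")$accuracy,
                         numeric(1)))
    losocv <- run_losocv(fms, "lda")$mean_accuracy
    if (losocv < loocv) wins <- wins + 1
  }
  expect_gte(wins, 9)
})
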