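new_cv_result <- function(predictions, scheme, classifier, n_folds,
                          subject_id = NA_character_) {
  acc <- accuracy(confusion_counts(predictions$truth, predictions$pred))
  structure(
    list(accuracy = acc, predictions = predictions, scheme = scheme,
         classifier = classifier, n_folds = n_folds,
         subject_id = subject_id),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s / %s: accuracy %.2f%% over %d folds\n",
              x$scheme, x$classifier, x$accuracy, x$n_folds))
  invisible(x)
}

#' @rdname run_loocv
#' @param x A `cv_result`.
#' @param ... Unused.
#' @export
tidy.cv_result <- function(x, ...) {
  tibble::tibble(subject_id = x$subject_id, scheme = x$scheme,
                 classifier = x$classifier, accuracy = x$accuracy,
                 n_folds = x$n_folds)
}

#' @rdname run_loocv
#' @export
glance.cv_result <- function(x, ...) tidy(x)

#' Leave-one-out cross-validation within a subject
#'
#' One fold per trial: the held-out trial is predicted from a model trained
#' on all remaining trials, features z-scored with parameters fit on the
#' training fold only. Every trial is tested exactly once; the reported
#' accuracy is the percentage of correct single-trial predictions. Seed-free
#' and deterministic.
#'
#' @param fm A [build_feature_matrix()] result (or any tibble with a
#'   `label` column plus feature columns).
#' @param classifier Classifier id or code, see [classifier_specs()].
#' @param standardize Z-score per fold (default `TRUE`).
#' @return A `cv_result`: accuracy (percent), per-fold predictions tibble
#'   (`index`, `truth`, `pred`, `fold`), fold count.
#' @export
run_loocv <- function(fm, classifier = "lda", standardize = TRUE) {
  X <- feature_values(fm)
  y <- feature_labels(fm)
  n <- nrow(X)
  stopifnot(n >= 3)
  pred <- integer(n)
  for (i in seq_len(n)) {
    sp <- split_features(X, y, test_idx = i, standardize)
    pred[i] <- train_predict(classifier, sp$train, y[-i], sp$test)
  }
  predictions <- tibble::tibble(index = seq_len(n), truth = y, pred = pred,
                                fold = seq_len(n))
  new_cv_result(predictions, "loocv", normalize_classifier_id(classifier),
                n, subject_id = subject_of(fm))
}

#' Stratified k-fold cross-validation within a subject
#'
#' Random stratified folds: within each class, trials are shuffled
#' (reproducibly under `seed`) and dealt to folds round-robin, so folds are
#' near-equal in size and class-balanced. Accuracy is pooled over all test
#' predictions. The caller's RNG state is left untouched.
#'
#' @inheritParams run_loocv
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold shuffle.
#' @return A `cv_result`, see [run_loocv()].
#' @export
run_kfold <- function(fm, classifier = "lda", k = 10, seed = 1,
                      standardize = TRUE) {
  X <- feature_values(fm)
  y <- feature_labels(fm)
  n <- nrow(X)
  stopifnot(n >= k, length(unique(y)) == 2)
  fold <- integer(n)
  local_seed(seed, {
    # deal classes in opposite directions so overall fold sizes stay equal
    # even when the per-class count is not a multiple of k
    for (ci in seq_along(unique(y))) {
      cls <- unique(y)[ci]
      idx <- sample(which(y == cls))
      order <- if (ci %% 2 == 1) seq_len(k) else rev(seq_len(k))
      fold[idx] <- rep_len(order, length(idx))
    }
  })
  pred <- integer(n)
  for (f in seq_len(k)) {
    test_idx <- which(fold == f)
    if (length(test_idx) == 0) next
    sp <- split_features(X, y, test_idx, standardize)
    pred[test_idx] <- train_predict(classifier, sp$train, y[-test_idx],
                                    sp$test)
  }
  predictions <- tibble::tibble(index = seq_len(n), truth = y, pred = pred,
                                fold = fold)
  new_cv_result(predictions, "kfold10",
                normalize_classifier_id(classifier), k,
                subject_id = subject_of(fm))
}

#' Leave-one-subject-out cross-validation
#'
#' One fold per subject: all trials of the held-out subject are predicted
#' from a model trained on every other subject's trials (z-scoring fit on
#' the training pool). Training rows never include the test subject. The
#' per-subject accuracies and their mean quantify cross-subject
#' generalization.
#'
#' @param fms Named list of [build_feature_matrix()] results, one per
#'   subject (feature columns must match).
#' @inheritParams run_loocv
#' @return List of class `losocv_result`: `per_subject` tibble
#'   (`subject_id`, `accuracy`, `n_test`), `mean_accuracy`, `n_folds`,
#'   `classifier`, and the pooled `predictions`.
#' @export
run_losocv <- function(fms, classifier = "svm_rbf", standardize = TRUE) {
  stopifnot(is.list(fms), length(fms) >= 2)
  ids <- vapply(fms, subject_of, character(1))
  stopifnot(!anyDuplicated(ids))
  Xs <- lapply(fms, feature_values)
  ys <- lapply(fms, feature_labels)
  rows <- vector("list", length(fms))
  preds <- vector("list", length(fms))
  for (s in seq_along(fms)) {
    X_test <- Xs[[s]]
    y_test <- ys[[s]]
    X_train <- do.call(rbind, Xs[-s])
    y_train <- unlist(ys[-s])
    if (standardize) {
      st <- suppressWarnings(standardize_train_apply(X_train, X_test))
      X_train <- st$train
      X_test <- st$test
    }
    p <- train_predict(classifier, X_train, y_train, X_test)
    rows[[s]] <- tibble::tibble(
      subject_id = ids[s],
      accuracy = accuracy(confusion_counts(y_test, p)),
      n_test = length(y_test))
    preds[[s]] <- tibble::tibble(subject_id = ids[s], truth = y_test,
                                 pred = p, fold = s)
  }
  per_subject <- dplyr::bind_rows(rows)
  structure(
    list(per_subject = per_subject,
         mean_accuracy = mean(per_subject$accuracy),
         n_folds = length(fms),
         classifier = normalize_classifier_id(classifier),
         predictions = dplyr::bind_rows(preds)),
    class = "losocv_result"
  )
}

#' @export
print.losocv_result <- function(x, ...) {
  cat(sprintf("<losocv_result> %s: mean accuracy %.2f%% over %d subjects\n",
              x$classifier, x$mean_accuracy, x$n_folds))
  invisible(x)
}

#' @rdname run_losocv
#' @param x A `losocv_result`.
#' @param ... Unused.
#' @export
tidy.losocv_result <- function(x, ...) {
  dplyr::mutate(x$per_subject, scheme = "losocv", classifier = x$classifier)
}

split_features <- function(X, y, test_idx, standardize) {
  X_train <- X[-test_idx, , drop = FALSE]
  X_test <- X[test_idx, , drop = FALSE]
  if (standardize) {
    st <- suppressWarnings(standardize_train_apply(X_train, X_test))
    list(train = st$train, test = st$test)
  } else {
    list(train = X_train, test = X_test)
  }
}

subject_of <- function(fm) {
  if (!is.null(fm$subject_id)) as.character(fm$subject_id[1]) else
    NA_character_
}
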