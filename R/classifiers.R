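#' The six reference classifiers
#'
#' The evaluation protocol compares six conventional classifiers, coded
#' C1-C6: linear-kernel SVM, RBF-kernel SVM, kNN with k = 3, kNN with
#' k = 5, Gaussian naive Bayes, and LDA (pooled covariance, priors from
#' training labels). Hyperparameters follow the most common defaults: SVM
#' cost 1.0 with the RBF width set by the "scale" convention
#' `1 / (n_features * var(Z))`; kNN with Euclidean metric and uniform
#' (majority) votes.
#'
#' @return A tibble with columns `id`, `code`, `label`.
#' @examples
#' classifier_specs()
#' @export
classifier_specs <- function() {
  tibble::tibble(
    id = c("svm_linear", "svm_rbf", "knn3", "knn5", "nb", "lda"),
    code = paste0("C", 1:6),
    label = c("SVM (linear)", "SVM (RBF)", "kNN (k=3)", "kNN (k=5)",
              "Gaussian naive Bayes", "LDA")
  )
}

#' @rdname classifier_specs
#' @param id Classifier id or C-code.
#' @export
classifier_code <- function(id) {
  sp <- classifier_specs()
  sp$code[match(id, sp$id)]
}

normalize_classifier_id <- function(id) {
  sp <- classifier_specs()
  if (id %in% sp$id) return(id)
  if (id %in% sp$code) return(sp$id[match(id, sp$code)])
  stop("unknown classifier '", id, "'; use one of ",
       paste(sp$id, collapse = ", "), " (or C1..C6)")
}

drop_constant_cols <- function(Z_train, Z_test) {
  keep <- apply(Z_train, 2, function(col) sd(col) > 1e-12)
  if (!any(keep)) stop("train_predict: all features are constant in training")
  list(train = Z_train[, keep, drop = FALSE],
       test = Z_test[, keep, drop = FALSE])
}

#' Train a classifier and predict test labels
#'
#' Fits one of the six reference classifiers (see [classifier_specs()]) on
#' standardized training features and returns binary predictions for the
#' test rows. Deterministic given fixed data and hyperparameters. Training
#' data must contain both classes.
#'
#' @param id Classifier id (`"svm_linear"`, `"svm_rbf"`, `"knn3"`,
#'   `"knn5"`, `"nb"`, `"lda"`) or code (`"C1"`..`"C6"`).
#' @param Z_train Numeric training matrix.
#' @param y_train Integer 0/1 labels for `Z_train`.
#' @param Z_test Numeric test matrix with matching columns.
#' @param cost SVM cost parameter (default 1).
#' @return Integer vector of 0/1 predictions, one per test row.
#' @export
train_predict <- function(id, Z_train, y_train, Z_test, cost = 1) {
  id <- normalize_classifier_id(id)
  Z_train <- as.matrix(Z_train)
  Z_test <- as.matrix(Z_test)
  y_train <- as.integer(y_train)
  if (length(unique(y_train)) < 2) {
    stop("train_predict: training set contains a single class")
  }
  yf <- factor(y_train, levels = c(0, 1))
  pred <- switch(
    id,
    svm_linear = {
      fit <- e1071::svm(Z_train, yf, kernel = "linear", cost = cost,
                        scale = FALSE)
      predict(fit, Z_test)
    },
    svm_rbf = {
      # "scale" convention for the RBF width
      gam <- 1 / (ncol(Z_train) * max(var(as.vector(Z_train)), 1e-12))
      fit <- e1071::svm(Z_train, yf, kernel = "radial", cost = cost,
                        gamma = gam, scale = FALSE)
      predict(fit, Z_test)
    },
    knn3 = class::knn(Z_train, Z_test, yf, k = 3),
    knn5 = class::knn(Z_train, Z_test, yf, k = 5),
    nb = {
      fit <- e1071::naiveBayes(Z_train, yf)
      predict(fit, Z_test)
    },
    lda = {
      zz <- drop_constant_cols(Z_train, Z_test)
      fit <- withCallingHandlers(
        MASS::lda(zz$train, grouping = yf),
        warning = function(w) {
          if (grepl("collinear", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
      predict(fit, zz$test)$class
    }
  )
  as.integer(as.character(pred))
}

#' Confusion counts with "lie" as the positive class
#'
#' Tallies true/false positives and negatives, where a positive is the lie
#' class (label 1).
#'
#' @param truth,pred Integer 0/1 vectors of equal length.
#' @return List with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, pred) {
  truth <- as.integer(truth)
  pred <- as.integer(pred)
  stopifnot(length(truth) == length(pred))
  list(tp = sum(truth == 1 & pred == 1),
       tn = sum(truth == 0 & pred == 0),
       fp = sum(truth == 0 & pred == 1),
       fn = sum(truth == 1 & pred == 0))
}

#' Classification accuracy from confusion counts
#'
#' `100 * (TP + TN) / (TP + TN + FP + FN)`, in percent.
#'
#' @param counts A list with `tp`, `tn`, `fp`, `fn` (see
#'   [confusion_counts()]).
#' @return Accuracy in `[0, 100]`.
#' @examples
#' accuracy(list(tp = 20, tn = 20, fp = 5, fn = 5)) # 80
#' @export
accuracy <- function(counts) {
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  if (total == 0) stop("accuracy: no evaluated samples")
  100 * (counts$tp + counts$tn) / total
}
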