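test_that("aggregation reproduces the bundled benchmark Mean/SD rows", {
  agg <- aggregate_report(ref_subject_accuracy())
  pick <- function(sch, clf) agg[agg$scheme == sch & agg$classifier == clf, ]
  expect_equal(round(pick("loocv", "lda")$mean, 2), 82.74)
  expect_equal(round(pick("loocv", "lda")$sd, 2), 10.87)
  expect_equal(round(pick("kfold10", "lda")$mean, 2), 82.00)
  expect_equal(round(pick("losocv", "svm_rbf")$mean, 2), 64.07)
  expect_equal(round(pick("losocv", "svm_rbf")$sd, 2), 10.49)
  expect_true(all(agg$n == 27))
})

test_that("aggregation handles constants and rejects empty input", {
  df <- tibble::tibble(classifier = "lda", scheme = "loocv",
                       accuracy = rep(84, 9))
  agg <- aggregate_report(df)
  expect_equal(agg$mean, 84)
  expect_equal(agg$sd, 0)
  expect_error(aggregate_report(df[0, ]), "empty")
})

test_that("report_wide lays out subjects x classifiers with Mean/SD rows", {
  rep <- ref_subject_accuracy()
  rep$channel_set <- "best"
  w <- report_wide(rep, "loocv")
  expect_equal(nrow(w), 29)
  expect_equal(w$subject[28:29], c("Mean", "SD"))
  expect_equal(w$C6[28], 82.74)
  expect_equal(w$C2[28], 80.15)
  body <- w[1:27, ]
  expect_equal(round(mean(body$C6), 2), w$C6[28])
})

test_that("best_channel_per_subject takes the argmax with montage tie-break", {
  grid <- tidyr::expand_grid(
    subject_id = c("S1", "S2"),
    channel_set = c("AF3", "T7", "PZ", "T8", "AF4"))
  report <- dplyr::mutate(grid, classifier = "lda", scheme = "loocv",
                          accuracy = c(60, 70, 90, 90, 50,   # S1: PZ/T8 tie
                                       55, 55, 55, 55, 55))  # S2: 5-way tie
  cr <- best_channel_per_subject(report, "lda", "loocv")
  best <- cr$best[order(cr$best$subject_id), ]
  expect_equal(best$channel, c("PZ", "AF3")) # montage order breaks ties
  expect_equal(best$ties[[1]], c("PZ", "T8"))
  expect_length(best$ties[[2]], 5)
  expect_equal(sum(cr$occurrence$n), 2)
})

test_that("missing single-channel cells are reported by name", {
  report <- tibble::tibble(
    subject_id = "S1", channel_set = c("AF3", "T7", "PZ", "T8"),
    classifier = "lda", scheme = "loocv", accuracy = 50)
  expect_error(best_channel_per_subject(report, "lda", "loocv"), "AF4")
})

test_that("channel occurrences tally the bundled best-channel tables", {
  bc <- ref_best_channels()
  t_loocv <- channel_occurrences(bc$channel[bc$scheme == "loocv"])
  expect_equal(t_loocv$n[match(c("PZ", "T7", "T8", "AF4", "AF3"),
                               t_loocv$channel)],
               c(8L, 7L, 7L, 4L, 1L))
  t_losocv <- channel_occurrences(bc$channel[bc$scheme == "losocv"])
  expect_equal(t_losocv$n[match(c("PZ", "T7", "AF4", "T8", "AF3"),
                                t_losocv$channel)],
               c(8L, 8L, 7L, 3L, 1L))
  expect_equal(sum(t_loocv$n), 27)
})

test_that("pairwise-channel table aggregates match its printed means", {
  agg <- aggregate_report(ref_pairwise_accuracy())
  pick <- function(sch, clf, pair) {
    agg[agg$scheme == sch & agg$classifier == clf &
          agg$channel_pair == pair, ]
  }
  expect_equal(round(pick("kfold10", "svm_rbf", "T7-PZ")$mean, 2), 75.33)
  expect_equal(round(pick("kfold10", "lda", "T7-PZ")$mean, 2), 76.89)
  expect_equal(round(pick("losocv", "svm_rbf", "PZ-T8")$mean, 2), 50.81)
})

test_that("plot builders return ggplot objects", {
  grid <- tidyr::expand_grid(subject_id = c("S1", "S2"),
                             channel_set = c("AF3", "T7", "PZ", "T8", "AF4"))
  report <- dplyr::mutate(grid, classifier = "lda", scheme = "loocv",
                          accuracy = runif(10, 40, 90))
  report <- structure(report,
                      class = c("eval_report", class(tibble::tibble())))
  expect_s3_class(autoplot(report), "ggplot")
  cr <- best_channel_per_subject(report, "lda", "loocv")
  expect_s3_class(autoplot(cr), "ggplot")
  expect_s3_class(autoplot(tsmfe(rnorm(100))), "ggplot")
  expect_s3_class(autoplot(hmfe(rnorm(128), level = 3)), "ggplot")
})
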