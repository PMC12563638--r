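test_that("the fused vector concatenates FE, TSMFE and HMFE in order", {
  set.seed(31)
  x <- rnorm(384)
  v <- extract_trial_features(x)
  expect_length(v, 16)
  expect_identical(unname(v[1]), fuzzy_entropy(x)$fe)
  expect_identical(unname(v[2:11]), tsmfe(x)$values)
  expect_identical(unname(v[12:16]), unname(hmfe(x)$values))
  expect_identical(v, extract_trial_features(x))
  expect_equal(names(v)[c(1, 2, 12, 16)],
               c("FE", "TSMFE.1", "HMFE.A4", "HMFE.D1"))
})

test_that("feature count follows 1 + k_max + level + 1 for any config", {
  for (km in c(3, 10)) {
    for (lev in c(2, 4)) {
      cfg <- entropy_config(k_max = km, level = lev)
      expect_equal(n_features_per_channel(cfg), 1 + km + lev + 1)
      v <- extract_trial_features(rnorm(256), cfg)
      expect_length(v, 1 + km + lev + 1)
    }
  }
})

make_tiny_trialset <- function(n_trials = 6, channels = c("PZ", "T7"),
                               n = 64, seed = 51) {
  set.seed(seed)
  trials <- array(rnorm(n_trials * length(channels) * n),
                  dim = c(n_trials, length(channels), n))
  trial_set(trials, rep(0:1, length.out = n_trials), 128, channels, "S1")
}

test_that("build_feature_matrix shapes and names per-channel blocks", {
  ts <- make_tiny_trialset()
  cfg <- entropy_config(k_max = 3, level = 2)
  fm1 <- build_feature_matrix(ts, channels = "PZ", cfg = cfg)
  expect_s3_class(fm1, "feature_matrix")
  expect_equal(dim(feature_values(fm1)), c(6, 7)) # 1 + 3 + (2 + 1)
  fm2 <- build_feature_matrix(ts, channels = c("T7", "PZ"), cfg = cfg)
  expect_equal(dim(feature_values(fm2)), c(6, 14))
  expect_equal(attr(fm2, "feature_names")[1], "T7.FE")
  expect_equal(attr(fm2, "feature_names")[8], "PZ.FE")
  # block content matches single-channel extraction, in requested order
  expect_equal(unname(feature_values(fm2)[, 8:14]),
               unname(feature_values(fm1)))
  expect_equal(feature_labels(fm2), ts$labels)
  expect_error(build_feature_matrix(ts, channels = "XX"), "available: PZ, T7")
})

test_that("permuting trials permutes feature rows identically", {
  ts <- make_tiny_trialset(n_trials = 5, channels = "PZ")
  cfg <- entropy_config(k_max = 3, level = 2)
  fm <- build_feature_matrix(ts, cfg = cfg)
  perm <- c(3, 1, 5, 2, 4)
  ts2 <- trial_set(ts$trials[perm, , , drop = FALSE], ts$labels[perm],
                   ts$fs, ts$channels, ts$subject_id)
  fm2 <- build_feature_matrix(ts2, cfg = cfg)
  expect_equal(unname(feature_values(fm2)),
               unname(feature_values(fm)[perm, ]))
})

test_that("standardization is fit on training rows only", {
  set.seed(61)
  X_train <- matrix(rnorm(40, mean = 3, sd = 2), ncol = 4)
  X_test <- matrix(rnorm(12, mean = 3, sd = 2), ncol = 4)
  st <- standardize_train_apply(X_train, X_test)
  expect_lt(max(abs(colMeans(st$train))), 1e-10)
  expect_lt(max(abs(apply(st$train, 2, sd) - 1)), 1e-10)
  # hand-computed 2x2 example
  tr <- matrix(c(1, 3, 10, 30), ncol = 2)
  te <- matrix(c(2, 20), ncol = 2)
  st2 <- standardize_train_apply(tr, te)
  expect_equal(st2$test,
               matrix(c((2 - 2) / sd(c(1, 3)), (20 - 20) / sd(c(10, 30))),
                      ncol = 2))
})

test_that("zero-variance features map to zero with a warning", {
  tr <- cbind(c(1, 2, 3), c(5, 5, 5))
  te <- cbind(c(2), c(9))
  expect_warning(st <- standardize_train_apply(tr, te), "zero-variance")
  expect_equal(st$train[, 2], rep(0, 3))
  expect_equal(st$test[, 2], 0)
})
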