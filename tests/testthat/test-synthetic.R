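test_that("generated datasets match the configured layout exactly", {
  cfg <- sim_config(n_subjects = 2, n_trials_per_condition = 4, seed = 3)
  ds <- generate_dataset(cfg)
  expect_s3_class(ds, "eeg_dataset")
  expect_length(ds, 2)
  expect_equal(dim(ds$S1$trials), c(8, 5, 384))
  expect_equal(sum(ds$S1$labels == 1), 4)
  expect_equal(sum(ds$S1$labels == 0), 4)
  expect_equal(ds$S1$channels, c("AF3", "T7", "PZ", "T8", "AF4"))
  # 25 x 3 s = 75 s per condition under defaults
  d <- sim_config()
  expect_equal(d$n_trials_per_condition * d$trial_seconds, 75)
})

test_that("the same seed regenerates a bitwise-identical dataset", {
  cfg <- sim_config(n_subjects = 2, n_trials_per_condition = 3, seed = 11)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$S1$trials, d2$S1$trials)
  expect_identical(d1$S2$trials, d2$S2$trials)
  d3 <- generate_dataset(sim_config(n_subjects = 2,
                                    n_trials_per_condition = 3, seed = 12))
  expect_false(identical(d1$S1$trials, d3$S1$trials))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  a <- rnorm(3)
  set.seed(123)
  invisible(generate_dataset(sim_config(n_subjects = 1,
                                        n_trials_per_condition = 2,
                                        seed = 99)))
  b <- rnorm(3)
  expect_identical(a, b)
})

test_that("the planted effect raises fuzzy entropy on informative channels", {
  cfg <- sim_config(seed = 5)
  fe_for <- function(cond, channel, n = 60) {
    vapply(seq_len(n), function(i) {
      fuzzy_entropy(generate_trial(cond, channel, sp, cfg))$fe
    }, numeric(1))
  }
  set.seed(5)
  sp <- msentropy:::draw_subject_params(cfg)
  lie_pz <- fe_for("lie", "PZ")
  truth_pz <- fe_for("truth", "PZ")
  expect_gt(mean(lie_pz), mean(truth_pz))
  expect_lt(stats::t.test(lie_pz, truth_pz)$p.value, 0.001)
})

test_that("without an effect the two conditions are indistinguishable", {
  cfg <- sim_config(effect_size = 0, seed = 6)
  set.seed(6)
  sp <- msentropy:::draw_subject_params(cfg)
  fe_for <- function(cond, n = 100) {
    vapply(seq_len(n), function(i) {
      fuzzy_entropy(generate_trial(cond, "PZ", sp, cfg))$fe
    }, numeric(1))
  }
  p <- stats::t.test(fe_for("lie"), fe_for("truth"))$p.value
  expect_gt(p, 0.01)
})

test_that("non-informative channels ignore the condition", {
  cfg <- sim_config(seed = 7) # effect on PZ, T7 only
  set.seed(7)
  sp <- msentropy:::draw_subject_params(cfg)
  fe_for <- function(cond, n = 100) {
    vapply(seq_len(n), function(i) {
      fuzzy_entropy(generate_trial(cond, "AF4", sp, cfg))$fe
    }, numeric(1))
  }
  p <- stats::t.test(fe_for("lie"), fe_for("truth"))$p.value
  expect_gt(p, 0.01)
})

test_that("write_dataset / load_dataset round-trips trials and labels", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(sim_config(n_subjects = 2,
                                    n_trials_per_condition = 3, seed = 21))
  manifest <- write_dataset(ds, dir)
  expect_true(file.exists(manifest))
  back <- load_dataset(manifest)
  expect_equal(names(back), c("S1", "S2"))
  expect_equal(back$S1$labels, sort(ds$S1$labels)) # truth block then lie block
  # condition blocks are written contiguously; compare per-condition trials
  for (lab in 0:1) {
    expect_equal(back$S2$trials[back$S2$labels == lab, , ],
                 ds$S2$trials[ds$S2$labels == lab, , ],
                 tolerance = 1e-9)
  }
})

test_that("load_dataset applies preprocessing only when data is raw", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(sim_config(n_subjects = 1,
                                    n_trials_per_condition = 2, seed = 22))
  manifest <- write_dataset(ds, dir, preprocessed = FALSE)
  raw <- load_dataset(manifest, preprocess = FALSE)
  filtered <- load_dataset(manifest) # manifest says raw -> filter
  expect_false(isTRUE(all.equal(raw$S1$trials, filtered$S1$trials)))
  # filtered trials are DC-free per channel over the recording
  expect_lt(abs(mean(filtered$S1$trials[, 1, ])), 0.5)
})
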