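#' Full entropy feature-stack configuration
#'
#' Bundles every estimator parameter of the fused feature stack: the fuzzy
#' entropy base parameters (`m`, `n`, `r_coef`/`r_abs`), the maximum
#' time-shift scale `k_max`, and the wavelet decomposition (`wavelet`,
#' `level`). Per trial and channel the stack yields
#' `1 + k_max + level + 1` features (16 under defaults): plain FE, the
#' TSMFE vector over scales `1..k_max`, and the HMFE vector over the
#' `level + 1` wavelet bands.
#'
#' @inheritParams fe_config
#' @param k_max Maximum time-shift scale (default 10).
#' @param wavelet,level Wavelet decomposition settings (defaults `"db4"`, 4).
#' @param tolerance_scope TSMFE tolerance rule, see [tsmfe()].
#' @return An object of class `entropy_config`.
#' @examples
#' entropy_config()
#' n_features_per_channel(entropy_config(k_max = 5, level = 3)) # 10
#' @export
entropy_config <- function(m = 2, n = 2, r_coef = 0.15, r_abs = NULL,
                           k_max = 10, wavelet = "db4", level = 4,
                           tolerance_scope = "subsequence") {
  base <- fe_config(m = m, n = n, r_coef = r_coef, r_abs = r_abs)
  stopifnot(k_max >= 1, level >= 1)
  structure(
    list(base = base, k_max = as.integer(k_max), wavelet = wavelet,
         level = as.integer(level), tolerance_scope = tolerance_scope),
    class = "entropy_config"
  )
}

#' @export
print.entropy_config <- function(x, ...) {
  cat(sprintf(
    "<entropy_config> m = %d, n = %g, r_coef = %g, k_max = %d, %s level %d (%d features/channel)\n",
    x$base$m, x$base$n, x$base$r_coef, x$k_max, x$wavelet, x$level,
    n_features_per_channel(x)))
  invisible(x)
}

#' @rdname entropy_config
#' @param cfg An `entropy_config`.
#' @export
n_features_per_channel <- function(cfg) {
  1L + cfg$k_max + cfg$level + 1L
}

feature_suffixes <- function(cfg) {
  c("FE",
    paste0("TSMFE.", seq_len(cfg$k_max)),
    paste0("HMFE.", c(paste0("A", cfg$level), paste0("D", cfg$level:1))))
}

#' Fused entropy feature vector of one trial channel
#'
#' Concatenates, in order: the trial's fuzzy entropy, its TSMFE vector over
#' scales `1..k_max`, and its HMFE vector over the `level + 1` wavelet
#' bands — 16 values under defaults.
#'
#' @param x Numeric series (one trial, one channel).
#' @param cfg An [entropy_config()].
#' @return Named numeric vector of length [n_features_per_channel()].
#' @examples
#' set.seed(1)
#' extract_trial_features(rnorm(384))
#' @export
extract_trial_features <- function(x, cfg = entropy_config()) {
  stopifnot(inherits(cfg, "entropy_config"))
  fe <- fuzzy_entropy(x, cfg$base)$fe
  ts <- tsmfe(x, k_max = cfg$k_max, cfg = cfg$base,
              tolerance_scope = cfg$tolerance_scope)$values
  hm <- hmfe(x, wavelet = cfg$wavelet, level = cfg$level, cfg = cfg$base)$values
  out <- c(fe, ts, unname(hm))
  names(out) <- feature_suffixes(cfg)
  out
}

#' Classifier-ready feature matrix for a channel subset
#'
#' Extracts the fused entropy vector of every trial on each requested
#' channel and concatenates the per-channel blocks in the requested order:
#' one row per trial, `n_channels * (1 + k_max + level + 1)` feature
#' columns named `"<channel>.<family>[.<index>]"` (e.g. `"PZ.FE"`,
#' `"PZ.TSMFE.3"`, `"PZ.HMFE.D2"`). Feature extraction is per-trial
#' independent — no statistic is shared across trials, so no information
#' leaks between future CV folds. Non-finite feature values are a hard
#' error.
#'
#' @param ts A [trial_set()].
#' @param channels Channel labels to use, a subset of `ts$channels`
#'   (default all, in montage order).
#' @param cfg An [entropy_config()].
#' @return A tibble of class `feature_matrix`: columns `subject_id`,
#'   `trial`, `label`, then the feature columns. Attributes
#'   `feature_names`, `channels_used` and `entropy_config` record
#'   provenance.
#' @export
build_feature_matrix <- function(ts, channels = NULL,
                                 cfg = entropy_config()) {
  stopifnot(inherits(ts, "trial_set"), inherits(cfg, "entropy_config"))
  if (is.null(channels)) channels <- ts$channels
  unknown <- setdiff(channels, ts$channels)
  if (length(unknown) > 0) {
    stop("build_feature_matrix: unknown channel(s) ",
         paste(unknown, collapse = ", "), "; available: ",
         paste(ts$channels, collapse = ", "))
  }
  blocks <- lapply(channels, function(ch) {
    extract_channel_block(ts, ch, cfg)
  })
  X <- do.call(cbind, blocks)
  assemble_feature_matrix(X, ts$labels, ts$subject_id, channels, cfg)
}

# n_trials x n_features_per_channel block for one channel
extract_channel_block <- function(ts, channel, cfg) {
  n_trials <- dim(ts$trials)[1]
  ch_idx <- match(channel, ts$channels)
  t(vapply(seq_len(n_trials), function(tr) {
    extract_trial_features(ts$trials[tr, ch_idx, ], cfg)
  }, numeric(n_features_per_channel(cfg))))
}

assemble_feature_matrix <- function(X, labels, subject_id, channels, cfg) {
  fnames <- as.vector(vapply(channels, function(ch) {
    paste0(ch, ".", feature_suffixes(cfg))
  }, character(n_features_per_channel(cfg))))
  if (any(!is.finite(X))) {
    bad <- which(!is.finite(X), arr.ind = TRUE)
    stop(sprintf(
      "build_feature_matrix: non-finite feature %s in trial %d",
      fnames[bad[1, 2]], bad[1, 1]))
  }
  colnames(X) <- fnames
  out <- tibble::as_tibble(X)
  out <- tibble::add_column(out,
                            subject_id = subject_id,
                            trial = seq_len(nrow(X)),
                            label = as.integer(labels),
                            .before = 1)
  structure(out,
            class = c("feature_matrix", class(tibble::tibble())),
            feature_names = fnames,
            channels_used = channels,
            entropy_config = cfg)
}

#' @rdname build_feature_matrix
#' @param fm A `feature_matrix`.
#' @return `feature_values()`: the bare numeric feature matrix
#'   (`n_trials x n_features`); `feature_labels()`: the integer label
#'   vector.
#' @export
feature_values <- function(fm) {
  fnames <- attr(fm, "feature_names")
  if (is.null(fnames)) {
    fnames <- setdiff(colnames(fm), c("subject_id", "trial", "label"))
  }
  as.matrix(fm[, fnames, drop = FALSE])
}

#' @rdname build_feature_matrix
#' @export
feature_labels <- function(fm) {
  as.integer(fm$label)
}

#' Fit z-scoring on training rows, apply to both splits
#'
#' Per-feature standardization fit on the training rows only (mean and
#' standard deviation), applied unchanged to the test rows — the test fold
#' never influences the transform. A zero-variance training feature is
#' mapped to 0 in both splits with a warning.
#'
#' @param X_train,X_test Numeric matrices with matching columns (`X_test`
#'   may be `NULL`).
#' @return List with `train`, `test`, `center`, `scale`.
#' @examples
#' s <- standardize_train_apply(matrix(c(1, 3, 2, 6), 2), matrix(c(2, 4), 1))
#' s$test # row z-scored with training parameters
#' @export
standardize_train_apply <- function(X_train, X_test = NULL) {
  X_train <- as.matrix(X_train)
  center <- colMeans(X_train)
  scale <- apply(X_train, 2, sd)
  zero_var <- !is.finite(scale) | scale < 1e-12
  if (any(zero_var)) {
    warning("standardize_train_apply: zero-variance feature(s) mapped to 0: ",
            paste(colnames(X_train)[zero_var], collapse = ", "))
    scale[zero_var] <- 1
    center[zero_var] <- X_train[1, zero_var]
  }
  z <- function(X) {
    Z <- sweep(sweep(as.matrix(X), 2, center), 2, scale, "/")
    Z[, zero_var] <- 0
    Z
  }
  list(train = z(X_train),
       test = if (is.null(X_test)) NULL else z(X_test),
       center = center, scale = scale)
}
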