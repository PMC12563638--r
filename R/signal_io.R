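#' Continuous multi-channel recording
#'
#' Container for a continuous multi-channel signal: a numeric matrix with one
#' sample per row and one channel per column, plus the sampling rate and
#' channel labels. Sample indices are 0-based and windows half-open in all
#' epoching arithmetic.
#'
#' @param data Numeric matrix `[n_samples x n_channels]` (microvolts).
#' @param fs Sampling rate in Hz, positive.
#' @param channels Unique channel labels, one per column.
#' @param subject_id Optional subject identifier.
#' @param condition One of `"lie"`, `"truth"`, `"unlabeled"`.
#' @return An object of class `recording`.
#' @examples
#' rec <- recording(matrix(rnorm(256 * 2), ncol = 2), fs = 128,
#'                  channels = c("PZ", "T7"))
#' rec
#' @export
recording <- function(data, fs, channels, subject_id = NA_character_,
                      condition = c("unlabeled", "lie", "truth")) {
  condition <- match.arg(condition)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  stopifnot(nrow(data) >= 1, ncol(data) >= 1)
  stopifnot(is.numeric(fs), length(fs) == 1, fs > 0)
  channels <- as.character(channels)
  if (length(channels) != ncol(data)) {
    stop("recording: ", ncol(data), " data columns but ", length(channels),
         " channel labels")
  }
  if (anyDuplicated(channels)) {
    stop("recording: duplicate channel labels: ",
         paste(unique(channels[duplicated(channels)]), collapse = ", "))
  }
  colnames(data) <- channels
  structure(
    list(data = data, fs = fs, channels = channels,
         subject_id = subject_id, condition = condition),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "<recording> %d samples x %d channels @ %g Hz (%.2f s)%s, condition: %s\n",
    nrow(x$data), ncol(x$data), x$fs, nrow(x$data) / x$fs,
    if (is.na(x$subject_id)) "" else paste0(", subject ", x$subject_id),
    x$condition))
  invisible(x)
}

#' Read a continuous recording from CSV
#'
#' Reads a numeric CSV (one sample per row, one channel per column, optional
#' header row of channel labels) into a [recording()]. Values are read as-is;
#' no preprocessing is applied. Non-numeric cells and channel-count
#' mismatches raise descriptive errors naming the offending row or column.
#' EDF files are not supported by this build; convert to CSV first.
#'
#' @param path Path to a CSV file.
#' @param fs Sampling rate in Hz.
#' @param channels Optional channel labels. Required when the file has no
#'   header; when given together with a header, order and names must match
#'   the header.
#' @inheritParams recording
#' @return A [recording()].
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, fs, channels = NULL,
                           subject_id = NA_character_,
                           condition = "unlabeled") {
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    stop("read_recording: EDF input is not supported; export the recording ",
         "to numeric CSV (samples x channels) and re-run")
  }
  if (!file.exists(path)) stop("read_recording: file not found: ", path)
  first <- readLines(path, n = 1)
  if (length(first) == 0) stop("read_recording: empty file: ", path)
  toks <- strsplit(first, ",", fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(toks))))
  df <- suppressWarnings(readr::read_csv(
    path,
    col_names = if (has_header) TRUE else FALSE,
    col_types = readr::cols(.default = readr::col_double()),
    progress = FALSE, show_col_types = FALSE
  ))
  pr <- readr::problems(df)
  if (nrow(pr) > 0) {
    p1 <- pr[1, ]
    stop(sprintf(
      "read_recording: non-numeric cell at data row %d, column %d of %s (expected %s, got '%s')",
      p1$row, p1$col, path, p1$expected, p1$actual))
  }
  mat <- as.matrix(df)
  file_channels <- if (has_header) colnames(df) else NULL
  if (!is.null(channels)) {
    if (length(channels) != ncol(mat)) {
      stop(sprintf(
        "read_recording: %s has %d columns but %d channel labels were given",
        path, ncol(mat), length(channels)))
    }
    if (has_header && !identical(file_channels, as.character(channels))) {
      stop("read_recording: header of ", path, " (",
           paste(file_channels, collapse = ", "),
           ") does not match requested channels (",
           paste(channels, collapse = ", "), ")")
    }
  } else {
    channels <- if (has_header) file_channels else
      paste0("ch", seq_len(ncol(mat)))
  }
  recording(mat, fs = fs, channels = channels, subject_id = subject_id,
            condition = condition)
}

#' Write a recording to CSV
#'
#' One sample per row, one channel per column, header row of channel labels.
#' Full double precision is retained, so [read_recording()] round-trips the
#' data.
#'
#' @param rec A [recording()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  df <- tibble::as_tibble(rec$data)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Remove the DC offset of every channel
#'
#' Subtracts each channel's arithmetic mean, leaving zero-mean signals.
#' Idempotent; shape unchanged. Accepts a [recording()], a matrix (columns =
#' channels) or a plain numeric vector.
#'
#' @param rec Recording, matrix, or numeric vector.
#' @return Same type as the input.
#' @export
remove_dc <- function(rec) {
  if (inherits(rec, "recording")) {
    rec$data <- sweep(rec$data, 2, colMeans(rec$data))
    return(rec)
  }
  if (is.matrix(rec)) return(sweep(rec, 2, colMeans(rec)))
  rec - mean(rec)
}

#' Zero-phase band-pass filter
#'
#' Band-limits every channel to `[lo, hi]` Hz with no group delay: an
#' order-4 Butterworth high-pass at `lo` cascaded with an order-8 Butterworth
#' low-pass at `hi`, each applied forward and backward
#' ([signal::filtfilt()]). The cascade (rather than a single band-pass
#' design) keeps the filter numerically stable at the very low normalized
#' drift edge typical of EEG (0.5 Hz at 128 Hz sampling) while attenuating
#' DC completely and frequencies beyond ~1.2x the upper edge by more than
#' 20 dB.
#'
#' @param rec A [recording()], matrix, or numeric vector. Matrices/vectors
#'   require `fs`.
#' @param lo,hi Band edges in Hz, `0 < lo < hi < fs/2`.
#' @param fs Sampling rate, only needed when `rec` is not a recording.
#' @return Same type as the input, filtered.
#' @export
bandpass_filter <- function(rec, lo = 0.5, hi = 45, fs = NULL) {
  if (inherits(rec, "recording")) {
    fs <- rec$fs
    rec$data <- apply(rec$data, 2, bandpass_channel, lo = lo, hi = hi,
                      fs = fs)
    colnames(rec$data) <- rec$channels
    return(rec)
  }
  if (is.null(fs)) stop("bandpass_filter: fs is required for non-recording input")
  if (is.matrix(rec)) return(apply(rec, 2, bandpass_channel, lo = lo,
                                   hi = hi, fs = fs))
  bandpass_channel(rec, lo, hi, fs)
}

bandpass_channel <- function(x, lo, hi, fs) {
  nyq <- fs / 2
  if (!(lo > 0 && lo < hi)) stop("bandpass_filter: need 0 < lo < hi")
  if (hi >= nyq) {
    stop(sprintf(
      "bandpass_filter: upper edge %g Hz is at or above the Nyquist frequency %g Hz",
      hi, nyq))
  }
  hp <- signal::butter(4, lo / nyq, type = "high")
  lp <- signal::butter(8, hi / nyq, type = "low")
  x <- signal::filtfilt(hp, x)
  signal::filtfilt(lp, x)
}

#' Epoched trial set
#'
#' Container for epoched, labeled trials: a 3-D array
#' `[n_trials x n_channels x n_samples_per_trial]`, a binary label vector
#' (lie = 1, truth = 0), sampling rate and channel labels.
#'
#' @param trials 3-D numeric array `[trial, channel, sample]`.
#' @param labels Integer/numeric vector of 0/1 labels, one per trial.
#' @param fs Sampling rate in Hz.
#' @param channels Channel labels matching `dim(trials)[2]`.
#' @param subject_id Optional subject identifier.
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(trials, labels, fs, channels,
                      subject_id = NA_character_) {
  stopifnot(is.array(trials), length(dim(trials)) == 3)
  labels <- as.integer(labels)
  if (length(labels) != dim(trials)[1]) {
    stop("trial_set: ", dim(trials)[1], " trials but ", length(labels),
         " labels")
  }
  if (!all(labels %in% c(0L, 1L))) {
    stop("trial_set: labels must be 0 (truth) or 1 (lie)")
  }
  channels <- as.character(channels)
  if (length(channels) != dim(trials)[2]) {
    stop("trial_set: ", dim(trials)[2], " channel slices but ",
         length(channels), " labels")
  }
  dimnames(trials) <- list(NULL, channels, NULL)
  structure(
    list(trials = trials, labels = labels, fs = fs, channels = channels,
         subject_id = subject_id),
    class = "trial_set"
  )
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$trials)
  cat(sprintf(
    "<trial_set> %d trials x %d channels x %d samples @ %g Hz%s (lie: %d, truth: %d)\n",
    d[1], d[2], d[3], x$fs,
    if (is.na(x$subject_id)) "" else paste0(", subject ", x$subject_id),
    sum(x$labels == 1), sum(x$labels == 0)))
  invisible(x)
}

#' Epoch a continuous recording into labeled trials
#'
#' Cuts the recording into consecutive non-overlapping windows of
#' `trial_seconds` each: trial `t` (0-based) covers samples
#' `[t*w, (t+1)*w)` with `w = round(trial_seconds * fs)`. When `labels` is
#' given its length fixes the number of trials and the recording must be at
#' least that long; without labels as many full trials as fit are taken. Any
#' trailing remainder is discarded with a warning. `trial_crop = c(a, b)`
#' optionally keeps only the `[a, b)` second sub-window of every trial (e.g.
#' `c(1, 3)` to drop a 1-s prompt).
#'
#' @param rec A [recording()].
#' @param trial_seconds Trial duration in seconds.
#' @param labels Optional 0/1 labels, one per trial.
#' @param trial_crop Optional `c(start_s, end_s)` crop within each trial.
#' @return A [trial_set()]. Labels default to the recording's condition
#'   (lie = 1, truth = 0, unlabeled = 0) when not given.
#' @examples
#' rec <- recording(matrix(rnorm(128 * 75), ncol = 1), 128, "PZ")
#' epoch_trials(rec, 3)  # 25 trials of 384 samples
#' @export
epoch_trials <- function(rec, trial_seconds, labels = NULL,
                         trial_crop = NULL) {
  stopifnot(inherits(rec, "recording"))
  w <- round(trial_seconds * rec$fs)
  stopifnot(w >= 1)
  n_samples <- nrow(rec$data)
  n_fit <- floor(n_samples / w)
  if (is.null(labels)) {
    n_trials <- n_fit
    if (n_trials < 1) {
      stop(sprintf(
        "epoch_trials: %d samples available but %d required for one %g-s trial",
        n_samples, w, trial_seconds))
    }
    labels <- rep(if (identical(rec$condition, "lie")) 1L else 0L, n_trials)
  } else {
    n_trials <- length(labels)
    if (n_fit < n_trials) {
      stop(sprintf(
        "epoch_trials: %d samples available but %d required for %d trials of %g s",
        n_samples, n_trials * w, n_trials, trial_seconds))
    }
  }
  used <- n_trials * w
  if (used < n_samples) {
    warning(sprintf(
      "epoch_trials: discarding trailing %.2f s (%d samples) that do not fill a trial",
      (n_samples - used) / rec$fs, n_samples - used))
  }
  keep <- seq_len(w)
  if (!is.null(trial_crop)) {
    stopifnot(length(trial_crop) == 2, trial_crop[1] >= 0,
              trial_crop[2] > trial_crop[1], trial_crop[2] <= trial_seconds)
    keep <- (round(trial_crop[1] * rec$fs) + 1):round(trial_crop[2] * rec$fs)
  }
  n_ch <- ncol(rec$data)
  trials <- array(0, dim = c(n_trials, n_ch, length(keep)))
  for (t in seq_len(n_trials)) {
    block <- rec$data[((t - 1) * w + 1):(t * w), , drop = FALSE]
    trials[t, , ] <- t(block[keep, , drop = FALSE])
  }
  trial_set(trials, labels, rec$fs, rec$channels, rec$subject_id)
}

#' Combine trial sets of one subject
#'
#' Concatenates trial sets (e.g. the lie-condition and truth-condition
#' epochs of one subject) along the trial axis. Sampling rates and channel
#' sets must agree.
#'
#' @param ... `trial_set` objects, or a single list of them.
#' @return A [trial_set()].
#' @export
bind_trial_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "trial_set")) {
    sets <- sets[[1]]
  }
  stopifnot(length(sets) >= 1, all(vapply(sets, inherits, TRUE, "trial_set")))
  ref <- sets[[1]]
  for (s in sets[-1]) {
    stopifnot(identical(s$fs, ref$fs), identical(s$channels, ref$channels),
              identical(dim(s$trials)[3], dim(ref$trials)[3]))
  }
  n_tot <- sum(vapply(sets, function(s) dim(s$trials)[1], integer(1)))
  out <- array(0, dim = c(n_tot, dim(ref$trials)[2], dim(ref$trials)[3]))
  labels <- integer(0)
  at <- 0
  for (s in sets) {
    nt <- dim(s$trials)[1]
    out[at + seq_len(nt), , ] <- s$trials
    labels <- c(labels, s$labels)
    at <- at + nt
  }
  trial_set(out, labels, ref$fs, ref$channels, ref$subject_id)
}
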