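# Independent straight-line reference implementations used as oracles.
# Deliberately naive (explicit loops, no shared code with the package
# internals beyond, where stated, the wavelet transform object).

# fuzzy entropy exactly as defined: embed, Chebyshev distances over all
# ordered pairs, exponential membership, phi at m and m+1, log difference
naive_phi <- function(x, m, r, n) {
  N <- length(x)
  W <- N - m + 1
  total <- 0
  for (i in seq_len(W)) {
    inner <- 0
    for (j in seq_len(W)) {
      if (j == i) next
      d <- 0
      for (t in 0:(m - 1)) {
        dt <- abs(x[i + t] - x[j + t])
        if (dt > d) d <- dt
      }
      inner <- inner + exp(-(d^n) / r)
    }
    total <- total + inner / (W - 1)
  }
  total / W
}

naive_fe <- function(x, m = 2, n = 2, r_coef = 0.15, r_abs = NULL) {
  # relative tolerance in sd units: effective absolute tolerance r_coef*sd^n
  r <- if (is.null(r_abs)) r_coef * sd(x)^n else r_abs
  log(naive_phi(x, m, r, n)) - log(naive_phi(x, m + 1, r, n))
}

naive_tsmfe <- function(x, k_max = 10, m = 2, n = 2, r_coef = 0.15) {
  N <- length(x)
  out <- numeric(k_max)
  for (k in seq_len(k_max)) {
    fes <- numeric(k)
    for (j in seq_len(k)) {
      sub <- x[seq(j, N, by = k)]
      fes[j] <- if (length(sub) < m + 2 || sd(sub) < 1e-12) 0 else
        naive_fe(sub, m, n, r_coef)
    }
    out[k] <- mean(fes)
  }
  out
}

# HMFE wiring recombined independently: single-band reconstructions, then
# naive FE per band with the adaptive absolute tolerance r * sd_b / sd_x
naive_hmfe <- function(x, wavelet = "db4", level = 4, m = 2, n = 2,
                       r_coef = 0.15) {
  dw <- dwt_decompose(x, wavelet, level)
  bands <- c(paste0("A", level), paste0("D", level:1))
  sd_x <- sd(x)
  r <- r_coef * sd_x^n
  vapply(bands, function(b) {
    xb <- reconstruct_band(dw, b)
    ratio <- sd(xb) / sd_x
    if (ratio < 1e-8) return(0)
    naive_fe(xb, m, n, r_abs = r * ratio)
  }, numeric(1))
}

# scalar-arithmetic periodized analysis step, cross-checks the vectorized one
naive_dwt_step <- function(x, h) {
  N <- length(x)
  g <- rev(h) * (-1)^(seq_along(h) - 1)
  half <- N / 2
  a <- numeric(half)
  d <- numeric(half)
  for (k in seq_len(half)) {
    for (t in seq_along(h)) {
      idx <- ((2 * (k - 1) + t - 1) %% N) + 1
      a[k] <- a[k] + h[t] * x[idx]
      d[k] <- d[k] + g[t] * x[idx]
    }
  }
  list(a = a, d = d)
}

# FFT amplitude at a single frequency (signal length a multiple of 1/f0*fs)
fft_amplitude <- function(x, f0, fs) {
  N <- length(x)
  bin <- round(f0 * N / fs) + 1
  2 * Mod(fft(x))[bin] / N
}

# small separable two-class feature cloud for classifier tests
make_blobs <- function(n_per_class, p = 4, sep = 6, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * p), ncol = p),
             matrix(rnorm(n_per_class * p, mean = sep), ncol = p))
  y <- rep(c(0L, 1L), each = n_per_class)
  idx <- sample(nrow(X))
  list(X = X[idx, ], y = y[idx])
}

# feature-matrix tibble from a bare matrix, for CV structure tests
fm_from_matrix <- function(X, y, subject_id = "S1") {
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  out <- tibble::as_tibble(X)
  out <- tibble::add_column(out, subject_id = subject_id,
                            trial = seq_len(nrow(X)), label = as.integer(y),
                            .before = 1)
  structure(out, class = c("feature_matrix", class(tibble::tibble())),
            feature_names = colnames(X))
}
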