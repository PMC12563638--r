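#' Fuzzy entropy estimator configuration
#'
#' Bundles the parameters of the fuzzy entropy (FE) estimator: the embedding
#' dimension `m` (length of the sliding pattern vectors), the fuzzy factor `n`
#' (exponent of the membership decay), and the tolerance. The tolerance is
#' either relative (`r_coef`, scaled by the standard deviation of the series
#' being measured) or an absolute override `r_abs`; exactly one of the two
#' governs any given call.
#'
#' The relative rule measures pattern distances in units of the series'
#' standard deviation: the effective absolute tolerance is
#' `r_coef * sd(x)^n`, which is identical to evaluating the membership
#' function on the unit-variance series with tolerance `r_coef`. This makes
#' the estimator independent of amplitude scale and recording units
#' (microvolts vs millivolts), which is the point of tying the tolerance to
#' the signal's own dispersion.
#'
#' Defaults (`m = 2`, `n = 2`, `r_coef = 0.15`) are the values commonly used
#' for EEG complexity analysis.
#'
#' @param m Embedding dimension, positive integer.
#' @param n Fuzzy factor, positive real; the membership function is
#'   `exp(-d^n / r)`.
#' @param r_coef Tolerance coefficient, positive real, multiplied by the
#'   standard deviation of the series.
#' @param r_abs Optional absolute tolerance, positive real. When set it takes
#'   precedence over `r_coef`.
#' @return An object of class `fe_config`.
#' @examples
#' fe_config()
#' fe_config(m = 3, r_coef = 0.2)
#' @export
fe_config <- function(m = 2, n = 2, r_coef = 0.15, r_abs = NULL) {
  stopifnot(is.numeric(m), length(m) == 1, m >= 1, m == round(m))
  stopifnot(is.numeric(n), length(n) == 1, n > 0)
  stopifnot(is.numeric(r_coef), length(r_coef) == 1, r_coef > 0)
  if (!is.null(r_abs)) {
    stopifnot(is.numeric(r_abs), length(r_abs) == 1, r_abs > 0)
  }
  structure(
    list(m = as.integer(m), n = n, r_coef = r_coef, r_abs = r_abs),
    class = "fe_config"
  )
}

#' @export
print.fe_config <- function(x, ...) {
  tol <- if (is.null(x$r_abs)) {
    sprintf("r = %g * sd(x)", x$r_coef)
  } else {
    sprintf("r = %g (absolute)", x$r_abs)
  }
  cat(sprintf("<fe_config> m = %d, n = %g, %s\n", x$m, x$n, tol))
  invisible(x)
}

# condition signalled when a series cannot support both phi^m and phi^(m+1);
# consumed by the TSMFE zero-fallback
short_series_error <- function(N, m) {
  stop(structure(
    class = c("msentropy_short_series", "error", "condition"),
    list(
      message = sprintf(
        "series too short: length %d, but length >= m + 2 = %d is required",
        N, m + 2
      ),
      call = NULL
    )
  ))
}

#' Overlapping embedded pattern vectors
#'
#' Builds the `N - m + 1` overlapping `m`-dimensional windows
#' `(x[i], ..., x[i + m - 1])` used by the fuzzy entropy estimator. No local
#' baseline is removed: windows are raw slices of the series (set
#' `baseline_removal = TRUE` to subtract each window's mean, the convention of
#' some older fuzzy-entropy variants).
#'
#' @param x Numeric series of length `N >= m + 2`.
#' @param m Embedding dimension.
#' @param baseline_removal Subtract each window's own mean? Default `FALSE`.
#' @return Numeric matrix with `N - m + 1` rows and `m` columns.
#' @examples
#' embed_vectors(c(1, 2, 3, 4), m = 2)
#' @export
embed_vectors <- function(x, m, baseline_removal = FALSE) {
  x <- as.numeric(x)
  N <- length(x)
  if (N < m + 2) short_series_error(N, m)
  W <- N - m + 1
  out <- vapply(seq_len(m), function(t) x[t:(t + W - 1)], numeric(W))
  if (W == 1) out <- matrix(out, nrow = 1)
  if (baseline_removal) out <- out - rowMeans(out)
  out
}

#' Chebyshev distance between two pattern vectors
#'
#' Maximum absolute coordinate-wise difference, the worst-case dissimilarity
#' at any position of the two windows.
#'
#' @param u,v Numeric vectors of equal length.
#' @return Non-negative scalar.
#' @examples
#' chebyshev_distance(c(1, 5), c(2, 2)) # 3
#' @export
chebyshev_distance <- function(u, v) {
  if (length(u) != length(v)) {
    stop("chebyshev_distance: vectors have lengths ", length(u), " and ",
         length(v))
  }
  max(abs(u - v))
}

#' Exponential fuzzy membership function
#'
#' Maps a pattern distance to a similarity degree in (0, 1] via
#' `exp(-d^n / r)`: 1 at zero distance, smoothly decaying with distance,
#' increasing in the tolerance `r`.
#'
#' @param d Non-negative distance(s); vectorized.
#' @param r Tolerance, positive.
#' @param n Fuzzy factor, positive.
#' @return Membership value(s) in (0, 1].
#' @examples
#' fe_membership(0, r = 0.2, n = 2)      # 1
#' fe_membership(sqrt(0.2), r = 0.2, n = 2) # exp(-1)
#' @export
fe_membership <- function(d, r, n = 2) {
  if (!is.numeric(r) || length(r) != 1 || r <= 0) {
    stop("fe_membership: tolerance r must be a single positive number")
  }
  exp(-(d^n) / r)
}

#' Mean pattern-match degree phi
#'
#' Average membership over all ordered pairs of distinct embedded vectors at
#' dimension `m`: the outer mean runs over the `N - m + 1` windows, the inner
#' mean over the other `N - m` windows.
#'
#' @inheritParams embed_vectors
#' @param r Absolute tolerance, positive.
#' @param n Fuzzy factor.
#' @return Scalar in (0, 1].
#' @examples
#' fe_phi(c(1, 2, 1, 2, 1, 2), m = 2, r = 0.5)
#' @export
fe_phi <- function(x, m, r, n = 2) {
  x <- as.numeric(x)
  N <- length(x)
  if (N < m + 2) short_series_error(N, m)
  if (!is.numeric(r) || length(r) != 1 || r <= 0) {
    stop("fe_phi: tolerance r must be a single positive number")
  }
  .fe_phi_pair(x, as.integer(m), r, n)[1]
}

#' Fuzzy entropy of a univariate series
#'
#' Computes `FE = ln(phi_m) - ln(phi_m1)`, the log-drop in mean pattern
#' similarity when the embedding dimension grows from `m` to `m + 1`.
#' Similarity between windows is `exp(-d^n / r)` with `d` the Chebyshev
#' distance. A complex, irregular series loses pattern similarity quickly as
#' the window grows and scores a high FE; a regular series scores low.
#'
#' The effective tolerance is `cfg$r_abs` when set, otherwise
#' `cfg$r_coef * sd(x)^n` — the relative rule measures distances in units of
#' the series' own standard deviation (see [fe_config()]), making FE exactly
#' invariant under amplitude scaling and translation. A degenerate series
#' (`sd(x) < 1e-12` with no absolute tolerance) returns `fe = 0` with
#' `degenerate = TRUE` rather than an undefined value.
#'
#' @param x Numeric series of length at least `m + 2`.
#' @param cfg An [fe_config()].
#' @return An object of class `fuzzy_entropy`: a list with elements `fe`
#'   (nats), `phi_m`, `phi_m1`, `n_vectors_m`, `r` (the tolerance actually
#'   used), `degenerate`, and the parameters `m`, `n`.
#' @examples
#' set.seed(1)
#' fuzzy_entropy(rnorm(100))
#' fuzzy_entropy(sin(2 * pi * 10 * (0:383) / 128))
#' @export
fuzzy_entropy <- function(x, cfg = fe_config()) {
  stopifnot(inherits(cfg, "fe_config"))
  x <- as.numeric(x)
  N <- length(x)
  if (N < cfg$m + 2) short_series_error(N, cfg$m)
  if (any(!is.finite(x))) stop("fuzzy_entropy: series contains non-finite values")
  if (is.null(cfg$r_abs)) {
    s <- sd(x)
    if (s < 1e-12) {
      return(new_fuzzy_entropy(0, NA_real_, NA_real_, N - cfg$m + 1, NA_real_,
                               TRUE, cfg))
    }
    r <- cfg$r_coef * s^cfg$n
  } else {
    r <- cfg$r_abs
  }
  ph <- .fe_phi_pair(x, cfg$m, r, cfg$n)
  fe <- log(ph[1]) - log(ph[2])
  # guard against pathological floating-point sign flips near zero
  if (abs(fe) < 1e-14) fe <- 0
  new_fuzzy_entropy(fe, ph[1], ph[2], N - cfg$m + 1, r, FALSE, cfg)
}

new_fuzzy_entropy <- function(fe, phi_m, phi_m1, n_vectors_m, r, degenerate,
                              cfg) {
  structure(
    list(fe = fe, phi_m = phi_m, phi_m1 = phi_m1, n_vectors_m = n_vectors_m,
         r = r, degenerate = degenerate, m = cfg$m, n = cfg$n),
    class = "fuzzy_entropy"
  )
}

#' @export
print.fuzzy_entropy <- function(x, ...) {
  cat(sprintf("<fuzzy_entropy> FE = %.6f nats (m = %d, n = %g, r = %s)%s\n",
              x$fe, x$m, x$n,
              if (is.na(x$r)) "NA" else sprintf("%.4g", x$r),
              if (x$degenerate) " [degenerate series]" else ""))
  invisible(x)
}

#' @export
as.double.fuzzy_entropy <- function(x, ...) x$fe

#' @rdname fuzzy_entropy
#' @param x An object returned by [fuzzy_entropy()].
#' @param ... Unused.
#' @export
tidy.fuzzy_entropy <- function(x, ...) {
  tibble::tibble(
    fe = x$fe, phi_m = x$phi_m, phi_m1 = x$phi_m1,
    n_vectors_m = x$n_vectors_m, r = x$r, m = x$m, n = x$n,
    degenerate = x$degenerate
  )
}
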