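#' Time-shifted subsequences at a scale
#'
#' Splits a series into `k` interleaved subsequences: subsequence `j`
#' (`j = 1..k`) starts at the `j`-th sample and takes every `k`-th sample
#' thereafter, so its length is `floor((N - j) / k) + 1`. The index sets of
#' the `k` subsequences are pairwise disjoint and jointly cover `1..N` — no
#' sample is averaged away, unlike coarse-graining.
#'
#' @param x Numeric series of length `N`.
#' @param k Scale, integer in `1..N`.
#' @return List of `k` numeric vectors.
#' @examples
#' time_shift_subsequences(1:10, 3)
#' @export
time_shift_subsequences <- function(x, k) {
  x <- as.numeric(x)
  N <- length(x)
  stopifnot(is.numeric(k), length(k) == 1, k == round(k), k >= 1)
  if (k > N) stop("time_shift_subsequences: scale k = ", k,
                  " exceeds series length N = ", N)
  lapply(seq_len(k), function(j) x[seq(j, N, by = k)])
}

#' Time-shifted multi-scale fuzzy entropy (TSMFE)
#'
#' For every scale `k = 1..k_max` the series is split into its `k`
#' time-shifted subsequences ([time_shift_subsequences()]), fuzzy entropy is
#' computed on each, and the scale value is the mean of the `k` per-subsequence
#' FE values. A subsequence that is too short for FE (length `< m + 2`), is
#' degenerate, or whose FE computation fails contributes 0 to the mean, so a
#' handful of unusable subsequences at coarse scales cannot distort the scale
#' average. Scale 1 has a single subsequence — the series itself — so
#' `values[1]` equals plain [fuzzy_entropy()].
#'
#' By default the tolerance is resolved per subsequence
#' (`r_coef * sd(subsequence)`); set `tolerance_scope = "series"` to fix
#' the tolerance from the whole series' standard deviation instead (useful for
#' sensitivity analyses).
#'
#' @param x Numeric series of length at least `m + 2`.
#' @param k_max Maximum scale, positive integer (default 10).
#' @param cfg An [fe_config()].
#' @param tolerance_scope `"subsequence"` (default) or `"series"`.
#' @return An object of class `tsmfe`: list with `values` (numeric of length
#'   `k_max`), `per_scale` (tibble of per-subsequence FE values, lengths and
#'   degeneracy flags), `k_max`, and the configuration used.
#' @examples
#' set.seed(1)
#' ts <- tsmfe(rnorm(384))
#' ts$values
#' @export
tsmfe <- function(x, k_max = 10, cfg = fe_config(),
                  tolerance_scope = c("subsequence", "series")) {
  stopifnot(inherits(cfg, "fe_config"))
  tolerance_scope <- match.arg(tolerance_scope)
  stopifnot(is.numeric(k_max), length(k_max) == 1, k_max >= 1,
            k_max == round(k_max))
  x <- as.numeric(x)
  N <- length(x)
  if (N < cfg$m + 2) short_series_error(N, cfg$m)

  sub_cfg <- cfg
  if (tolerance_scope == "series" && is.null(cfg$r_abs)) {
    s <- sd(x)
    sub_cfg <- if (s < 1e-12) cfg else
      fe_config(cfg$m, cfg$n, cfg$r_coef, r_abs = cfg$r_coef * s^cfg$n)
  }

  rows <- vector("list", k_max)
  values <- numeric(k_max)
  for (k in seq_len(k_max)) {
    subs <- time_shift_subsequences(x, min(k, N))
    fe_k <- numeric(k)
    deg_k <- logical(k)
    len_k <- integer(k)
    for (j in seq_len(k)) {
      s_j <- if (j <= length(subs)) subs[[j]] else numeric(0)
      len_k[j] <- length(s_j)
      if (length(s_j) < cfg$m + 2) {
        fe_k[j] <- 0
        deg_k[j] <- TRUE
      } else {
        res <- tryCatch(fuzzy_entropy(s_j, sub_cfg), error = function(e) NULL)
        if (is.null(res) || !is.finite(res$fe)) {
          fe_k[j] <- 0
          deg_k[j] <- TRUE
        } else {
          fe_k[j] <- res$fe
          deg_k[j] <- res$degenerate
        }
      }
    }
    values[k] <- mean(fe_k)
    rows[[k]] <- tibble::tibble(scale = k, shift = seq_len(k),
                                length = len_k, fe = fe_k,
                                degenerate = deg_k)
  }
  structure(
    list(values = values, per_scale = dplyr::bind_rows(rows), k_max = k_max,
         cfg = cfg, tolerance_scope = tolerance_scope),
    class = "tsmfe"
  )
}

#' @export
print.tsmfe <- function(x, ...) {
  cat(sprintf("<tsmfe> %d scales (m = %d, n = %g, r_coef = %g, %s tolerance)\n",
              x$k_max, x$cfg$m, x$cfg$n, x$cfg$r_coef, x$tolerance_scope))
  print(round(x$values, 4))
  invisible(x)
}

#' @rdname tsmfe
#' @param x A `tsmfe` object.
#' @param ... Unused.
#' @export
tidy.tsmfe <- function(x, ...) {
  tibble::tibble(scale = seq_len(x$k_max), tsmfe = x$values)
}

#' @rdname tsmfe
#' @param object A `tsmfe` object.
#' @export
autoplot.tsmfe <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$scale, y = .data$tsmfe)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "scale k", y = "TSMFE (nats)",
                  title = "Time-shifted multi-scale fuzzy entropy") +
    ggplot2::theme_minimal()
}
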