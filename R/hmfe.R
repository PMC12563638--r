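#' Hierarchical multi-band fuzzy entropy (HMFE)
#'
#' Decomposes the series into `level + 1` wavelet bands
#' ([dwt_decompose()]), reconstructs each band alone in the time domain
#' ([reconstruct_band()]), and computes fuzzy entropy per band with a
#' band-adaptive tolerance: the base tolerance (the relative rule of
#' [fe_config()] resolved on the full signal, or `r_abs` when set) is
#' rescaled by `sd(band) / sd(x)` before each band's FE call, and passed as
#' an *absolute* tolerance. This keeps the membership function equally
#' sensitive in low- and high-energy bands — without it a quiet band would
#' be measured against a tolerance sized for the full signal — while the
#' whole vector stays invariant under amplitude scaling. A near-silent band
#' (`sd(band)/sd(x) < 1e-8`) yields `FE = 0` with a degeneracy flag instead
#' of an exploding estimate.
#'
#' Output order follows the decomposition: approximation first, then details
#' from coarsest to finest (`A_L, D_L, ..., D_1`).
#'
#' @param x Numeric series; length must be divisible by `2^level`.
#' @param wavelet,level Passed to [dwt_decompose()]; defaults `"db4"`, 4.
#' @param cfg An [fe_config()].
#' @return An object of class `hmfe`: list with `values` (named numeric of
#'   length `level + 1`), `band_sd`, `signal_sd`, `adaptive_r`, `degenerate`
#'   flags, `wavelet`, `level`.
#' @examples
#' set.seed(1)
#' h <- hmfe(rnorm(384))
#' h$values
#' @export
hmfe <- function(x, wavelet = "db4", level = 4, cfg = fe_config()) {
  stopifnot(inherits(cfg, "fe_config"))
  x <- as.numeric(x)
  N <- length(x)
  if (N < cfg$m + 2) short_series_error(N, cfg$m)
  dw <- dwt_decompose(x, wavelet = wavelet, level = level)
  bands <- reconstruct_all(dw)
  band_names <- colnames(bands)

  signal_sd <- sd(x)
  band_sd <- apply(bands, 2, sd)
  values <- numeric(level + 1)
  names(values) <- band_names
  degenerate <- logical(level + 1)
  names(degenerate) <- band_names
  adaptive_r <- rep(NA_real_, level + 1)
  names(adaptive_r) <- band_names

  if (signal_sd < 1e-12) {
    degenerate[] <- TRUE
  } else {
    r_base <- if (is.null(cfg$r_abs)) cfg$r_coef * signal_sd^cfg$n else
      cfg$r_abs
    for (b in seq_along(band_names)) {
      ratio <- band_sd[b] / signal_sd
      if (!is.finite(ratio) || ratio < 1e-8) {
        degenerate[b] <- TRUE
        next
      }
      adaptive_r[b] <- r_base * ratio
      band_cfg <- fe_config(cfg$m, cfg$n, cfg$r_coef,
                            r_abs = adaptive_r[b])
      res <- tryCatch(fuzzy_entropy(bands[, b], band_cfg),
                      error = function(e) NULL)
      if (is.null(res) || !is.finite(res$fe)) {
        degenerate[b] <- TRUE
        values[b] <- 0
      } else {
        values[b] <- res$fe
      }
    }
  }
  structure(
    list(values = values, band_sd = band_sd, signal_sd = signal_sd,
         adaptive_r = adaptive_r, degenerate = degenerate,
         wavelet = wavelet, level = level, cfg = cfg),
    class = "hmfe"
  )
}

#' @export
print.hmfe <- function(x, ...) {
  cat(sprintf("<hmfe> %s, level %d (m = %d, n = %g, r_coef = %g)\n",
              x$wavelet, x$level, x$cfg$m, x$cfg$n, x$cfg$r_coef))
  print(round(x$values, 4))
  invisible(x)
}

#' @rdname hmfe
#' @param x An `hmfe` object.
#' @param ... Unused.
#' @export
tidy.hmfe <- function(x, ...) {
  tibble::tibble(
    band = names(x$values), fe = unname(x$values),
    band_sd = unname(x$band_sd), adaptive_r = unname(x$adaptive_r),
    degenerate = unname(x$degenerate)
  )
}

#' @rdname hmfe
#' @param object An `hmfe` object.
#' @export
autoplot.hmfe <- function(object, ...) {
  td <- tidy(object)
  td$band <- factor(td$band, levels = td$band)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$band, y = .data$fe)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "wavelet band", y = "FE (nats)",
                  title = "Hierarchical multi-band fuzzy entropy") +
    ggplot2::theme_minimal()
}
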