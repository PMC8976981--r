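#' Multi-b-value diffusion-weighted series
#'
#' A stack of co-registered 3-D volumes, one per diffusion weighting
#' (b-value). Under the mono-exponential model the expected signal is
#' \deqn{S(b) = S_0 e^{-b\,\mathrm{ADC}}}{S(b) = S0 exp(-b ADC)}
#' with b in s/mm^2 and ADC in mm^2/s.
#'
#' @param b_values numeric vector of b-values (s/mm^2), at least two distinct.
#' @param volumes list of 3-D arrays, one per b-value, identical shapes.
#' @param spacing voxel spacing in mm.
#' @return An object of class `dwi_series`.
#' @export
dwi_series <- function(b_values, volumes, spacing = c(1, 1, 1)) {
  assert_that(is.numeric(b_values) && all(b_values >= 0),
              "b-values must be non-negative")
  assert_that(length(unique(b_values)) >= 2L,
              "at least 2 distinct b-values are required to constrain the fit")
  assert_that(length(volumes) == length(b_values),
              "need one volume per b-value")
  d <- dim(volumes[[1]])
  assert_that(length(d) == 3L, "volumes must be 3-D arrays")
  for (v in volumes) {
    assert_that(identical(dim(v), d), "all volumes must share one shape")
  }
  structure(list(b_values = as.numeric(b_values), volumes = volumes,
                 spacing = as.numeric(spacing)),
            class = "dwi_series")
}

#' @export
print.dwi_series <- function(x, ...) {
  d <- dim(x$volumes[[1]])
  cat(sprintf("dwi_series: b = [%s] s/mm^2, grid %dx%dx%d\n",
              paste(x$b_values, collapse = ", "), d[1], d[2], d[3]))
  invisible(x)
}

#' Pixelwise mono-exponential ADC fit
#'
#' Fits `log S = log S0 - b * ADC` per voxel by ordinary least squares in the
#' log domain, the standard closed-form approach for series with 2-4
#' b-values. Voxels where any signal is at or below `min_signal` are excluded
#' from the valid mask (the log is undefined there) and get ADC = 0, S0 = 0.
#'
#' The log-domain fit is unweighted; at low SNR this downweights high-b
#' volumes less than a noise-aware fit would, which is documented as a
#' limitation.
#'
#' @param series a [dwi_series].
#' @param min_signal exclusion threshold in image units (default `1e-6`).
#' @return An object of class `adc_fit` with elements `adc_map` (mm^2/s),
#'   `s0_map`, `valid_mask` and `spacing`.
#' @examples
#' b <- c(0, 400, 800)
#' S <- lapply(b, function(bb) array(1000 * exp(-bb * 1e-3), c(4, 4, 4)))
#' fit <- fit_adc(dwi_series(b, S))
#' fit$adc_map[1]   # 0.001
#' @export
fit_adc <- function(series, min_signal = 1e-6) {
  assert_that(inherits(series, "dwi_series"), "series must be a dwi_series")
  assert_that(is.numeric(min_signal) && min_signal >= 0,
              "min_signal must be >= 0")
  b <- series$b_values
  d <- dim(series$volumes[[1]])
  nvox <- prod(d)
  S <- vapply(series$volumes, as.numeric, numeric(nvox))  # nvox x nb
  valid <- rowSums(S <= min_signal) == 0L
  adc <- numeric(nvox)
  s0 <- numeric(nvox)
  if (any(valid)) {
    y <- log(S[valid, , drop = FALSE])
    bc <- b - mean(b)
    slope <- as.numeric(y %*% bc) / sum(bc^2)
    intercept <- rowMeans(y) - slope * mean(b)
    adc[valid] <- -slope
    s0[valid] <- exp(intercept)
  } else {
    warning("no voxel exceeded min_signal at every b-value; valid mask is empty",
            call. = FALSE)
  }
  structure(list(adc_map = array(adc, d), s0_map = array(s0, d),
                 valid_mask = array(valid, d), spacing = series$spacing),
            class = "adc_fit")
}

#' @export
print.adc_fit <- function(x, ...) {
  cat(sprintf("adc_fit: %d/%d voxels valid, median ADC %.3g mm^2/s\n",
              sum(x$valid_mask), length(x$valid_mask),
              stats::median(x$adc_map[x$valid_mask])))
  invisible(x)
}

#' Synthesize a high-b-value diffusion image
#'
#' Extrapolates the mono-exponential model to an unacquired diffusion
#' weighting: `S0 * exp(-b_target * ADC)` on the valid mask, 0 elsewhere.
#' b = 1400 s/mm^2 is the conventional target for prostate imaging and the
#' default here.
#'
#' @param fit an [adc_fit].
#' @param b_target target b-value in s/mm^2 (default 1400).
#' @return 3-D array of synthesized signal.
#' @export
synthesize_high_b <- function(fit, b_target = 1400) {
  assert_that(inherits(fit, "adc_fit"), "fit must be an adc_fit")
  assert_that(is.numeric(b_target) && length(b_target) == 1L && b_target >= 0,
              "b_target must be a single non-negative number")
  out <- fit$s0_map * exp(-b_target * fit$adc_map)
  out[!fit$valid_mask] <- 0
  out
}
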