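# Per-band TFR features (peak frequency, peak latency, peak amplitude,
# average relative power) inside an analysis window, and min-max
# normalization across participants.

.band_freqs <- list(beta = c(15, 29), NBG = c(30, 100), BBG = c(100, 250))

#' Define a band-limited analysis window
#'
#' Frequency bounds default to the band definition (beta 15-29 Hz, NBG
#' 30-100 Hz, BBG 100-250 Hz; the 100 Hz boundary bin belongs to NBG).
#' The time window defaults to the 10-500 ms poststimulus analysis window
#' (the first 10 ms are excluded because of the stimulus-artifact
#' interpolation); narrower presets such as 10-190 ms can be set explicitly.
#'
#' @param band `"beta"`, `"NBG"` or `"BBG"`.
#' @param t_lo,t_hi Time window in ms (default 10-500; `t_lo` >= 10).
#' @param f_lo,f_hi Optional frequency bounds overriding the band defaults.
#' @return An object of class `band_window`.
#' @export
band_window <- function(band = c("beta", "NBG", "BBG"), t_lo = 10, t_hi = 500,
                        f_lo = NULL, f_hi = NULL) {
  band <- match.arg(band)
  fb <- .band_freqs[[band]]
  if (is.null(f_lo)) f_lo <- fb[1]
  if (is.null(f_hi)) f_hi <- fb[2]
  if (f_lo >= f_hi) stop_arg("`f_lo` must be below `f_hi`")
  if (t_lo < 10) stop_arg("`t_lo` must be >= 10 ms (interpolated onset excluded)")
  if (t_lo >= t_hi) stop_arg("`t_lo` must be below `t_hi`")
  structure(list(band = band, f_lo = f_lo, f_hi = f_hi,
                 t_lo = t_lo, t_hi = t_hi), class = "band_window")
}

#' Extract band-limited TFR features
#'
#' Within the window x band rectangle (valid pixels only), locates the pixel
#' with the largest relative power change. Peak frequency and latency are
#' that pixel's coordinates, peak amplitude its RPC value, and the average
#' power is the mean RPC over the rectangle. The 100 Hz bin is excluded from
#' BBG (it belongs to NBG). Ties are broken by earliest latency, then lowest
#' frequency.
#'
#' @param map A baseline-corrected `tfr_map` (values in RPC percent).
#' @param window A [band_window()].
#' @return One-row data.frame: `band`, `peak_frequency`, `peak_latency`,
#'   `peak_amplitude`, `avg_power`, `missing` (TRUE when no valid pixel
#'   exists in the rectangle).
#' @export
extract_band_features <- function(map, window) {
  stopifnot(inherits(map, "tfr_map"), inherits(window, "band_window"))
  f_lo <- window$f_lo
  if (window$band == "BBG" && f_lo <= 100) f_lo <- 100 + 1e-9
  fsel <- which(map$frequencies >= f_lo & map$frequencies <= window$f_hi)
  tsel <- which(map$times >= window$t_lo & map$times <= window$t_hi)
  miss <- data.frame(band = window$band, peak_frequency = NA_real_,
                     peak_latency = NA_real_, peak_amplitude = NA_real_,
                     avg_power = NA_real_, missing = TRUE)
  if (!length(fsel) || !length(tsel)) return(miss)
  vals <- map$values[fsel, tsel, drop = FALSE]
  ok <- map$valid[fsel, tsel, drop = FALSE]
  if (!any(ok)) return(miss)
  vals[!ok] <- NA_real_
  m <- max(vals, na.rm = TRUE)
  hits <- which(vals == m, arr.ind = TRUE)
  lat <- map$times[tsel][hits[, 2L]]
  frq <- map$frequencies[fsel][hits[, 1L]]
  j <- order(lat, frq)[1L]
  data.frame(band = window$band, peak_frequency = frq[j], peak_latency = lat[j],
             peak_amplitude = m, avg_power = mean(vals, na.rm = TRUE),
             missing = FALSE)
}

#' Min-max normalize a feature across participants
#'
#' `(x - min(x)) / (max(x) - min(x))`: the minimum maps to 0, the maximum to
#' 1, order is preserved. Degenerate inputs (all values equal) are an error
#' because the denominator vanishes; callers may skip such features.
#'
#' @param values Numeric vector (>= 2 distinct values).
#' @return Normalized vector in `[0, 1]`.
#' @export
minmax_normalize <- function(values) {
  if (!is.numeric(values) || length(values) < 2)
    stop_arg("`values` must be a numeric vector of length >= 2")
  rng <- range(values, na.rm = TRUE)
  if (rng[1] == rng[2])
    stop_arg("all values are equal: min-max normalization is undefined")
  (values - rng[1]) / (rng[2] - rng[1])
}
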