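# Component detection on trial-averaged waveforms: envelopes through local
# extrema, 3-SD-above-prestimulus peak picking inside named latency windows,
# and overlapping-window group comparison of averaged waveforms.

#' Component latency windows for a modality
#'
#' MEG-like recordings use the visual evoked field components M100 (40-100
#' ms), M150 (100-150 ms], M250 (150-250 ms] and M500 (250-500 ms];
#' EEG-like recordings use the N1/P1/N2/P3 peaks over the same latency
#' ranges. Windows are half-open on the left (except the first) so each
#' latency belongs to exactly one component. The polarity column encodes the
#' expected deflection direction (alternating, starting negative for N1).
#'
#' @param modality `"MEG-like"` or `"EEG-like"`.
#' @return data.frame with columns `component`, `lo`, `hi`, `polarity`.
#' @export
component_windows <- function(modality = c("MEG-like", "EEG-like")) {
  modality <- match.arg(modality)
  nm <- if (modality == "MEG-like") c("M100", "M150", "M250", "M500")
        else c("N1", "P1", "N2", "P3")
  data.frame(component = nm,
             lo = c(40, 100, 150, 250), hi = c(100, 150, 250, 500),
             polarity = if (modality == "MEG-like") c(1, -1, 1, -1)
                        else c(-1, 1, -1, 1))
}

#' Average trials into an evoked waveform
#'
#' @param recording An [epoched_recording()] with at least one trial.
#' @return List of class `evoked_waveform` with `waveform`, `times`, `fs`,
#'   `interp_mask` (propagated from the recording).
#' @export
average_evoked <- function(recording) {
  stopifnot(inherits(recording, "epoched_recording"))
  if (nrow(recording$data) < 1) stop_arg("recording has no trials")
  structure(list(waveform = colMeans(recording$data), times = recording$times,
                 fs = recording$fs, interp_mask = recording$interp_mask),
            class = "evoked_waveform")
}

# interior local extrema indices; plateaus collapse to their first sample
.local_extrema <- function(x, kind = c("max", "min")) {
  kind <- match.arg(kind)
  if (kind == "min") x <- -x
  n <- length(x)
  idx <- integer()
  i <- 2L
  while (i < n) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L
      if (j < n && x[j + 1L] < x[j]) idx <- c(idx, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  idx
}

#' Upper and lower envelopes of a waveform
#'
#' The upper envelope is the cubic spline through the interior local maxima
#' (plus the endpoints); the lower envelope passes through the local minima.
#' A monotone waveform has no interior extrema: both envelopes then fall back
#' to the straight line joining the endpoints and the result is flagged.
#'
#' @param waveform Numeric vector (length >= 3) or an `evoked_waveform`.
#' @return List with `upper`, `lower` (same length as the waveform) and
#'   `fallback` (logical).
#' @export
compute_envelopes <- function(waveform) {
  x <- if (inherits(waveform, "evoked_waveform")) waveform$waveform else as.numeric(waveform)
  n <- length(x)
  if (n < 3) stop_arg("waveform must have length >= 3")
  env_through <- function(idx) {
    knots <- unique(sort(c(1L, idx, n)))
    if (length(knots) < 3) return(NULL)
    stats::spline(knots, x[knots], xout = seq_len(n), method = "natural")$y
  }
  up <- env_through(.local_extrema(x, "max"))
  lo <- env_through(.local_extrema(x, "min"))
  fallback <- is.null(up) || is.null(lo)
  if (fallback) {
    line <- seq(x[1], x[n], length.out = n)
    if (is.null(up)) up <- line
    if (is.null(lo)) lo <- line
  }
  list(upper = up, lower = lo, fallback = fallback)
}

#' Detect evoked components in named latency windows
#'
#' Inside each component window, the extremum of the expected polarity is
#' located (on the matching envelope by default, or on the raw averaged
#' waveform) and accepted when its magnitude reaches the detection threshold:
#' the mean prestimulus magnitude plus `k` standard deviations of the
#' prestimulus waveform (inclusive, i.e. an amplitude of exactly the
#' threshold counts as detected). Interpolated samples are excluded from both
#' the prestimulus statistics and the search. Ties are broken by larger
#' magnitude, then earlier latency.
#'
#' @param waveform An `evoked_waveform` from [average_evoked()], or a numeric
#'   vector (then `times` must be given).
#' @param windows data.frame as returned by [component_windows()].
#' @param times Time axis in ms (taken from the `evoked_waveform` if absent).
#' @param prestim Prestimulus window in ms (default `c(-200, 0)`).
#' @param k Threshold multiplier on the prestimulus SD (default 3).
#' @param on `"envelope"` (default) or `"waveform"`: signal used for peak
#'   height.
#' @return data.frame with one row per component: `component`, `latency_ms`,
#'   `amplitude` (signed), `polarity`, `found`.
#' @export
detect_components <- function(waveform, windows = component_windows(),
                              times = NULL, prestim = c(-200, 0), k = 3,
                              on = c("envelope", "waveform")) {
  on <- match.arg(on)
  mask <- NULL
  if (inherits(waveform, "evoked_waveform")) {
    times <- waveform$times
    mask <- waveform$interp_mask
    waveform <- waveform$waveform
  }
  if (is.null(times)) stop_arg("`times` required for plain waveforms")
  if (is.null(mask)) mask <- rep(FALSE, length(waveform))
  if (max(windows$hi) > max(times) || min(windows$lo) < min(times))
    stop_arg("component windows must lie inside the epoch")
  pres <- which(times >= prestim[1] & times <= prestim[2] & !mask)
  if (length(pres) < 2) stop_arg("prestimulus window has no usable samples")
  thr <- mean(abs(waveform[pres])) + k * stats::sd(waveform[pres])
  env <- if (on == "envelope") compute_envelopes(waveform) else NULL
  out <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    left_closed <- i == 1L
    sel <- which((if (left_closed) times >= w$lo else times > w$lo) &
                 times <= w$hi & !mask)
    res <- data.frame(component = w$component, latency_ms = NA_real_,
                      amplitude = NA_real_, polarity = w$polarity,
                      found = FALSE)
    if (!length(sel)) return(res)
    sig <- if (on == "envelope") {
      if (w$polarity > 0) env$upper[sel] else env$lower[sel]
    } else waveform[sel]
    val <- w$polarity * sig                      # oriented so peaks are maxima
    j <- which(val == max(val))
    j <- j[which.min(times[sel][j])]             # earliest among tied maxima
    res$latency_ms <- times[sel][j]
    res$amplitude <- sig[j]
    res$found <- val[j] >= thr && val[j] > 0   # a flat zero waveform has no peak
    res
  })
  do.call(rbind, out)
}

#' Compare group-averaged waveforms in overlapping windows
#'
#' Splits the poststimulus axis into `window_len` ms windows with the given
#' overlap (25 ms / 50 percent by default, i.e. a 12.5 ms step: 39 windows
#' on 0-500 ms), computes each subject's mean amplitude per window, tests
#' group differences with the Wilcoxon rank-sum test and applies
#' Benjamini-Hochberg FDR across windows. Windows containing only
#' interpolated samples are excluded.
#'
#' @param group_a,group_b Subject x sample matrices of averaged waveforms.
#' @param times Time axis in ms shared by both matrices.
#' @param window_len Window length in ms (default 25).
#' @param overlap Fractional overlap between consecutive windows (default
#'   0.5).
#' @param t_max Last window may not extend beyond this latency (default 500).
#' @param alpha FDR level (default 0.05).
#' @param interp_mask Optional logical vector of samples to exclude.
#' @return data.frame with `t_lo`, `t_hi`, `statistic`, `p`, `p_adj`,
#'   `significant`.
#' @export
windowed_group_compare <- function(group_a, group_b, times, window_len = 25,
                                   overlap = 0.5, t_max = 500, alpha = 0.05,
                                   interp_mask = NULL) {
  group_a <- as.matrix(group_a); group_b <- as.matrix(group_b)
  if (nrow(group_a) < 2 || nrow(group_b) < 2)
    stop_arg("need >= 2 subjects per group")
  if (is.null(interp_mask)) interp_mask <- rep(FALSE, length(times))
  step <- window_len * (1 - overlap)
  starts <- seq(0, t_max - window_len, by = step)
  rows <- lapply(starts, function(s) {
    sel <- which(times >= s & times < s + window_len & !interp_mask)
    if (!length(sel)) return(NULL)
    ma <- rowMeans(group_a[, sel, drop = FALSE])
    mb <- rowMeans(group_b[, sel, drop = FALSE])
    rs <- ranksum(ma, mb)
    data.frame(t_lo = s, t_hi = s + window_len,
               statistic = rs$statistic, p = rs$p)
  })
  res <- do.call(rbind, rows)
  adj <- fdr_bh(res$p, q = alpha)
  res$p_adj <- adj$p_adjusted
  res$significant <- adj$rejected
  res
}
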