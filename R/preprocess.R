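# Waveform-level preprocessing: Butterworth band-pass + notch filtering,
# epoching of continuous records, stimulus-artifact interpolation, and
# outlier-run exclusion.

#' Specify the band-pass / notch filter
#'
#' The analysis uses a fourth-order IIR Butterworth band-pass in one of two
#' ranges — `"low"` (1-100 Hz) or `"high"` (100-250 Hz) — together with a
#' 60 Hz notch and its harmonics (120, 180, 240 Hz). The default application
#' mode is zero-phase (forward-backward) so that component-peak latencies are
#' not biased by filter delay; a single-pass mode is available.
#'
#' @param band `"low"`, `"high"`, or a numeric length-2 vector of band edges
#'   in Hz.
#' @param order Overall band-pass filter order (default 4).
#' @param notch Notch center frequencies in Hz (default 60 Hz and harmonics);
#'   `NULL` or empty disables the notch.
#' @param mode `"zero-phase"` (default) or `"single-pass"`.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(band = "low", order = 4,
                        notch = c(60, 120, 180, 240),
                        mode = c("zero-phase", "single-pass")) {
  if (is.character(band))
    band <- switch(match.arg(band, c("low", "high")),
                   low = c(1, 100), high = c(100, 250))
  if (length(band) != 2 || band[1] <= 0 || band[1] >= band[2])
    stop_arg("`band` edges must be positive with low < high")
  if (order %% 2 != 0) stop_arg("`order` must be even")
  structure(list(band = band, order = order, notch = notch,
                 mode = match.arg(mode)), class = "filter_spec")
}

# reflection-padded application of a signal::Arma filter to one trial
.apply_filt <- function(filt, x, zero_phase) {
  n <- length(x)
  pad <- min(n - 1L, 500L)
  xp <- c(2 * x[1] - rev(x[2:(pad + 1L)]), x, 2 * x[n] - rev(x[(n - pad):(n - 1L)]))
  y <- if (zero_phase) signal::filtfilt(filt, xp)
       else as.numeric(signal::filter(filt, xp))
  y[(pad + 1L):(pad + n)]
}

#' Band-pass and notch filter an epoched recording
#'
#' Removes the DC offset per trial, applies the Butterworth band-pass and
#' then each configured notch (second-order band-stop of half-width 2 Hz per
#' harmonic, skipping harmonics outside the pass band). Trials are filtered
#' independently with reflection padding to suppress edge transients. Output
#' has the same shape as the input.
#'
#' @param recording An [epoched_recording()] or a plain numeric waveform.
#' @param spec A [filter_spec()].
#' @param fs Sampling rate in Hz (taken from the recording if available).
#' @return Filtered object of the same type as `recording`.
#' @export
bandpass_notch <- function(recording, spec = filter_spec(), fs = NULL) {
  stopifnot(inherits(spec, "filter_spec"))
  is_rec <- inherits(recording, "epoched_recording")
  if (is_rec) fs <- recording$fs
  if (is.null(fs)) stop_arg("`fs` required for plain waveforms")
  nyq <- fs / 2
  if (spec$band[2] >= nyq) stop_arg("band edge must be below the Nyquist frequency")
  zp <- spec$mode == "zero-phase"
  bp <- signal::butter(spec$order / 2, spec$band / nyq, type = "pass")
  notches <- lapply(Filter(function(f) f > spec$band[1] && f < min(spec$band[2], nyq - 2),
                           spec$notch),
                    function(f) signal::butter(2, c(f - 2, f + 2) / nyq, type = "stop"))
  run <- function(x) {
    x <- x - mean(x)
    y <- .apply_filt(bp, x, zp)
    for (nf in notches) y <- .apply_filt(nf, y, zp)
    y
  }
  if (!is_rec) return(run(as.numeric(recording)))
  recording$data <- t(apply(recording$data, 1L, run))
  recording
}

#' Epoch a continuous waveform around stimulus events
#'
#' Cuts fixed windows `[t_start, t_end]` ms around each event, inclusive of
#' both endpoints (701 samples at 1 kHz for the default -200 to 500 ms
#' window). Events whose window would exceed the record bounds are dropped
#' with a warning.
#'
#' @param waveform Numeric continuous record.
#' @param events_ms Event (stimulus onset) times in ms from record start.
#' @param fs Sampling rate in Hz.
#' @param t_start,t_end Epoch bounds in ms relative to each event.
#' @param ... Passed to [epoched_recording()] (subject_id, group, modality).
#' @return An [epoched_recording()].
#' @export
epoch <- function(waveform, events_ms, fs = 1000, t_start = -200, t_end = 500, ...) {
  if (t_start >= t_end) stop_arg("`t_start` must be below `t_end`")
  step <- 1000 / fs
  rel <- seq(t_start, t_end, by = step)
  n <- length(waveform)
  trials <- list()
  dropped <- 0L
  for (ev in events_ms) {
    idx <- round((ev + rel) * fs / 1000) + 1L
    if (idx[1] < 1L || idx[length(idx)] > n) {
      dropped <- dropped + 1L
      next
    }
    trials[[length(trials) + 1L]] <- waveform[idx]
  }
  if (dropped > 0L)
    warning(sprintf("%d event(s) dropped: epoch window outside record bounds", dropped))
  if (!length(trials)) stop_arg("no valid trials after epoching")
  epoched_recording(do.call(rbind, trials), fs = fs, times = rel, ...)
}

#' Interpolate the stimulus artifact around onset
#'
#' Replaces samples strictly inside `(t_lo, t_hi)` ms by the straight line
#' joining the sample values at `t_lo` and `t_hi`, trial by trial. The
#' endpoints are untouched. Interpolated samples are flagged in
#' `$interp_mask` so downstream statistics can exclude them.
#'
#' @param recording An [epoched_recording()].
#' @param t_lo,t_hi Artifact window bounds in ms (defaults -10 and +10).
#' @return The recording with interpolated data and an updated mask.
#' @export
interpolate_stimulus_artifact <- function(recording, t_lo = -10, t_hi = 10) {
  stopifnot(inherits(recording, "epoched_recording"))
  if (t_lo >= t_hi) stop_arg("`t_lo` must be below `t_hi`")
  times <- recording$times
  if (t_lo < min(times) || t_hi > max(times))
    stop_arg("artifact window must lie inside the epoch")
  i_lo <- time_index(times, t_lo)
  i_hi <- time_index(times, t_hi)
  inner <- which(times > times[i_lo] & times < times[i_hi])
  if (length(inner)) {
    w <- (times[inner] - times[i_lo]) / (times[i_hi] - times[i_lo])
    for (tr in seq_len(nrow(recording$data))) {
      a <- recording$data[tr, i_lo]
      b <- recording$data[tr, i_hi]
      recording$data[tr, inner] <- a + w * (b - a)
    }
    recording$interp_mask[inner] <- TRUE
  }
  recording
}

#' Exclude runs whose response features deviate from a reference condition
#'
#' Feature spread is estimated from the reference condition's trial-level
#' feature vectors; a run is excluded when any of its features deviates by
#' more than `k` standard deviations from the reference mean (strictly more:
#' a run at exactly `k` SD is kept). Features with zero spread in the
#' reference are skipped with a warning rather than treated as infinite
#' z-scores.
#'
#' @param run_features Matrix/data.frame of per-run feature vectors (rows =
#'   runs).
#' @param reference_features Matrix/data.frame of trial-level feature vectors
#'   from the reference condition (>= 2 rows), same columns.
#' @param k Exclusion threshold in SD units (default 3).
#' @return List with `kept` and `excluded` run indices and a `log` data.frame
#'   naming each offending feature and its z-score.
#' @export
reject_outlier_runs <- function(run_features, reference_features, k = 3) {
  run_features <- as.matrix(run_features)
  reference_features <- as.matrix(reference_features)
  if (nrow(reference_features) < 2)
    stop_arg("need >= 2 reference trials to estimate spread")
  if (ncol(run_features) != ncol(reference_features))
    stop_arg("feature columns must match between runs and reference")
  mu <- colMeans(reference_features)
  sdv <- apply(reference_features, 2L, stats::sd)
  usable <- sdv > 0
  if (any(!usable))
    warning(sprintf("zero-spread feature(s) skipped: %s",
                    paste(colnames(reference_features)[!usable], collapse = ", ")))
  log_rows <- list()
  excluded <- integer()
  for (r in seq_len(nrow(run_features))) {
    z <- (run_features[r, usable] - mu[usable]) / sdv[usable]
    bad <- which(abs(z) > k)
    if (length(bad)) {
      excluded <- c(excluded, r)
      nms <- colnames(run_features)[usable][bad]
      if (is.null(nms)) nms <- as.character(which(usable)[bad])
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(run = r, feature = nms, z = as.numeric(z[bad]))
    }
  }
  list(kept = setdiff(seq_len(nrow(run_features)), excluded),
       excluded = excluded,
       log = if (length(log_rows)) do.call(rbind, log_rows) else
         data.frame(run = integer(), feature = character(), z = numeric()))
}
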