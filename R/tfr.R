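# Morlet wavelet time-frequency engine: raw power maps, 1/f spectral
# flattening, relative-power-change (RPC) baseline correction, evoked and
# induced decomposition modes, and the 2x-background oscillation criterion.
#
# Conventions: power is the squared magnitude of the complex wavelet
# coefficient; wavelets are unit-energy normalized so raw power is comparable
# across frequencies before flattening; amplitude (for the oscillation
# criterion) is sqrt(power). Samples closer to an epoch edge than half the
# wavelet support (3 envelope SDs) are flagged invalid.

#' Frequency grid for a named analysis range
#'
#' 1 Hz-step grids: `"low"` 1-30 Hz, `"mid"` 30-100 Hz, `"high"` 100-250 Hz,
#' `"full"` 1-100 Hz. 100 Hz appears in both the mid and high grids; band
#' feature extraction assigns it to narrowband gamma only.
#'
#' @param range Range name or numeric `c(lo, hi)` in Hz.
#' @return Integer frequency vector in Hz.
#' @export
band_grid <- function(range = "full") {
  if (is.numeric(range)) return(seq(range[1], range[2], by = 1))
  switch(match.arg(range, c("low", "mid", "high", "full")),
         low = 1:30, mid = 30:100, high = 100:250, full = 1:100)
}

new_tfr_map <- function(frequencies, times, values, valid, mode = "raw",
                        flattened = FALSE, baseline_corrected = FALSE,
                        n_trials = 1L, raw = NULL, baseline_power = NULL) {
  structure(list(frequencies = frequencies, times = times, values = values,
                 valid = valid, mode = mode, flattened = flattened,
                 baseline_corrected = baseline_corrected,
                 n_trials = as.integer(n_trials), raw = raw,
                 baseline_power = baseline_power),
            class = "tfr_map")
}

#' @export
print.tfr_map <- function(x, ...) {
  cat(sprintf("<tfr_map> %s: %d freqs (%g-%g Hz) x %d times (%g-%g ms)%s%s, n_trials=%d\n",
              x$mode, length(x$frequencies), min(x$frequencies), max(x$frequencies),
              length(x$times), min(x$times), max(x$times),
              if (x$flattened) ", flattened" else "",
              if (x$baseline_corrected) ", baseline-corrected (RPC %)" else "",
              x$n_trials))
  invisible(x)
}

# Batched Morlet decomposition of a trials x samples matrix.
# Hands the callback, per frequency, the n x n_trials complex coefficient
# matrix (fastest memory layout for per-trial baseline correction).
.morlet_apply <- function(data, fs, frequencies, n_cycles, fun) {
  n <- ncol(data)
  ntr <- nrow(data)
  dt <- 1 / fs
  sigma_t <- n_cycles / (2 * pi * frequencies)       # seconds
  half <- pmin(ceiling(3 * sigma_t * fs), 5L * n)    # samples (support cap)
  pad <- min(n - 1L, max(half))
  cols <- t(data)                                    # n x ntr
  padded <- rbind(cols[(pad + 1L):2L, , drop = FALSE], cols,
                  cols[(n - 1L):(n - pad), , drop = FALSE])
  np <- n + 2L * pad
  nfft <- stats::nextn(np + 2L * max(half) + 1L, 2)
  buf <- matrix(0, nfft, ntr)
  buf[seq_len(np), ] <- padded
  X <- stats::mvfft(buf)
  for (k in seq_along(frequencies)) {
    f <- frequencies[k]
    h <- half[k]
    tt <- (-h:h) * dt
    w <- exp(-tt^2 / (2 * sigma_t[k]^2)) * exp(2i * pi * f * tt)
    w <- w / sqrt(sum(Mod(w)^2))                     # unit energy
    wv <- complex(length.out = nfft)
    wv[1:(h + 1L)] <- w[(h + 1L):(2L * h + 1L)]
    wv[(nfft - h + 1L):nfft] <- w[1:h]
    C <- X * Conj(stats::fft(wv))
    co <- stats::mvfft(C, inverse = TRUE)[(pad + 1L):(pad + n), , drop = FALSE] / nfft
    fun(k, co, h)
  }
  invisible(NULL)
}

#' Morlet wavelet power map of a single waveform
#'
#' Complex Morlet wavelets (default five cycles) at the requested center
#' frequencies; power is the squared coefficient magnitude. The waveform is
#' reflection-padded; samples within half the wavelet support (3 envelope
#' SDs) of an epoch edge are flagged invalid in `$valid`. At low frequencies
#' the support can exceed the epoch, in which case the whole row is invalid.
#'
#' @param waveform Numeric vector or `evoked_waveform`.
#' @param frequencies Frequency grid in Hz (see [band_grid()]); all must be
#'   below the Nyquist frequency.
#' @param fs Sampling rate in Hz (taken from an `evoked_waveform`).
#' @param times Time axis in ms (taken from an `evoked_waveform`).
#' @param n_cycles Wavelet width in cycles (default 5).
#' @return A `tfr_map` of raw power.
#' @export
morlet_power <- function(waveform, frequencies, fs = NULL, times = NULL,
                         n_cycles = 5) {
  if (inherits(waveform, "evoked_waveform")) {
    fs <- waveform$fs; times <- waveform$times; waveform <- waveform$waveform
  }
  if (is.null(fs)) stop_arg("`fs` required")
  if (is.null(times)) times <- (seq_along(waveform) - 1L) * 1000 / fs
  if (max(frequencies) >= fs / 2)
    stop_arg("all frequencies must be below the Nyquist frequency")
  n <- length(waveform)
  vals <- matrix(NA_real_, length(frequencies), n)
  valid <- matrix(FALSE, length(frequencies), n)
  .morlet_apply(matrix(waveform, nrow = 1L), fs, frequencies, n_cycles,
                function(k, co, h) {
                  vals[k, ] <<- Mod(co[, 1L])^2
                  if (2L * h < n) valid[k, (h + 1L):(n - h)] <<- TRUE
                })
  new_tfr_map(frequencies, times, vals, valid)
}

#' Multiply each frequency bin by its frequency (1/f flattening)
#'
#' Counteracts 1/f power decay so low-frequency power does not mask gamma
#' responses: `values[f, t] <- f * values[f, t]`. Only defined for maps whose
#' frequencies lie within 1-100 Hz; the 100-250 Hz range is analyzed
#' unflattened because the correction overcompensates there. Refuses to
#' flatten twice.
#'
#' @param map A raw-power `tfr_map`.
#' @return The flattened map.
#' @export
spectral_flatten <- function(map) {
  stopifnot(inherits(map, "tfr_map"))
  if (map$flattened) stop_arg("map is already flattened")
  if (map$baseline_corrected)
    stop_arg("flattening applies to raw power, before baseline correction")
  if (max(map$frequencies) > 100)
    stop_arg("flattening is restricted to frequencies <= 100 Hz; the 100-250 Hz range stays unadjusted")
  map$values <- map$values * map$frequencies
  map$flattened <- TRUE
  map
}

# per-frequency baseline indices: valid baseline samples where >= min_n exist,
# otherwise the whole baseline window (edge-dominated low frequencies)
.baseline_index <- function(times, valid_row, baseline, min_n = 10L) {
  base <- which(times >= baseline[1] & times <= baseline[2])
  if (length(base) < min_n) stop_arg("baseline window too short")
  ok <- base[valid_row[base]]
  if (length(ok) >= min_n) ok else base
}

#' Baseline-correct a power map to relative power change (percent)
#'
#' `values[f, t] <- 100 * (values[f, t] - B_f) / B_f`, where `B_f` is the
#' mean baseline power at frequency `f` over the baseline window (edge-valid
#' samples when at least 10 exist at that frequency, otherwise the whole
#' window). The uncorrected power and the baseline vector are retained on the
#' returned map for the oscillation criterion.
#'
#' @param map A power `tfr_map` (raw or flattened).
#' @param baseline Baseline window in ms (default `c(-200, 0)`).
#' @return The baseline-corrected map (values in percent change).
#' @export
baseline_rpc <- function(map, baseline = c(-200, 0)) {
  stopifnot(inherits(map, "tfr_map"))
  if (map$baseline_corrected) stop_arg("map is already baseline-corrected")
  raw <- map$values
  B <- vapply(seq_along(map$frequencies), function(k) {
    idx <- .baseline_index(map$times, map$valid[k, ], baseline)
    mean(raw[k, idx])
  }, numeric(1))
  if (any(B == 0)) stop_arg("zero baseline power: cannot form relative change")
  map$values <- 100 * (raw - B) / B
  map$raw <- raw
  map$baseline_power <- B
  map$baseline_corrected <- TRUE
  map
}

#' Evoked time-frequency map of a recording
#'
#' Evoked (phase-locked) pipeline: the trials are averaged (equivalently,
#' the per-trial wavelet coefficients are averaged — the transform is
#' linear), the averaged coefficients are squared to power, spectrally
#' flattened (ranges fully within 1-100 Hz only) and expressed as relative
#' power change. The background `B_f` is the mean per-trial baseline power,
#' not the baseline power of the average: this keeps the evoked and induced
#' maps on a common background scale, so non-phase-locked activity (which
#' cancels in the average) yields near-zero evoked RPC instead of being
#' re-inflated by an equally cancelled baseline, and it stabilizes `B_f` by
#' pooling all trials.
#'
#' @param recording An [epoched_recording()].
#' @param range Frequency range (see [band_grid()]); default `"full"`
#'   (1-100 Hz).
#' @param n_cycles Wavelet cycles (default 5).
#' @param baseline Baseline window in ms.
#' @return A `tfr_map` with `mode = "evoked"`, values in RPC percent,
#'   `$raw` holding the power of the averaged signal.
#' @export
evoked_tfr <- function(recording, range = "full", n_cycles = 5,
                       baseline = c(-200, 0)) {
  stopifnot(inherits(recording, "epoched_recording"))
  freqs <- band_grid(range)
  fs <- recording$fs
  if (max(freqs) >= fs / 2)
    stop_arg("all frequencies must be below the Nyquist frequency")
  flatten <- max(freqs) <= 100
  times <- recording$times
  n <- length(times)
  vals <- matrix(NA_real_, length(freqs), n)
  raw <- matrix(NA_real_, length(freqs), n)
  valid <- matrix(FALSE, length(freqs), n)
  basepow <- numeric(length(freqs))
  .morlet_apply(recording$data, fs, freqs, n_cycles, function(k, co, h) {
    P <- Mod(rowMeans(co))^2                       # power of the average
    vrow <- rep(FALSE, n)
    if (2L * h < n) vrow[(h + 1L):(n - h)] <- TRUE
    idx <- .baseline_index(times, vrow, baseline)
    B <- mean(Mod(co[idx, , drop = FALSE])^2)      # trial-averaged background
    if (flatten) {
      P <- P * freqs[k]
      B <- B * freqs[k]
    }
    if (B == 0) stop_arg("zero baseline power: cannot form relative change")
    vals[k, ] <<- 100 * (P - B) / B
    raw[k, ] <<- P
    valid[k, ] <<- vrow
    basepow[k] <<- B
  })
  out <- new_tfr_map(freqs, times, vals, valid, mode = "evoked",
                     flattened = flatten, baseline_corrected = TRUE,
                     n_trials = nrow(recording$data), raw = raw,
                     baseline_power = basepow)
  out$band_range <- if (is.character(range)) range else paste(range, collapse = "-")
  out
}

#' Induced time-frequency map of a recording
#'
#' Induced (non-phase-locked) pipeline: Morlet-decompose every trial
#' separately, flatten per trial (`"low"` and `"mid"` ranges only),
#' baseline-correct each trial to relative power change, then average the
#' corrected maps. Phase-randomized activity that cancels in the trial
#' average survives this per-trial route.
#'
#' @param recording An [epoched_recording()] with at least 2 trials.
#' @param range `"low"` (1-30 Hz), `"mid"` (30-100 Hz) or `"high"`
#'   (100-250 Hz); numeric `c(lo, hi)` also accepted.
#' @param n_cycles Wavelet cycles (default 5).
#' @param baseline Baseline window in ms.
#' @return A `tfr_map` with `mode = "induced"`, values in RPC percent,
#'   `$raw` holding the trial-averaged (flattened) power.
#' @export
induced_tfr <- function(recording, range = "mid", n_cycles = 5,
                        baseline = c(-200, 0)) {
  stopifnot(inherits(recording, "epoched_recording"))
  if (nrow(recording$data) < 2) stop_arg("induced TFR needs >= 2 trials")
  freqs <- band_grid(range)
  fs <- recording$fs
  if (max(freqs) >= fs / 2)
    stop_arg("all frequencies must be below the Nyquist frequency")
  flatten <- max(freqs) <= 100
  times <- recording$times
  n <- length(times)
  ntr <- nrow(recording$data)
  vals <- matrix(NA_real_, length(freqs), n)
  raw <- matrix(NA_real_, length(freqs), n)
  valid <- matrix(FALSE, length(freqs), n)
  basepow <- numeric(length(freqs))
  .morlet_apply(recording$data, fs, freqs, n_cycles, function(k, co, h) {
    p <- Mod(co)^2
    if (flatten) p <- p * freqs[k]
    vrow <- rep(FALSE, n)
    if (2L * h < n) vrow[(h + 1L):(n - h)] <- TRUE
    idx <- .baseline_index(times, vrow, baseline)
    B <- colMeans(p[idx, , drop = FALSE])            # per-trial baseline power
    if (any(B == 0)) stop_arg("zero baseline power in a trial")
    rpc <- 100 * sweep(sweep(p, 2L, B, "-"), 2L, B, "/")
    vals[k, ] <<- rowMeans(rpc)
    raw[k, ] <<- rowMeans(p)
    valid[k, ] <<- vrow
    basepow[k] <<- mean(B)
  })
  out <- new_tfr_map(freqs, times, vals, valid, mode = "induced",
                     flattened = flatten, baseline_corrected = TRUE,
                     n_trials = ntr, raw = raw, baseline_power = basepow)
  out$band_range <- if (is.character(range)) range else paste(range, collapse = "-")
  out
}

#' Oscillation mask: amplitude at least a factor above background
#'
#' A time-frequency pixel counts as a genuine oscillation when its amplitude
#' (square root of uncorrected power) is at least `factor` times the
#' background amplitude at that frequency, the background being the mean
#' baseline-period amplitude. "At least" is inclusive. For baseline-corrected
#' maps the retained uncorrected power (`$raw`) is used.
#'
#' @param map A `tfr_map` (raw, or baseline-corrected with `$raw` retained).
#' @param factor Amplitude threshold multiplier (default 2).
#' @param baseline Baseline window in ms.
#' @return Logical frequencies x times matrix.
#' @export
oscillation_mask <- function(map, factor = 2, baseline = c(-200, 0)) {
  stopifnot(inherits(map, "tfr_map"))
  pow <- if (map$baseline_corrected) map$raw else map$values
  if (is.null(pow))
    stop_arg("no uncorrected power available for the amplitude comparison")
  amp <- sqrt(pow)
  bg <- vapply(seq_along(map$frequencies), function(k) {
    idx <- .baseline_index(map$times, map$valid[k, ], baseline)
    mean(amp[k, idx])
  }, numeric(1))
  amp >= factor * bg
}
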