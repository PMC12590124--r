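# Synthetic two-group cohorts of single virtual-sensor epochs: phase-locked
# evoked deflections + non-phase-locked induced bursts + 1/f background noise,
# with known ground-truth group effects for parameter-recovery tests.

# canonical component latency windows (ms), shared by MEG-like (M*) and
# EEG-like (N1/P1/N2/P3) naming; half-open on the left except the first
.component_windows <- list(
  M100 = c(40, 100), M150 = c(100, 150), M250 = c(150, 250), M500 = c(250, 500),
  N1   = c(40, 100), P1   = c(100, 150), N2   = c(150, 250), P3   = c(250, 500)
)

.band_bounds <- list(beta = c(15, 29), NBG = c(30, 100), BBG = c(100, 250))

#' Specify a phase-locked evoked component
#'
#' An evoked component is a Gaussian-envelope deflection that occurs at (very
#' nearly) the same latency on every trial, so it survives trial averaging.
#' Component names follow the visual evoked field/potential convention:
#' `M100`/`N1` (40-100 ms), `M150`/`P1` (100-150 ms), `M250`/`N2`
#' (150-250 ms), `M500`/`P3` (250-500 ms).
#'
#' @param name Component name (one of `M100`, `M150`, `M250`, `M500`, `N1`,
#'   `P1`, `N2`, `P3`).
#' @param center_latency Peak latency in ms after stimulus onset; must lie in
#'   the component's latency window.
#' @param width Gaussian temporal envelope SD in ms.
#' @param amplitude Peak amplitude (arbitrary units).
#' @param polarity `+1` or `-1`.
#' @param trial_jitter_sd SD (ms) of the per-trial latency jitter. Small by
#'   default (5 ms) so the component stays phase-locked.
#' @return An object of class `evoked_component_spec`.
#' @export
evoked_component <- function(name, center_latency, width, amplitude,
                             polarity = 1, trial_jitter_sd = 5) {
  name <- match.arg(name, names(.component_windows))
  win <- .component_windows[[name]]
  check_number(center_latency, "center_latency", win[1], win[2])
  check_number(width, "width", 0, strict_lower = TRUE)
  check_number(amplitude, "amplitude", 0)
  if (!polarity %in% c(-1, 1)) stop_arg("`polarity` must be +1 or -1")
  check_number(trial_jitter_sd, "trial_jitter_sd", 0)
  structure(list(name = name, center_latency = center_latency, width = width,
                 amplitude = amplitude, polarity = polarity,
                 trial_jitter_sd = trial_jitter_sd),
            class = "evoked_component_spec")
}

#' Specify a non-phase-locked induced burst
#'
#' An induced burst is a Gaussian-envelope sinusoid whose carrier phase is
#' drawn uniformly at random on every trial, so it cancels in the trial
#' average but survives per-trial spectral analysis. Bands: `beta` (15-29 Hz),
#' `NBG` narrowband gamma (30-100 Hz), `BBG` broadband gamma (100-250 Hz).
#'
#' @param band `"beta"`, `"NBG"` or `"BBG"`; constrains `center_frequency`.
#' @param center_frequency Carrier frequency in Hz.
#' @param center_latency Envelope peak latency in ms after stimulus onset.
#' @param duration Envelope full width at half maximum in ms.
#' @param amplitude Envelope peak amplitude (arbitrary units).
#' @param latency_jitter_sd SD (ms) of per-trial latency jitter.
#' @param bandwidth Optional nominal spectral bandwidth in Hz (informational;
#'   the effective bandwidth follows from `duration`).
#' @param phase_locked If `TRUE` the carrier phase is fixed at zero on every
#'   trial instead of drawn uniformly, producing a phase-locked burst for
#'   evoked/induced fidelity experiments (default `FALSE`).
#' @return An object of class `induced_burst_spec`.
#' @export
induced_burst <- function(band, center_frequency, center_latency, duration,
                          amplitude, latency_jitter_sd = 0, bandwidth = NULL,
                          phase_locked = FALSE) {
  band <- match.arg(band, names(.band_bounds))
  bb <- .band_bounds[[band]]
  check_number(center_frequency, "center_frequency", bb[1], bb[2])
  check_number(center_latency, "center_latency")
  check_number(duration, "duration", 0, strict_lower = TRUE)
  check_number(amplitude, "amplitude", 0)
  check_number(latency_jitter_sd, "latency_jitter_sd", 0)
  structure(list(band = band, center_frequency = center_frequency,
                 center_latency = center_latency, duration = duration,
                 amplitude = amplitude, latency_jitter_sd = latency_jitter_sd,
                 bandwidth = bandwidth, phase_locked = isTRUE(phase_locked)),
            class = "induced_burst_spec")
}

#' Configure a synthetic two-group cohort
#'
#' Bundles everything needed to generate a reproducible cohort: group sizes,
#' the epoch/sampling design, background-noise parameters, the evoked and
#' induced content, and the group effects applied to the patient group.
#'
#' @param n_control,n_patient Number of subjects per group.
#' @param n_trials Trials per subject (default 85, one per stimulus
#'   presentation).
#' @param fs Sampling rate in Hz (default 1000).
#' @param t_start,t_end Epoch bounds in ms relative to stimulus onset
#'   (defaults -200 and 500; both endpoints included, so 701 samples at
#'   1 kHz).
#' @param noise_exponent Spectral slope of the 1/f background
#'   (power ~ f^-exponent; default 1).
#' @param noise_scale SD of the background noise per trial (arbitrary units;
#'   0 disables noise).
#' @param components List of [evoked_component()] specs.
#' @param bursts List of [induced_burst()] specs.
#' @param group_effects Named list keyed by component name or burst band;
#'   each entry is a list with optional `amp_ratio` (multiplies the patient
#'   amplitude, must be >= 0) and `latency_shift` (ms added to the patient
#'   latency).
#' @param seed Integer master seed; per-subject seeds are derived from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_control, n_patient, n_trials = 85, fs = 1000,
                          t_start = -200, t_end = 500, noise_exponent = 1,
                          noise_scale = 1, components = list(),
                          bursts = list(), group_effects = list(), seed = 1) {
  check_number(n_control, "n_control", 1)
  check_number(n_patient, "n_patient", 1)
  check_number(n_trials, "n_trials", 1)
  check_number(fs, "fs", 0, strict_lower = TRUE)
  check_number(t_start, "t_start")
  check_number(t_end, "t_end", 0, strict_lower = TRUE)
  if (t_start >= 0) stop_arg("`t_start` must be negative (prestimulus)")
  check_number(noise_exponent, "noise_exponent", 0)
  check_number(noise_scale, "noise_scale", 0)
  stopifnot(all(vapply(components, inherits, TRUE, "evoked_component_spec")),
            all(vapply(bursts, inherits, TRUE, "induced_burst_spec")))
  for (b in bursts)
    if (fs <= 2 * b$center_frequency)
      stop_arg("`fs` must exceed twice the highest burst frequency")
  for (eff in group_effects) {
    if (!is.null(eff$amp_ratio)) check_number(eff$amp_ratio, "amp_ratio", 0)
    if (!is.null(eff$latency_shift)) check_number(eff$latency_shift, "latency_shift")
  }
  structure(list(n_control = as.integer(n_control),
                 n_patient = as.integer(n_patient),
                 n_trials = as.integer(n_trials), fs = fs,
                 t_start = t_start, t_end = t_end,
                 noise_exponent = noise_exponent, noise_scale = noise_scale,
                 components = components, bursts = bursts,
                 group_effects = group_effects, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Construct an epoched single-sensor recording
#'
#' @param data Numeric trials x samples matrix (arbitrary units).
#' @param fs Sampling rate in Hz.
#' @param times Time axis in ms, one value per column of `data`.
#' @param subject_id Subject identifier.
#' @param group `"control"` or `"patient"`.
#' @param modality `"MEG-like"` or `"EEG-like"` (waveform provenance tag).
#' @param truth Optional list of generator specs that produced the data.
#' @param interp_mask Optional logical vector marking interpolated samples.
#' @return An object of class `epoched_recording`.
#' @export
epoched_recording <- function(data, fs, times, subject_id = "s01",
                              group = c("control", "patient"),
                              modality = c("MEG-like", "EEG-like"),
                              truth = NULL, interp_mask = NULL) {
  group <- match.arg(group)
  modality <- match.arg(modality)
  data <- as.matrix(data)
  if (length(times) != ncol(data))
    stop_arg("`times` length must equal the number of samples")
  if (!all(is.finite(data))) stop_arg("`data` must be finite")
  if (is.null(interp_mask)) interp_mask <- rep(FALSE, ncol(data))
  structure(list(subject_id = subject_id, group = group, modality = modality,
                 fs = fs, times = as.numeric(times), data = data,
                 truth = truth, interp_mask = interp_mask),
            class = "epoched_recording")
}

#' @export
print.epoched_recording <- function(x, ...) {
  cat(sprintf("<epoched_recording> %s (%s, %s): %d trials x %d samples, %g-%g ms @ %g Hz\n",
              x$subject_id, x$group, x$modality, nrow(x$data), ncol(x$data),
              min(x$times), max(x$times), x$fs))
  invisible(x)
}

#' Generate 1/f ("pink"-family) background noise
#'
#' Synthesizes a zero-mean waveform whose expected power spectrum follows
#' f^(-exponent), by spectral shaping: Gaussian white Fourier coefficients
#' are scaled by f^(-exponent/2) and inverted to the time domain. The DC
#' coefficient is zeroed.
#'
#' @param n_samples Number of samples (> 1).
#' @param exponent Spectral slope (>= 0; 0 gives white noise).
#' @param scale Target standard deviation of the waveform (0 gives zeros).
#' @param fs Sampling rate in Hz (sets the physical frequency axis only).
#' @param seed Optional integer seed; the global RNG stream is untouched.
#' @return Numeric vector of length `n_samples`.
#' @export
generate_noise <- function(n_samples, exponent = 1, scale = 1, fs = 1000,
                           seed = NULL) {
  if (!is.numeric(n_samples) || n_samples <= 1)
    stop_arg("`n_samples` must exceed 1")
  check_number(exponent, "exponent", 0)
  check_number(scale, "scale", 0)
  n <- as.integer(n_samples)
  if (scale == 0) return(numeric(n))
  with_seed(seed, {
    freqs <- seq_len(n %/% 2) * fs / n            # positive frequencies
    amp <- freqs^(-exponent / 2)
    coef <- complex(real = stats::rnorm(length(freqs)),
                    imaginary = stats::rnorm(length(freqs))) * amp
    spec <- complex(length.out = n)
    spec[2:(length(freqs) + 1L)] <- coef
    if (n %% 2L == 0L)  # Nyquist bin must be real for a real signal
      spec[length(freqs) + 1L] <- complex(real = stats::rnorm(1) * amp[length(amp)])
    spec[n:(n - length(freqs) + if (n %% 2L == 0L) 2L else 1L)] <-
      Conj(spec[2:(length(freqs) + if (n %% 2L == 0L) 0L else 1L)])
    x <- Re(stats::fft(spec, inverse = TRUE)) / n
    x <- x - mean(x)
    s <- stats::sd(x)
    if (s > 0) x <- x * (scale / s)
    x
  })
}

# Gaussian-envelope deflection or burst evaluated on the epoch time axis (ms)
.gauss_env <- function(times, center, sd_ms) exp(-(times - center)^2 / (2 * sd_ms^2))

# apply group effects to a spec (patient group only)
.apply_effect <- function(spec, effects) {
  key <- if (inherits(spec, "evoked_component_spec")) spec$name else spec$band
  eff <- effects[[key]]
  if (is.null(eff)) return(spec)
  if (!is.null(eff$amp_ratio)) spec$amplitude <- spec$amplitude * eff$amp_ratio
  if (!is.null(eff$latency_shift))
    spec$center_latency <- spec$center_latency + eff$latency_shift
  spec
}

#' Generate one subject's epoched recording
#'
#' Each trial is the sum of the configured evoked components (fixed polarity
#' and latency up to a small phase-locked jitter), the induced bursts (a fresh
#' uniform-random carrier phase on every trial), and 1/f background noise.
#' For `group = "patient"` the configured `group_effects` are applied to the
#' component/burst specs first; the modified specs are retained in `$truth`.
#'
#' @param config A [cohort_config()].
#' @param group `"control"` or `"patient"`.
#' @param subject_seed Integer seed for this subject's randomness.
#' @param subject_id Identifier stored in the recording.
#' @param modality Modality tag.
#' @return An [epoched_recording()].
#' @export
generate_subject <- function(config, group = c("control", "patient"),
                             subject_seed = 1, subject_id = "s01",
                             modality = "MEG-like") {
  stopifnot(inherits(config, "cohort_config"))
  group <- match.arg(group)
  fs <- config$fs
  times <- seq(config$t_start, config$t_end, by = 1000 / fs)
  n <- length(times)
  comps <- config$components
  bursts <- config$bursts
  if (group == "patient") {
    comps <- lapply(comps, .apply_effect, effects = config$group_effects)
    bursts <- lapply(bursts, .apply_effect, effects = config$group_effects)
  }
  with_seed(subject_seed, {
    data <- matrix(0, nrow = config$n_trials, ncol = n)
    for (tr in seq_len(config$n_trials)) {
      x <- numeric(n)
      for (cm in comps) {
        jit <- if (cm$trial_jitter_sd > 0) stats::rnorm(1, 0, cm$trial_jitter_sd) else 0
        x <- x + cm$polarity * cm$amplitude *
          .gauss_env(times, cm$center_latency + jit, cm$width)
      }
      for (b in bursts) {
        jit <- if (b$latency_jitter_sd > 0) stats::rnorm(1, 0, b$latency_jitter_sd) else 0
        ctr <- b$center_latency + jit
        phase <- if (b$phase_locked) 0 else stats::runif(1, 0, 2 * pi)
        sd_ms <- b$duration / (2 * sqrt(2 * log(2)))  # FWHM -> SD
        x <- x + b$amplitude * .gauss_env(times, ctr, sd_ms) *
          cos(2 * pi * b$center_frequency * (times - ctr) / 1000 + phase)
      }
      if (config$noise_scale > 0)
        x <- x + generate_noise(n, config$noise_exponent, config$noise_scale, fs)
      data[tr, ] <- x
    }
    epoched_recording(data, fs, times, subject_id = subject_id, group = group,
                      modality = modality,
                      truth = list(components = comps, bursts = bursts))
  })
}

# deterministic per-subject seed from the master seed and subject index
.subject_seed <- function(master, index) {
  ((as.numeric(master) * 1000003 + index * 7919) %% 2147483629) + 1
}

#' Generate a full two-group cohort
#'
#' Produces `n_control + n_patient` recordings with deterministic per-subject
#' seeds derived from `config$seed`, plus a truth table recording every
#' effective (post group-effect) component and burst parameter.
#'
#' @param config A [cohort_config()].
#' @param modality Modality tag applied to all subjects.
#' @return A list with `recordings` (list of [epoched_recording()]) and
#'   `truth` (data.frame of effective generator parameters per subject).
#' @export
generate_cohort <- function(config, modality = "MEG-like") {
  stopifnot(inherits(config, "cohort_config"))
  groups <- c(rep("control", config$n_control), rep("patient", config$n_patient))
  ids <- sprintf("%s%02d", ifelse(groups == "control", "ctl", "pat"),
                 c(seq_len(config$n_control), seq_len(config$n_patient)))
  recs <- vector("list", length(ids))
  rows <- list()
  for (i in seq_along(ids)) {
    recs[[i]] <- generate_subject(config, groups[i], .subject_seed(config$seed, i),
                                  subject_id = ids[i], modality = modality)
    tr <- recs[[i]]$truth
    for (cm in tr$components)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = ids[i], group = groups[i], kind = "component",
        name = cm$name, amplitude = cm$amplitude,
        center_latency = cm$center_latency, frequency = NA_real_)
    for (b in tr$bursts)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = ids[i], group = groups[i], kind = "burst",
        name = b$band, amplitude = b$amplitude,
        center_latency = b$center_latency, frequency = b$center_frequency)
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(), group = character(), kind = character(),
               name = character(), amplitude = numeric(),
               center_latency = numeric(), frequency = numeric())
  list(recordings = recs, truth = truth)
}

#' Generate a continuous record with event times
#'
#' A minimal continuous-acquisition mode used to exercise epoching: ongoing
#' 1/f noise with the configured evoked components inserted at each stimulus
#' event. Inter-stimulus intervals are drawn uniformly from
#' `isi_ms[1] +/- isi_jitter_ms`.
#'
#' @param config A [cohort_config()] (its components, noise and fs are used).
#' @param n_events Number of stimulus events.
#' @param isi_ms Mean inter-stimulus interval in ms (default 4000).
#' @param isi_jitter_ms Half-range of the uniform ISI jitter (default 1000).
#' @param seed Optional seed.
#' @return List with `waveform`, `events_ms`, `fs`.
#' @export
generate_continuous <- function(config, n_events, isi_ms = 4000,
                                isi_jitter_ms = 1000, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(seed, {
    isis <- stats::runif(n_events, isi_ms - isi_jitter_ms, isi_ms + isi_jitter_ms)
    events <- cumsum(isis) + abs(config$t_start)
    total_ms <- events[n_events] + config$t_end + isi_ms
    n <- as.integer(round(total_ms * config$fs / 1000)) + 1L
    times <- (seq_len(n) - 1L) * 1000 / config$fs
    x <- if (config$noise_scale > 0)
      generate_noise(n, config$noise_exponent, config$noise_scale, config$fs)
    else numeric(n)
    for (ev in events)
      for (cm in config$components)
        x <- x + cm$polarity * cm$amplitude *
          .gauss_env(times, ev + cm$center_latency, cm$width)
    list(waveform = x, events_ms = events, fs = config$fs)
  })
}
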