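# Morlet decomposition, spectral flattening, RPC baseline correction,
# evoked/induced modes and the oscillation criterion.

fs <- 1000
times <- seq(-200, 500)

test_that("wavelet power localizes pure sinusoids on the frequency axis", {
  x <- sin(2 * pi * 40 * times / 1000)
  m <- morlet_power(x, 1:100, fs = fs, times = times)
  interior <- which(m$times >= 0 & m$times <= 300)
  peaks <- apply(m$values[, interior], 2L, which.max)
  expect_true(all(abs(m$frequencies[peaks] - 40) <= 1))
  # zero waveform: all-zero map
  z <- morlet_power(numeric(length(times)), 10:50, fs = fs, times = times)
  expect_true(all(z$values == 0))
  # two tones resolve into two ridges (flattening corrects the slight
  # downward argmax bias of unit-energy wavelets at high frequencies)
  x2 <- sin(2 * pi * 20 * times / 1000) + sin(2 * pi * 80 * times / 1000)
  m2 <- spectral_flatten(morlet_power(x2, 1:100, fs = fs, times = times))
  mid <- which(m2$times == 150)
  prof <- m2$values[, mid]
  expect_lte(abs(which.max(prof[1:50]) - 20), 1)
  expect_lte(abs(which.max(prof[51:100]) + 50 - 80), 1)
  expect_error(morlet_power(x, 1:600, fs = fs), "Nyquist")
})

test_that("sinusoid power concentrates near its frequency (FFT oracle)", {
  for (f0 in c(20, 80)) {
    x <- sin(2 * pi * f0 * times / 1000)
    m <- morlet_power(x, 1:100, fs = fs, times = times)
    mid <- which(m$times == 150)
    prof <- m$values[, mid]
    inband <- sum(prof[abs(m$frequencies - f0) <= 0.25 * f0])
    expect_gte(inband / sum(prof), 0.8)
    # periodogram oracle agrees on the peak location
    spec <- Mod(stats::fft(x))^2
    fax <- (seq_along(x) - 1) * fs / length(x)
    expect_lt(abs(fax[which.max(spec[fax <= 500])] - f0), 2)
    flat <- spectral_flatten(m)
    expect_lte(abs(flat$frequencies[which.max(flat$values[, mid])] - f0), 1)
  }
})

test_that("ridge temporal width scales as n_cycles over frequency", {
  fwhm_at <- function(f0) {
    imp <- numeric(length(times))
    imp[times == 150] <- 1
    m <- morlet_power(imp, f0, fs = fs, times = times)
    prof <- m$values[1, ]
    half <- max(prof) / 2
    diff(range(which(prof >= half)))
  }
  ratio <- fwhm_at(20) / fwhm_at(80)
  expect_lt(abs(ratio - 4), 4 * 0.2)
})

test_that("spectral flattening is exact algebra with guarded preconditions", {
  cvals <- outer(1 / (1:100), rep(1, 30)) * 3      # P(f) = c / f with c = 3
  m <- make_map(cvals, freqs = 1:100)
  fl <- spectral_flatten(m)
  expect_lt(max(abs(fl$values - 3) / 3), 1e-9)
  expect_true(fl$flattened)
  z <- spectral_flatten(make_map(matrix(0, 50, 10), freqs = 1:50))
  expect_true(all(z$values == 0))
  expect_error(spectral_flatten(fl), "already flattened")
  expect_error(spectral_flatten(make_map(matrix(1, 151, 10), freqs = 100:250)),
               "100-250")
})

test_that("RPC baseline correction maps power ratios to percent change", {
  tgrid <- seq(-200, 500, by = 10)
  base_cols <- tgrid <= 0
  mk <- function(post_ratio) {
    v <- matrix(1, 20, length(tgrid))
    v[, !base_cols] <- post_ratio
    make_map(v, freqs = 1:20, times = tgrid)
  }
  expect_true(all(abs(baseline_rpc(mk(1))$values) < 1e-12))
  r2 <- baseline_rpc(mk(2))
  expect_equal(unique(as.vector(r2$values[, !base_cols])), 100)
  expect_equal(unique(as.vector(baseline_rpc(mk(0.5))$values[, !base_cols])), -50)
  expect_error(baseline_rpc(r2), "already")
  expect_error(baseline_rpc(make_map(matrix(0, 5, length(tgrid)), freqs = 1:5,
                                     times = tgrid)), "zero baseline")
})

test_that("identical trials make the induced and evoked maps coincide", {
  trial <- sin(2 * pi * 30 * times / 1000) * exp(-(times - 150)^2 / (2 * 40^2)) +
    0.1 * sin(2 * pi * 7 * times / 1000)
  rec <- epoched_recording(rbind(trial, trial, trial), fs, times)
  ind <- induced_tfr(rec, "mid")
  ev <- evoked_tfr(rec, "mid")
  expect_lt(max(abs(ind$values - ev$values)) / max(abs(ev$values)), 1e-9)
})

test_that("random-phase bursts appear induced but not evoked; locked bursts appear in both", {
  cfg_rand <- cohort_config(1, 1, noise_scale = 0.2,
                            bursts = list(induced_burst("NBG", 40, 100, 100, 1)))
  cfg_lock <- cohort_config(1, 1, noise_scale = 0.2,
                            bursts = list(induced_burst("NBG", 40, 100, 100, 1,
                                                        phase_locked = TRUE)))
  rec_r <- generate_subject(cfg_rand, "control", 7)
  rec_l <- generate_subject(cfg_lock, "control", 7)
  px <- function(m) m$values[m$frequencies == 40, which.min(abs(m$times - 100))]
  ind_r <- induced_tfr(rec_r, "mid")
  ev_r <- evoked_tfr(rec_r, "mid")
  ind_l <- induced_tfr(rec_l, "mid")
  ev_l <- evoked_tfr(rec_l, "mid")
  # induced ridge survives phase randomization; evoked is strongly attenuated
  expect_gt(px(ind_r), 1000)
  expect_lt(abs(px(ev_r)), 0.2 * px(ev_l))
  # induced includes the phase-locked part
  expect_gte(px(ind_l), px(ev_l) * 0.9)
  # the induced ridge sits at the burst frequency
  ft <- extract_band_features(ind_r, band_window("NBG"))
  expect_lte(abs(ft$peak_frequency - 40), 1)
})

test_that("induced maps are invariant to trial order", {
  cfg <- cohort_config(1, 1, n_trials = 12, noise_scale = 0.3,
                       bursts = list(induced_burst("NBG", 45, 150, 80, 1)))
  rec <- generate_subject(cfg, "control", 5)
  shuf <- rec
  set.seed(1)
  shuf$data <- shuf$data[sample(nrow(shuf$data)), ]
  expect_equal(induced_tfr(rec, "mid")$values, induced_tfr(shuf, "mid")$values,
               tolerance = 1e-12)
})

test_that("the oscillation mask applies an inclusive 2x amplitude criterion", {
  tgrid <- seq(-200, 500, by = 10)
  v <- matrix(1, 10, length(tgrid))       # amplitude 1 everywhere = background
  m <- make_map(v, freqs = 11:20, times = tgrid)
  expect_false(any(oscillation_mask(m)))
  v2 <- v
  v2[3, 40] <- 4                          # power 4 = amplitude 2 = 2x background
  m2 <- make_map(v2, freqs = 11:20, times = tgrid)
  msk <- oscillation_mask(m2)
  expect_true(msk[3, 40])
  expect_equal(sum(msk), 1)
  v3 <- v
  v3[5, 30:45] <- 9                       # 3x background over a ridge
  expect_equal(sum(oscillation_mask(make_map(v3, freqs = 11:20, times = tgrid))), 16)
})

test_that("baseline-corrected maps expose the raw power for the mask", {
  cfg <- cohort_config(1, 1, n_trials = 10, noise_scale = 0.2,
                       bursts = list(induced_burst("NBG", 40, 150, 100, 2)))
  rec <- generate_subject(cfg, "control", 8)
  ind <- induced_tfr(rec, "mid")
  msk <- oscillation_mask(ind)
  ridge <- which(ind$frequencies == 40)
  t150 <- which.min(abs(ind$times - 150))
  expect_true(msk[ridge, t150])
  expect_lt(mean(msk[, ind$times < 0 & ind$valid[1, ]]), 0.05)
})
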