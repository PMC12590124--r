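# Envelope computation, component peak detection, and the overlapping-window
# group comparison of averaged waveforms.

times <- seq(-200, 500)

test_that("trial averaging is the pointwise mean with mask propagation", {
  rec <- epoched_recording(rbind(c(1, 2, 3), c(3, 2, 1)), 1000, c(0, 1, 2))
  expect_equal(average_evoked(rec)$waveform, c(2, 2, 2))
  one <- epoched_recording(rbind(c(4, 5, 6)), 1000, c(0, 1, 2))
  expect_equal(average_evoked(one)$waveform, c(4, 5, 6))
})

test_that("envelopes trace the amplitude of an oscillation and flag degenerate input", {
  t2 <- seq(0, 1000)
  s <- 2 * sin(2 * pi * 10 * t2 / 1000)
  env <- compute_envelopes(s)
  mid <- 350:650                        # away from the spline's edge ringing
  expect_lt(max(abs(env$upper[mid] - 2)), 0.05 * 2)
  expect_lt(max(abs(env$lower[mid] + 2)), 0.05 * 2)
  expect_true(all(env$upper[mid] >= env$lower[mid]))
  cst <- compute_envelopes(rep(3, 50))
  expect_equal(cst$upper, rep(3, 50))
  expect_equal(cst$lower, rep(3, 50))
  ramp <- compute_envelopes(seq(0, 1, length.out = 50))
  expect_true(ramp$fallback)
})

test_that("component peaks are detected against the 3-SD prestimulus threshold", {
  set.seed(42)
  wav <- numeric(length(times))
  wav[times <= 0] <- rnorm(sum(times <= 0))             # prestim SD ~1
  wav <- wav + 10 * exp(-(times - 90)^2 / (2 * 10^2))   # M100-window deflection
  det <- detect_components(wav, component_windows("MEG-like"), times = times,
                           on = "waveform")
  m100 <- det[det$component == "M100", ]
  expect_true(m100$found)
  expect_lt(abs(m100$latency_ms - 90), 2)
  expect_lt(abs(m100$amplitude - 10), 0.05 * 10)
  # flat zero waveform: nothing found
  flat <- detect_components(numeric(length(times)), times = times)
  expect_false(any(flat$found))
  # a deflection at 88 ms belongs to the M100 window
  w88 <- 10 * exp(-(times - 88)^2 / (2 * 8^2))
  d88 <- detect_components(w88, times = times, on = "waveform")
  expect_true(d88$found[d88$component == "M100"])
  expect_equal(d88$latency_ms[d88$component == "M100"], 88)
})

test_that("detection latency is scale-invariant and amplitude scales linearly", {
  set.seed(7)
  wav <- rnorm(length(times), sd = 0.5) +
    8 * exp(-(times - 120)^2 / (2 * 12^2))
  d1 <- detect_components(wav, times = times, on = "waveform")
  d2 <- detect_components(2.5 * wav, times = times, on = "waveform")
  expect_equal(d1$latency_ms, d2$latency_ms)
  expect_equal(2.5 * d1$amplitude, d2$amplitude, tolerance = 1e-12)
  expect_equal(d1$found, d2$found)
})

test_that("an amplitude of exactly 3 SD above prestimulus mean counts as detected", {
  pre <- rep(c(1, -1), length.out = sum(times < 0))
  wav <- numeric(length(times))
  wav[times < 0] <- pre
  thr <- mean(abs(wav[times >= -200 & times <= 0])) +
    3 * sd(wav[times >= -200 & times <= 0])
  wav <- wav + thr * exp(-(times - 90)^2 / (2 * 10^2))
  det <- detect_components(wav, times = times, on = "waveform")
  expect_true(det$found[det$component == "M100"])
})

test_that("EEG-like windows mirror the MEG-like ranges with alternating polarity", {
  w <- component_windows("EEG-like")
  expect_equal(w$component, c("N1", "P1", "N2", "P3"))
  expect_equal(w$lo, component_windows("MEG-like")$lo)
  expect_equal(w$polarity, c(-1, 1, -1, 1))
  # negative-going N1 is found on the lower envelope
  wav <- -9 * exp(-(times - 85)^2 / (2 * 10^2)) +
    c(rnorm(sum(times <= 0), sd = 0.5), numeric(sum(times > 0)))
  det <- detect_components(wav, w, times = times, on = "waveform")
  n1 <- det[det$component == "N1", ]
  expect_true(n1$found)
  expect_lt(n1$amplitude, 0)
})

test_that("the 0-500 ms axis yields 39 overlapping 25 ms windows", {
  set.seed(3)
  A <- matrix(rnorm(6 * length(times)), nrow = 6)
  B <- matrix(rnorm(6 * length(times)), nrow = 6)
  res <- windowed_group_compare(A, B, times)
  expect_equal(nrow(res), 39)
  expect_equal(res$t_lo[1:3], c(0, 12.5, 25))
})

test_that("identical-generator groups rarely produce significant windows", {
  any_sig <- logical(100)
  for (r in 1:100) {
    set.seed(900 + r)
    A <- matrix(rnorm(6 * length(times)), nrow = 6)
    B <- matrix(rnorm(6 * length(times)), nrow = 6)
    any_sig[r] <- any(windowed_group_compare(A, B, times)$significant)
  }
  expect_gte(mean(!any_sig), 0.95)
})

test_that("a planted 50-350 ms amplitude reduction is localized by the windows", {
  set.seed(5)
  shape <- 5 * exp(-(times - 200)^2 / (2 * 80^2))
  mk <- function(scale_win) t(replicate(15, {
    w <- shape + rnorm(length(times), sd = 0.3)
    w[times >= 50 & times <= 350] <- w[times >= 50 & times <= 350] * scale_win
    w
  }))
  A <- mk(1)
  B <- mk(0.5)
  res <- windowed_group_compare(A, B, times)
  sig <- res[res$significant, ]
  expect_gt(nrow(sig), 0)
  expect_true(all(sig$t_hi >= 50 & sig$t_lo <= 350))
})
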