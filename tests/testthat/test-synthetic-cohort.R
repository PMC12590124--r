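# Synthetic cohort generator: spectral slope of the background noise,
# phase-locking structure, group effects, determinism, and the plain-text
# cohort container.

test_that("noise spectral slope follows the requested 1/f exponent", {
  n <- 2048
  fs <- 1000
  fsel <- NULL
  mean_spec <- function(exponent) {
    acc <- 0
    for (i in 1:100) {
      x <- generate_noise(n, exponent, scale = 1, fs = fs, seed = 5000 + i)
      acc <- acc + Mod(stats::fft(x))^2
    }
    freqs <- (seq_len(n) - 1) * fs / n
    fsel <<- freqs >= 2 & freqs <= 400
    list(f = freqs[fsel], p = (acc / 100)[fsel])
  }
  for (ex in c(0, 1)) {
    sp <- mean_spec(ex)
    slope <- stats::coef(stats::lm(log(sp$p) ~ log(sp$f)))[2]
    expect_lt(abs(slope - (-ex)), 0.1)
  }
})

test_that("noise generation is deterministic and handles edge cases", {
  expect_identical(generate_noise(500, 1, seed = 7), generate_noise(500, 1, seed = 7))
  expect_false(identical(generate_noise(500, 1, seed = 7), generate_noise(500, 1, seed = 8)))
  expect_identical(generate_noise(300, 1, scale = 0), numeric(300))
  expect_error(generate_noise(1, 1), "exceed 1")
  x <- generate_noise(701, 1, scale = 2, seed = 3)
  expect_lt(abs(mean(x)), 1e-10)
  expect_equal(sd(x), 2)
})

test_that("phase-locked components survive averaging at full amplitude", {
  cfg <- cohort_config(1, 1, n_trials = 10, noise_scale = 0,
                       components = list(evoked_component("M100", 90, 10, 3,
                                                          trial_jitter_sd = 0)))
  rec <- generate_subject(cfg, "control", 1)
  avg <- colMeans(rec$data)
  expect_equal(length(rec$times), 701)
  expect_lt(abs(max(avg) - 3), 1e-6)
  expect_equal(rec$times[which.max(avg)], 90)
  # 85 noiseless identical trials average to any single trial
  expect_lt(max(abs(avg - rec$data[1, ])), 1e-12)
})

test_that("uniform-random-phase bursts attenuate ~1/sqrt(n) in the average", {
  cfg <- cohort_config(1, 1, n_trials = 85, noise_scale = 0,
                       bursts = list(induced_burst("NBG", 40, 150, 100, 1)))
  ratios <- vapply(1:10, function(s) {
    rec <- generate_subject(cfg, "control", 20 + s)
    win <- rec$times >= 100 & rec$times <= 200
    avg_rms <- sqrt(mean(colMeans(rec$data)[win]^2))
    single_rms <- sqrt(mean(rec$data[1, win]^2))
    avg_rms / single_rms
  }, numeric(1))
  # random-phase mean shrinks as ~1/sqrt(n_trials) = 0.108 at n = 85
  expect_lt(mean(ratios), 0.15)
})

test_that("group amplitude effects are exact in the noiseless case", {
  base <- list(bursts = list(induced_burst("NBG", 40, 150, 100, 2)))
  cfg <- cohort_config(1, 1, n_trials = 5, noise_scale = 0,
                       bursts = base$bursts,
                       group_effects = list(NBG = list(amp_ratio = 0.5)))
  ctl <- generate_subject(cfg, "control", 77)
  pat <- generate_subject(cfg, "patient", 77)
  expect_equal(pat$data, 0.5 * ctl$data, tolerance = 1e-14)
  expect_equal(pat$truth$bursts[[1]]$amplitude, 1)
})

test_that("cohorts are sized, labelled, reproducible, and carry truth", {
  cfg <- cohort_config(5, 5, n_trials = 3, noise_scale = 0.5, seed = 9,
                       components = list(evoked_component("M100", 80, 10, 2)),
                       group_effects = list(M100 = list(latency_shift = -10)))
  coh1 <- generate_cohort(cfg)
  coh2 <- generate_cohort(cfg)
  expect_length(coh1$recordings, 10)
  grp <- vapply(coh1$recordings, `[[`, "", "group")
  expect_equal(sum(grp == "control"), 5)
  expect_equal(sum(grp == "patient"), 5)
  expect_identical(lapply(coh1$recordings, `[[`, "data"),
                   lapply(coh2$recordings, `[[`, "data"))
  tr <- coh1$truth
  expect_equal(unique(tr$center_latency[tr$group == "patient"]), 70)
  expect_equal(unique(tr$center_latency[tr$group == "control"]), 80)
})

test_that("identity group effects give no spurious NBG power difference", {
  sig <- logical(50)
  for (r in 1:50) {
    cfg <- cohort_config(5, 5, n_trials = 20, noise_scale = 0.3, seed = 100 + r,
                         bursts = list(induced_burst("NBG", 40, 150, 100, 1)))
    coh <- generate_cohort(cfg)
    win <- coh$recordings[[1]]$times >= 100 & coh$recordings[[1]]$times <= 200
    pow <- vapply(coh$recordings, function(rec) mean(rec$data[, win]^2), numeric(1))
    grp <- vapply(coh$recordings, `[[`, "", "group")
    sig[r] <- ranksum(pow[grp == "control"], pow[grp == "patient"])$p < 0.05
  }
  expect_gte(mean(!sig), 0.9)
})

test_that("configuration invariants are enforced", {
  expect_error(evoked_component("M100", 150, 10, 1), "allowed range")
  expect_error(induced_burst("beta", 40, 100, 50, 1), "allowed range")
  expect_error(cohort_config(0, 5), "allowed range")
  expect_error(cohort_config(2, 2, fs = 300,
                             bursts = list(induced_burst("BBG", 200, 100, 50, 1))),
               "twice the highest")
  expect_error(cohort_config(2, 2, t_start = 10), "negative")
})

test_that("the CSV+JSON cohort container round-trips bit-exactly", {
  cfg <- cohort_config(2, 1, n_trials = 4, noise_scale = 1, seed = 12)
  coh <- generate_cohort(cfg)
  dir <- tempfile("cohort")
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_length(back, 3)
  for (i in seq_along(back)) {
    orig <- coh$recordings[[i]]
    got <- back[vapply(back, `[[`, "", "subject_id") == orig$subject_id][[1]]
    expect_identical(got$data, unname(orig$data))
    expect_identical(got$group, orig$group)
    expect_identical(got$times, orig$times)
  }
  unlink(dir, recursive = TRUE)
})

test_that("continuous mode generates epochs consistent with direct generation", {
  cfg <- cohort_config(1, 1, n_trials = 10, noise_scale = 0.2,
                       components = list(evoked_component("M100", 80, 10, 2,
                                                          trial_jitter_sd = 0)))
  cont <- generate_continuous(cfg, n_events = 10, seed = 31)
  rec <- epoch(cont$waveform, cont$events_ms, fs = cont$fs)
  expect_equal(dim(rec$data), c(10, 701))
  avg <- colMeans(rec$data)
  expect_equal(rec$times[which.max(avg)], 80, tolerance = 3)
})
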