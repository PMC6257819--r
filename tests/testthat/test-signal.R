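# minimal single-channel dataset helper for wavelet tests
toy_eeg <- function(signal_fun, srate = 250, window = c(-1250, 700),
                    pad = 500, n_channels = 1) {
  times <- seq(window[1] - pad, window[2] + pad, by = 1000 / srate)
  x <- signal_fun(times / 1000)
  dat <- array(rep(x, each = n_channels), dim = c(1, n_channels, length(times)))
  structure(list(data = dat, srate = srate, times = times,
                 analysis_window = window,
                 montage = paste0("ch", seq_len(n_channels)),
                 schedule = NULL), class = "eeg_dataset")
}

test_that("wavelet bank matches its defining formulas", {
  b <- wavelet_bank()
  expect_length(b$freqs, 32)
  expect_equal(b$freqs[1], 4)
  expect_equal(b$freqs[32], 35)
  expect_true(all(diff(b$freqs) > 0))
  expect_true(all(diff(log(b$freqs)) - diff(log(b$freqs))[1] < 1e-12))
  expect_equal(b$cycles[1], 3)
  expect_equal(b$cycles[32], 10)
  expect_true(all(diff(b$cycles) >= 0))
  expect_equal(b$sigma, b$cycles / (2 * pi * b$freqs), tolerance = 1e-15)
  expect_equal(b$sigma[1], 3 / (2 * pi * 4), tolerance = 1e-12)

  two <- wavelet_bank(n_freqs = 2)
  expect_equal(two$freqs, c(4, 35))
  expect_equal(two$cycles, c(3, 10))
  expect_error(wavelet_bank(f_max = 130), "Nyquist")
})

test_that("wavelet power matches an independent time-domain convolution", {
  eeg <- toy_eeg(function(t) sin(2 * pi * 10 * t))
  bank <- wavelet_bank()
  tf <- tf_power(eeg, bank)
  center <- which.min(abs(tf$times + 300))
  pw <- tf$power[1, 1, , center]
  k <- which.min(abs(bank$freqs - 10))
  expect_equal(which.max(pw), k)

  # oracle: explicit complex Morlet convolved in the time domain, scaled to
  # unit gain at its center frequency (continuous FT peak = sigma*sqrt(2pi),
  # doubled analytic part, discrete sum approximates the integral via dt)
  dt <- 1 / eeg$srate
  sigma <- bank$sigma[k]
  wt <- seq(-4 * sigma, 4 * sigma, by = dt)
  w <- exp(2i * pi * bank$freqs[k] * wt) * exp(-wt^2 / (2 * sigma^2))
  w <- w * 2 * dt / (sigma * sqrt(2 * pi))
  sig <- sin(2 * pi * 10 * eeg$times / 1000)
  z <- stats::convolve(sig, Conj(rev(w)), type = "open")
  mid <- which.min(abs(eeg$times + 300)) + (length(wt) - 1) / 2
  oracle_power <- Mod(z[mid])^2
  expect_equal(pw[k], oracle_power, tolerance = 0.1)
})

test_that("power is zero for zero input and scales quadratically", {
  zero <- toy_eeg(function(t) 0 * t)
  tfz <- tf_power(zero, wavelet_bank(n_freqs = 4))
  expect_true(all(tfz$power == 0))

  one <- toy_eeg(function(t) sin(2 * pi * 10 * t))
  two <- one; two$data <- one$data * 2
  b <- wavelet_bank(n_freqs = 8)
  expect_equal(tf_power(two, b)$power, 4 * tf_power(one, b)$power,
               tolerance = 1e-12)
})

test_that("every bank frequency localizes its own sinusoid", {
  bank <- wavelet_bank()
  for (k in seq(1, 32, by = 3)) {
    f <- bank$freqs[k]
    eeg <- toy_eeg(function(t) sin(2 * pi * f * t))
    tf <- tf_power(eeg, bank)
    center <- which.min(abs(tf$times + 200))
    expect_equal(which.max(tf$power[1, 1, , center]), k)
  }
})

test_that("wavelet power grows monotonically with noise variance", {
  b <- wavelet_bank(n_freqs = 4)
  tot <- vapply(c(1, 3, 9), function(sd) {
    set.seed(20)
    eeg <- toy_eeg(function(t) rnorm(length(t), sd = sd))
    sum(tf_power(eeg, b)$power)
  }, numeric(1))
  expect_true(all(diff(tot) > 0))
})

test_that("epochs without enough padding are refused", {
  eeg <- toy_eeg(function(t) 0 * t, pad = 100)
  expect_error(tf_power(eeg, wavelet_bank()), "padding")
})

test_that("rejection rules match injected artifact ground truth", {
  s <- build_schedule(experiment_design("exp1"), seed = 6, n_blocks = 1,
                      allow_unbalanced = TRUE)
  eeg <- simulate_eeg(s, default_patterns(amplitude = 0),
                      noise_spec(noise_sd = 3), seed = 13)
  clean <- reject_artifacts(eeg)
  expect_equal(sum(clean$rejected), 0)

  dirty <- inject_artifacts(eeg, list(blink_rate = 0.15, blink_amp = 120,
                                      flat_rate = 0.1, flat_ms = 220),
                            seed = 14)
  rep <- reject_artifacts(dirty)
  truth_blink <- dirty$artifact_mask$trial[dirty$artifact_mask$type == "blink"]
  truth_flat <- dirty$artifact_mask$trial[dirty$artifact_mask$type == "blocking"]
  # sensitivity and specificity both 1 on well-separated artifacts
  expect_setequal(which(rep$blink), truth_blink)
  expect_setequal(which(rep$blocking), truth_flat)
  expect_setequal(which(rep$rejected), c(truth_blink, truth_flat))
})

test_that("a lateral step is flagged as an eye movement", {
  s <- build_schedule(experiment_design("exp1"), seed = 6, n_blocks = 1,
                      allow_unbalanced = TRUE)
  eeg <- simulate_eeg(s, default_patterns(amplitude = 0),
                      noise_spec(noise_sd = 3), seed = 15)
  t3 <- match("T3", eeg$montage); t4 <- match("T4", eeg$montage)
  mid <- which(eeg$times > -200)
  eeg$data[5, t3, mid] <- eeg$data[5, t3, mid] + 30
  eeg$data[5, t4, mid] <- eeg$data[5, t4, mid] - 30
  rep <- reject_artifacts(eeg)
  expect_true(rep$eye_movement[5])
  expect_error(reject_artifacts(eeg, heog_channels = c("XX", "T4")), "missing")
})

test_that("band power contrast is null, zero, or detects an injected boost", {
  fx <- small_tf(amplitude = 0, seed = 120, n_blocks = 2)
  tf <- fx$tf
  # identical data in both conditions: exactly zero contrast
  same <- tf
  same$power <- array(1.7, dim = dim(tf$power))
  res0 <- band_power_contrast(list(same))
  expect_equal(res0$per_subject, 0)

  # null calibration: shuffled labels give |t| < 2 in most seeded runs
  set.seed(31)
  n_null <- 0
  for (r in 1:30) {
    tfs <- replicate(8, {
      x <- tf
      x$schedule$within_position <- sample(x$schedule$within_position)
      x
    }, simplify = FALSE)
    res <- band_power_contrast(tfs)
    if (abs(res$t) < 2) n_null <- n_null + 1
  }
  expect_gte(n_null / 30, 0.8)

  # injected uniform theta boost at position 1 is detected
  set.seed(77)
  boosted <- replicate(6, {
    x <- tf
    sel <- x$schedule$within_position == 1
    fsel <- x$freqs >= 4 & x$freqs <= 7
    x$power[sel, , fsel, ] <- x$power[sel, , fsel, ] + rnorm(1, 40, 5)
    x
  }, simplify = FALSE)
  res1 <- band_power_contrast(boosted)
  expect_gt(res1$b, 0)
  expect_gt(res1$t, 2)
})

test_that("average re-reference zeroes the channel mean", {
  fx <- small_tf(amplitude = 0, seed = 120, n_blocks = 2)
  s <- build_schedule(experiment_design("exp1"), seed = 8, n_blocks = 1,
                      allow_unbalanced = TRUE)
  eeg <- simulate_eeg(s, default_patterns(amplitude = 2), noise_spec(),
                      seed = 16)
  rr <- avg_reref(eeg)
  expect_lt(max(abs(apply(rr$data, c(1, 3), mean))), 1e-10)
})

test_that("epoched text ingestion reconstructs the array", {
  arr <- array(rnorm(2 * 2 * 5), dim = c(2, 2, 5))
  df <- expand.grid(trial = 1:2, channel = c("E1", "E2"),
                    time_ms = seq(-8, 8, by = 4))
  df$uv <- arr[cbind(df$trial, match(df$channel, c("E1", "E2")),
                     match(df$time_ms, seq(-8, 8, by = 4)))]
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  eeg <- read_epoched_tsv(path, analysis_window = c(-4, 4),
                          channel_map = c(E1 = "Fz", E2 = "Cz"))
  expect_equal(eeg$montage, c("Fz", "Cz"))
  expect_equal(eeg$data[2, 1, 3], arr[2, 1, 3])
})
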