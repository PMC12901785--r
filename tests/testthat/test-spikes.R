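test_that("moving thresholds collapse to the constant on a flat trace", {
  thr <- moving_threshold(rep(3.5, 500), fs = 20000, window_ms = 5, k = 5)
  expect_equal(thr$center, rep(3.5, 500))
  expect_equal(thr$sd, rep(0, 500))
  expect_equal(thr$upper, rep(3.5, 500))
  expect_equal(thr$lower, rep(3.5, 500))
  expect_error(moving_threshold(rnorm(100), fs = 100, window_ms = 5), "2 samples")
})

test_that("moving thresholds match the explicit per-window oracle", {
  set.seed(10)
  x <- rnorm(1000)
  fs <- 19754
  for (guard in c(0, 1)) {
    got <- moving_threshold(x, fs, 5, 5, guard_ms = guard)
    want <- oracle_threshold(x, fs, 5, 5, guard_ms = guard)
    expect_equal(got$center, want$center, tolerance = 1e-10)
    expect_equal(got$upper, want$upper, tolerance = 1e-10)
    expect_equal(got$lower, want$lower, tolerance = 1e-10)
  }
  # with a mask: invalid samples excluded from the window statistics
  mask <- rep(TRUE, 1000)
  mask[300:420] <- FALSE
  got <- moving_threshold(x, fs, 5, 5, mask = mask)
  want <- oracle_threshold(x, fs, 5, 5, mask = mask)
  expect_equal(got$upper, want$upper, tolerance = 1e-10)
})

test_that("threshold spread scales linearly with the trace", {
  set.seed(11)
  x <- rnorm(400)
  fs <- 19754
  a <- moving_threshold(x, fs)
  b <- moving_threshold(-2.5 * x, fs)
  expect_equal(b$upper - b$center, 2.5 * (a$upper - a$center), tolerance = 1e-10)
})

test_that("spike detection is empty on constant traces and exact on clean spikes", {
  expect_length(detect_spikes(rep(1, 2000), fs = 20000)$times, 0)

  # 10 spikes at SNR 10, known times; all recovered within +/-0.5 ms
  fs <- 19754
  set.seed(12)
  x <- rnorm(fs * 2)
  w <- spikexpr:::spike_waveform(fs, 10)
  starts <- seq(2000, by = 3500, length.out = 10)
  truth <- integer(10)
  for (i in seq_along(starts)) {
    idx <- starts[i]:(starts[i] + length(w) - 1)
    x[idx] <- x[idx] + w
    truth[i] <- starts[i] + attr(w, "peak") - 1
  }
  tr <- detect_spikes(x, fs = fs)
  tol <- round(0.5e-3 * fs)
  expect_true(all(vapply(truth, function(t) any(abs(tr$times - t) <= tol),
                         logical(1))))
})

test_that("detected event counts equal the naive loop oracle on noise", {
  fs <- 19754
  for (seed in 1:4) {
    set.seed(seed)
    x <- rnorm(1000)
    got <- length(detect_spikes(x, fs = fs, k = 2.5)$times)
    expect_equal(got, oracle_event_count(x, fs, k = 2.5))
  }
})

test_that("raising the threshold multiplier never finds more spikes", {
  fs <- 19754
  set.seed(13)
  x <- rnorm(20000)
  counts <- vapply(c(2, 3, 4, 5), function(k)
    length(detect_spikes(x, fs = fs, k = k)$times), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("channel frequency uses the effective (masked) duration", {
  fs <- 1000
  mask <- rep(TRUE, 300 * fs)
  tr0 <- spike_train(integer(0), numeric(0), channel = 1)
  expect_equal(channel_frequency(tr0, mask, fs)$freq_hz, 0)

  times <- as.integer(seq(1000, by = 995, length.out = 300))
  tr <- spike_train(times, channel = 2)
  expect_equal(channel_frequency(tr, mask, fs)$freq_hz, 1.0)

  mask2 <- mask
  mask2[1:(30 * fs)] <- FALSE # 30 s masked out of 300 s
  expect_equal(channel_frequency(tr, mask2, fs)$freq_hz, 300 / 270)
})

test_that("channel selection excludes hyperactive channels then ranks", {
  acts <- data.frame(channel = 1:31,
                     freq_hz = c(6.0, 1.0, 0.9, seq(0.8, by = -0.01, length.out = 28)))
  sel <- select_channels(acts, top_n = 30, max_hz = 5)
  expect_false(1 %in% sel$channel) # the 6 Hz channel is gone before ranking
  expect_equal(nrow(sel), 30)
  expect_equal(sel$channel[1:2], c(2, 3))

  # brute-force sort-and-slice oracle on random frequencies
  set.seed(14)
  acts2 <- data.frame(channel = 1:100, freq_hz = round(runif(100, 0, 8), 2))
  sel2 <- select_channels(acts2, top_n = 30, max_hz = 5)
  keep <- acts2[acts2$freq_hz <= 5, ]
  want <- keep[order(-keep$freq_hz, keep$channel), ][1:30, ]
  expect_equal(sel2$channel, want$channel)

  # 30 quiet channels: all selected
  acts3 <- data.frame(channel = 1:30, freq_hz = runif(30, 0, 4))
  expect_equal(nrow(select_channels(acts3)), 30)
})

test_that("organoid inclusion applies the 0.5 Hz floor with >= boundary", {
  sel <- data.frame(channel = 1:10, freq_hz = rep(0.4, 10))
  expect_false(organoid_summary(sel, "a")$included)
  sel2 <- data.frame(channel = 1:10, freq_hz = rep(0.5, 10))
  expect_true(organoid_summary(sel2, "b")$included)
  expect_error(organoid_summary(data.frame()), "empty")
})

test_that("detection on synthetic recordings is sensitive and specific at SNR 8", {
  # SNR 8 = 80 uV spikes in 10 uV noise; 4 active channels x 15 s at 1 Hz
  cfg <- mea_sim_config(n_channels = 4, duration = 15, active_fraction = 1,
                        rate_hz = 1, spike_amp = 80, noise_sd = 10,
                        flash_rate = 0.05, seed = 21)
  sim <- generate_mea_recording(cfg)
  rec <- sim$recording
  mask <- detect_flashes(rec, excise_recalibration(rec, 100))
  coefs <- design_bandpass_fir(rec$fs)
  tol <- round(0.5e-3 * rec$fs)
  hits <- c(); n_fp <- 0; n_det <- 0
  for (ch in seq_len(4)) {
    filt <- bandpass_filter(rec$samples[ch, ], rec$fs, mask = mask, coefs = coefs)
    tr <- detect_spikes(filt, mask, rec$fs)
    tt <- sim$truth$spike_times[[ch]]
    tt <- tt[mask[tt]] # spikes in excised time are not recoverable
    hits <- c(hits, vapply(tt, function(t) any(abs(tr$times - t) <= tol),
                           logical(1)))
    n_fp <- n_fp + sum(!vapply(tr$times, function(t) any(abs(tt - t) <= tol),
                               logical(1)))
    n_det <- n_det + length(tr$times)
  }
  expect_gte(mean(hits), 0.95)
  expect_lte(n_fp / n_det, 0.05)
})
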