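test_that("recalibration excision invalidates exactly the bordered windows", {
  rec <- recording(matrix(0, 2, 10000), fs = 19754)
  expect_true(all(excise_recalibration(rec, 100)))

  rec1 <- recording(matrix(0, 1, 10000), fs = 19754,
                    recalib_timestamps = 5000L)
  mask <- excise_recalibration(rec1, 100)
  expect_equal(sum(!mask), 201) # timestamp plus 100 either side
  expect_true(all(which(!mask) == 4900:5100))
  # ~10 ms at the chip sampling rate
  expect_equal(sum(!mask) / 19754 * 1000, 10.17, tolerance = 0.01)

  # overlapping borders merge
  rec2 <- recording(matrix(0, 1, 1000), fs = 1000,
                    recalib_timestamps = c(400L, 420L))
  m2 <- excise_recalibration(rec2, 50)
  expect_equal(which(!m2), 350:470)
})

test_that("every injected recalibration sample lies in an excised region", {
  sim <- small_sim()
  mask <- excise_recalibration(sim$recording, 100)
  art <- sim$truth$artifact_intervals
  for (i in seq_len(nrow(art)))
    expect_true(all(!mask[art[i, "start"]:art[i, "end"]]))
  # effective duration with k isolated events: duration - k*(2*border+1)/fs
  k <- nrow(art)
  expect_equal(effective_duration(mask, sim$recording$fs),
               ncol(sim$recording$samples) / sim$recording$fs -
                 k * 201 / sim$recording$fs)
})

test_that("flash removal flags multi-channel saturation and only that", {
  x <- matrix(rnorm(10 * 2000, sd = 10), 10, 2000)
  rec <- recording(x, fs = 20000, metadata = list(rail = 1000))
  expect_true(all(detect_flashes(rec))) # sub-saturation noise everywhere

  x2 <- x
  x2[1:9, 500:520] <- 1000 # 90% of channels saturated
  rec2 <- recording(x2, fs = 20000, metadata = list(rail = 1000))
  m <- detect_flashes(rec2, channel_frac = 0.5)
  expect_true(all(!m[500:520]))
  expect_true(all(m[-(500:520)]))

  x3 <- x
  x3[1, 500:520] <- 1000 # single channel: below the majority criterion
  rec3 <- recording(x3, fs = 20000, metadata = list(rail = 1000))
  expect_true(all(detect_flashes(rec3, channel_frac = 0.5)))

  rec4 <- recording(x, fs = 20000)
  expect_error(detect_flashes(rec4), "rail")
})

test_that("flash intervals from the generator are invalidated; masks compose", {
  sim <- small_sim()
  mask1 <- excise_recalibration(sim$recording, 100)
  mask2 <- detect_flashes(sim$recording, mask1)
  fl <- sim$truth$flash_intervals
  expect_gt(nrow(fl), 0) # fixture seed is chosen to contain flashes
  for (i in seq_len(nrow(fl)))
    expect_true(all(!mask2[fl[i, "start"]:fl[i, "end"]]))
  # monotone composition: flash removal never re-validates a sample
  expect_true(all(which(!mask1) %in% which(!mask2)))
})

test_that("band-pass keeps the passband flat and crushes the stopbands", {
  fs <- 19754
  coefs <- design_bandpass_fir(fs)
  gain <- function(f0) {
    t <- seq(0, 1, by = 1 / fs)
    x <- sin(2 * pi * f0 * t)
    y <- bandpass_filter(x, fs, coefs = coefs)
    i <- seq(round(0.2 * fs), round(0.8 * fs)) # interior, away from edges
    sqrt(mean(y[i]^2) / mean(x[i]^2))
  }
  expect_lt(abs(20 * log10(gain(1000))), 1) # within +/-1 dB
  expect_lt(20 * log10(gain(50)), -40) # >= 40 dB down
  expect_lt(20 * log10(gain(3500)), -20)

  expect_equal(bandpass_filter(rep(0, 5000), fs, coefs = coefs), rep(0, 5000))
  expect_error(design_bandpass_fir(fs, low = 3000, high = 150), "band edges")
  expect_error(design_bandpass_fir(fs, low = 150, high = 12000), "band edges")
})

test_that("the FIR is linear and length-preserving, also under masks", {
  fs <- 19754
  coefs <- design_bandpass_fir(fs)
  set.seed(1)
  x <- rnorm(4000)
  y <- rnorm(4000)
  fx <- bandpass_filter(x, fs, coefs = coefs)
  fy <- bandpass_filter(y, fs, coefs = coefs)
  fxy <- bandpass_filter(2 * x - 3 * y, fs, coefs = coefs)
  expect_equal(fxy, 2 * fx - 3 * fy, tolerance = 1e-9)
  expect_length(fx, length(x))

  mask <- rep(TRUE, 4000)
  mask[1500:1700] <- FALSE
  fm <- bandpass_filter(x, fs, mask = mask, coefs = coefs)
  expect_length(fm, 4000)
  expect_true(all(fm[1500:1700] == 0)) # invalid samples carry no signal
  # segments are filtered independently: first segment unaffected by second
  fm1 <- bandpass_filter(x[1:1499], fs, coefs = coefs)
  expect_equal(fm[1:1499], fm1, tolerance = 1e-12)
})
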