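#' Configuration for a synthetic HD-MEA recording
#'
#' Describes a multichannel extracellular recording with Poisson spike trains
#' on a subset of channels, periodic chip-recalibration artifacts, and rare
#' multi-channel saturation "flashes", all embedded in Gaussian noise. The
#' defaults mirror the acquisition conditions of the study design this package
#' supports: 19,754 Hz sampling, 5-minute recordings, recalibration roughly
#' every 400 ms.
#'
#' @param n_channels number of recording channels.
#' @param fs sampling frequency in Hz.
#' @param duration recording length in seconds.
#' @param active_fraction fraction of channels carrying spikes, in \[0, 1\].
#' @param rate_hz mean Poisson firing rate per active channel (spikes/s).
#' @param spike_amp peak amplitude of the negative spike lobe, in uV.
#' @param noise_sd standard deviation of the Gaussian background noise, in uV.
#' @param recalib_period period of the chip recalibration, in seconds.
#' @param recalib_amp amplitude of the recalibration pulse, in uV.
#' @param flash_rate rate of saturation flashes, events per second.
#' @param flash_channel_frac fraction of channels saturated by a flash.
#' @param rail saturation rail of the acquisition system, in uV.
#' @param seed integer RNG seed; identical configs give identical recordings.
#' @return an object of class `mea_sim_config`.
#' @export
mea_sim_config <- function(n_channels = 64, fs = 19754, duration = 300,
                           active_fraction = 0.25, rate_hz = 1,
                           spike_amp = 80, noise_sd = 10,
                           recalib_period = 0.4, recalib_amp = 1500,
                           flash_rate = 0.01, flash_channel_frac = 0.9,
                           rail = 2048, seed = 1L) {
  cfg <- list(n_channels = n_channels, fs = fs, duration = duration,
              active_fraction = active_fraction, rate_hz = rate_hz,
              spike_amp = spike_amp, noise_sd = noise_sd,
              recalib_period = recalib_period, recalib_amp = recalib_amp,
              flash_rate = flash_rate, flash_channel_frac = flash_channel_frac,
              rail = rail, seed = as.integer(seed))
  check_num <- function(field, ok, what) {
    v <- cfg[[field]]
    if (length(v) != 1 || !is.numeric(v) || is.na(v) || !ok(v))
      stop("invalid `", field, "`: must be ", what, call. = FALSE)
  }
  check_num("n_channels", function(v) v >= 1 && v == floor(v), "a positive integer")
  check_num("fs", function(v) v > 0, "> 0")
  check_num("duration", function(v) v > 0, "> 0")
  check_num("active_fraction", function(v) v >= 0 && v <= 1, "in [0, 1]")
  check_num("rate_hz", function(v) v >= 0, ">= 0")
  check_num("spike_amp", function(v) v >= 0, ">= 0")
  check_num("noise_sd", function(v) v >= 0, ">= 0")
  check_num("recalib_period", function(v) v > 0, "> 0")
  check_num("recalib_amp", function(v) v >= 0, ">= 0")
  check_num("flash_rate", function(v) v >= 0, ">= 0")
  check_num("flash_channel_frac", function(v) v >= 0 && v <= 1, "in [0, 1]")
  check_num("rail", function(v) v > 0, "> 0")
  structure(cfg, class = "mea_sim_config")
}

# biphasic extracellular spike template: negative lobe (~0.6 ms) followed by a
# smaller positive lobe (~0.4 ms); peak of the negative lobe is the spike time
spike_waveform <- function(fs, amp) {
  n1 <- max(2L, round(0.6e-3 * fs))
  n2 <- max(2L, round(0.4e-3 * fs))
  w <- c(-amp * sin(pi * seq_len(n1) / (n1 + 1)),
         0.5 * amp * sin(pi * seq_len(n2) / (n2 + 1)))
  attr(w, "peak") <- which.min(w)
  w
}

#' Generate a synthetic HD-MEA recording with ground truth
#'
#' Simulates Gaussian background noise on every channel, biphasic spikes
#' (amplitude jittered +/-20%) at Poisson times on the active channels,
#' a square recalibration pulse of 1 ms on all channels at exact multiples of
#' `recalib_period`, and rail-level saturation flashes of 5 ms on a random
#' subset of channels. The final trace is clipped at `+/-rail`. Spike times on
#' a channel are thinned to a 3 ms minimum separation (a coarse refractory
#' period) so that ground-truth events are individually resolvable.
#'
#' @param cfg a [mea_sim_config()].
#' @return a list with elements `recording` (class `mea_recording`, see
#'   [recording()]) and `truth` (class `mea_ground_truth`) holding per-channel
#'   spike times (sample index of the negative peak), per-spike amplitudes,
#'   and artifact / flash sample intervals (two-column matrices, inclusive).
#' @export
generate_mea_recording <- function(cfg) {
  if (!inherits(cfg, "mea_sim_config")) cfg <- do.call(mea_sim_config, cfg)
  set.seed(cfg$seed)
  n_samp <- floor(cfg$duration * cfg$fs)
  nc <- cfg$n_channels

  samples <- matrix(stats::rnorm(nc * n_samp, sd = cfg$noise_sd),
                    nrow = nc, ncol = n_samp)

  n_active <- round(cfg$active_fraction * nc)
  active <- if (n_active > 0) sort(sample.int(nc, n_active)) else integer(0)

  min_gap <- round(3e-3 * cfg$fs)
  spike_times <- rep(list(integer(0)), nc)
  spike_amps <- rep(list(numeric(0)), nc)
  template_len <- length(spike_waveform(cfg$fs, 1))
  for (ch in active) {
    n_sp <- stats::rpois(1, cfg$rate_hz * cfg$duration)
    if (n_sp == 0) next
    t_peak <- sort(sample.int(n_samp - template_len, n_sp))
    if (length(t_peak) > 1) { # refractory thinning
      keep <- c(TRUE, diff(t_peak) >= min_gap)
      t_peak <- t_peak[keep]
    }
    amps <- cfg$spike_amp * stats::runif(length(t_peak), 0.8, 1.2)
    for (i in seq_along(t_peak)) {
      w <- spike_waveform(cfg$fs, amps[i])
      start <- t_peak[i]
      idx <- start:(start + length(w) - 1L)
      samples[ch, idx] <- samples[ch, idx] + w
      t_peak[i] <- start + attr(w, "peak") - 1L
    }
    spike_times[[ch]] <- t_peak
    spike_amps[[ch]] <- amps
  }

  # recalibration: 1 ms square pulse on all channels at multiples of the period
  pulse_len <- max(1L, round(1e-3 * cfg$fs))
  recalib <- seq(round(cfg$recalib_period * cfg$fs), n_samp - pulse_len,
                 by = round(cfg$recalib_period * cfg$fs))
  recalib <- as.integer(recalib)
  artifact_intervals <- cbind(start = recalib, end = recalib + pulse_len - 1L)
  for (t0 in recalib)
    samples[, t0:(t0 + pulse_len - 1L)] <-
      samples[, t0:(t0 + pulse_len - 1L)] + cfg$recalib_amp

  # flashes: 5 ms rail-level saturation on a random channel subset
  flash_len <- max(1L, round(5e-3 * cfg$fs))
  n_flash <- stats::rpois(1, cfg$flash_rate * cfg$duration)
  flash_start <- if (n_flash > 0)
    sort(sample.int(n_samp - flash_len, n_flash)) else integer(0)
  flash_channels <- vector("list", n_flash)
  n_fch <- max(1L, round(cfg$flash_channel_frac * nc))
  for (i in seq_len(n_flash)) {
    chs <- sort(sample.int(nc, n_fch))
    flash_channels[[i]] <- chs
    samples[chs, flash_start[i]:(flash_start[i] + flash_len - 1L)] <- cfg$rail
  }
  flash_intervals <- cbind(start = as.integer(flash_start),
                           end = as.integer(flash_start) + flash_len - 1L)

  samples <- pmin(pmax(samples, -cfg$rail), cfg$rail)

  rec <- recording(samples, fs = cfg$fs, recalib_timestamps = recalib,
                   metadata = list(rail = cfg$rail, simulated = TRUE,
                                   seed = cfg$seed))
  truth <- structure(
    list(spike_times = spike_times, spike_amps = spike_amps,
         active_channels = active,
         artifact_intervals = artifact_intervals,
         flash_intervals = flash_intervals,
         flash_channels = flash_channels),
    class = "mea_ground_truth")
  list(recording = rec, truth = truth)
}
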