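#' Moving-window detection thresholds
#'
#' For each sample, computes mean +/- k*SD of the trace over a window of
#' `floor(window_ms * fs / 1000)` samples centered on that sample (truncated
#' at the trace edges), using valid samples only. An optional guard interval
#' of `+/-guard_ms` around the evaluated sample can be excluded from the
#' window statistics so that a candidate event does not inflate its own
#' threshold; `guard_ms = 0` (the default here) is the plain estimator.
#'
#' @param trace numeric vector, single channel.
#' @param fs sampling frequency, Hz.
#' @param window_ms window length, ms; must span at least 2 samples.
#' @param k threshold multiplier (> 0).
#' @param mask optional logical validity mask.
#' @param guard_ms half-width of the central guard interval excluded from the
#'   window statistics, ms.
#' @param sd_floor lower bound applied to the windowed SD before thresholds
#'   are formed (same units as the trace). A short window holds few
#'   statistically independent samples of band-limited noise, so the raw
#'   local SD occasionally dips far below the true noise scale and spuriously
#'   lowers the threshold; flooring it at a channel-wide robust noise
#'   estimate (see [detect_spikes()]) stabilizes detection. 0 disables.
#' @return list with per-sample `center`, `sd`, `upper`, `lower` (NA where
#'   fewer than 2 valid samples remain in the window).
#' @export
moving_threshold <- function(trace, fs, window_ms = 5, k = 5, mask = NULL,
                             guard_ms = 0, sd_floor = 0) {
  if (window_ms <= 0 || k <= 0) stop("`window_ms` and `k` must be > 0")
  w <- floor(window_ms * fs / 1000)
  if (w < 2) stop("window spans fewer than 2 samples")
  n <- length(trace)
  if (is.null(mask)) mask <- rep(TRUE, n)
  stopifnot(length(mask) == n)
  g <- if (guard_ms > 0) round(guard_ms * fs / 1000) else -1L

  v <- as.numeric(mask)
  x <- ifelse(mask, trace, 0)
  cs1 <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x * x))
  csn <- c(0, cumsum(v))
  idx <- seq_len(n)
  lo <- pmax(idx - ((w - 1L) %/% 2L), 1L)
  hi <- pmin(idx + (w %/% 2L), n)
  S <- cs1[hi + 1L] - cs1[lo]
  Q <- cs2[hi + 1L] - cs2[lo]
  m <- csn[hi + 1L] - csn[lo]
  if (g >= 0) {
    glo <- pmax(idx - g, lo)
    ghi <- pmin(idx + g, hi)
    S <- S - (cs1[ghi + 1L] - cs1[glo])
    Q <- Q - (cs2[ghi + 1L] - cs2[glo])
    m <- m - (csn[ghi + 1L] - csn[glo])
  }
  ok <- m >= 2
  center <- ifelse(ok, S / m, NA_real_)
  varr <- ifelse(ok, pmax(Q - S^2 / m, 0) / (m - 1), NA_real_)
  sdv <- pmax(sqrt(varr), sd_floor)
  list(center = center, sd = sdv,
       upper = center + k * sdv, lower = center - k * sdv)
}

#' Spike train container
#'
#' @param times sample indices of detected spikes, strictly increasing.
#' @param amplitudes peak amplitudes, uV.
#' @param channel channel identifier.
#' @return an object of class `spike_train`.
#' @export
spike_train <- function(times, amplitudes = rep(NA_real_, length(times)),
                        channel = NA) {
  times <- as.integer(times)
  if (is.unsorted(times, strictly = TRUE) && length(times) > 1)
    stop("spike times must be strictly increasing")
  if (length(amplitudes) != length(times))
    stop("one amplitude per spike time required")
  structure(list(channel = channel, times = times, amplitudes = amplitudes),
            class = "spike_train")
}

#' Detect spikes by moving-window threshold crossing
#'
#' A spike is a contiguous excursion of the trace beyond either of the
#' moving-window thresholds (mean +/- k*SD, two-sided); its time is the sample
#' of maximum absolute deviation from the window mean within the excursion,
#' and its amplitude the trace value there. Excursions separated by less than
#' `refractory_ms` are merged. Samples invalid under the mask can neither
#' trigger nor host a spike.
#'
#' Two refinements keep the short-window estimator honest, both on by
#' default:
#' * the window statistics exclude a +/-1 ms guard interval around the
#'   evaluated sample (`guard_ms = 1`): the threshold is meant to estimate
#'   the local background noise, and a ~1 ms extracellular spike inside its
#'   own 5 ms window would otherwise inflate the SD several-fold and suppress
#'   detection of moderate-SNR events;
#' * the windowed SD is floored at the channel-wide robust noise scale
#'   (MAD-based, spike-insensitive; `robust_floor = TRUE`), because a 5 ms
#'   window of band-limited noise holds too few independent samples for a
#'   stable SD and its low excursions would otherwise admit noise crossings.
#'
#' Set `guard_ms = 0` and `robust_floor = FALSE` for the plain estimator.
#'
#' @inheritParams moving_threshold
#' @param refractory_ms merge distance between excursions, ms.
#' @param guard_ms guard half-width, ms (see [moving_threshold()]).
#' @param robust_floor floor the windowed SD at `mad()` of the valid trace.
#' @param channel channel identifier stored on the result.
#' @return a [spike_train()].
#' @export
detect_spikes <- function(trace, mask = NULL, fs, window_ms = 5, k = 5,
                          refractory_ms = 1, guard_ms = 1,
                          robust_floor = TRUE, channel = NA) {
  n <- length(trace)
  if (is.null(mask)) mask <- rep(TRUE, n)
  floor_sd <- if (robust_floor) stats::mad(trace[mask]) else 0
  thr <- moving_threshold(trace, fs, window_ms, k, mask, guard_ms, floor_sd)
  dev <- trace - thr$center
  exceed <- !is.na(thr$sd) & mask & (trace > thr$upper | trace < thr$lower)
  if (!any(exceed)) return(spike_train(integer(0), numeric(0), channel))

  r <- rle(exceed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  runs <- cbind(starts[on], ends[on])
  ref <- max(1L, round(refractory_ms * fs / 1000))
  if (nrow(runs) > 1) { # merge excursions closer than the refractory distance
    gap <- runs[-1, 1] - runs[-nrow(runs), 2] - 1L
    grp <- cumsum(c(1L, as.integer(gap >= ref)))
    runs <- cbind(tapply(runs[, 1], grp, min), tapply(runs[, 2], grp, max))
  }
  times <- integer(nrow(runs))
  amps <- numeric(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    seg <- runs[i, 1]:runs[i, 2]
    seg <- seg[mask[seg] & !is.na(dev[seg])]
    peak <- seg[which.max(abs(dev[seg]))]
    times[i] <- peak
    amps[i] <- trace[peak]
  }
  spike_train(times, amps, channel)
}

#' Per-channel activity summary
#'
#' Firing frequency is spike count divided by the effective (valid) duration,
#' not the nominal recording length.
#'
#' @param train a [spike_train()].
#' @param mask logical validity mask.
#' @param fs sampling frequency, Hz.
#' @return data.frame with `channel`, `n_spikes`, `freq_hz`.
#' @export
channel_frequency <- function(train, mask, fs) {
  stopifnot(inherits(train, "spike_train"))
  dur <- effective_duration(mask, fs)
  if (dur <= 0) stop("effective duration is zero")
  data.frame(channel = train$channel, n_spikes = length(train$times),
             freq_hz = length(train$times) / dur)
}

#' Select the most active channels
#'
#' Channels with frequency above `max_hz` (abnormally high activity) are
#' excluded first; the remainder are ranked by frequency, descending, with
#' ties broken by ascending channel id, and the top `top_n` kept.
#'
#' @param activities data.frame with columns `channel` and `freq_hz` (one row
#'   per channel), e.g. from rbinding [channel_frequency()] results.
#' @param top_n number of channels to keep.
#' @param max_hz exclusion threshold, Hz (strict: `> max_hz` is excluded).
#' @return the selected rows of `activities`, ranked.
#' @export
select_channels <- function(activities, top_n = 30, max_hz = 5) {
  stopifnot(is.data.frame(activities),
            all(c("channel", "freq_hz") %in% names(activities)))
  if (nrow(activities) == 0) stop("at least one channel required")
  keep <- activities[activities$freq_hz <= max_hz, , drop = FALSE]
  ord <- order(-keep$freq_hz, keep$channel)
  keep <- keep[ord, , drop = FALSE]
  utils::head(keep, top_n)
}

#' Organoid-level activity summary
#'
#' Mean firing frequency over the selected channels, with the inclusion flag
#' used for downstream group statistics: organoids whose mean frequency falls
#' below `min_rate` lack activity and are excluded (boundary convention:
#' exactly `min_rate` is included).
#'
#' @param selection data.frame from [select_channels()].
#' @param organoid organoid identifier.
#' @param min_rate minimum mean frequency, Hz.
#' @return list with `organoid`, `channels`, `freqs`, `mean_freq`, `included`.
#' @export
organoid_summary <- function(selection, organoid = NA, min_rate = 0.5) {
  if (!is.data.frame(selection) || nrow(selection) == 0)
    stop("empty channel selection")
  mean_freq <- mean(selection$freq_hz)
  list(organoid = organoid, channels = selection$channel,
       freqs = selection$freq_hz, mean_freq = mean_freq,
       included = mean_freq >= min_rate)
}
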