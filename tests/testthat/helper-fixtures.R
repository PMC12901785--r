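# Shared fixtures, built in code. Sizes are desk-scale; the generators are the
# package's own synthetic-data module, so these double as integration points.

# small recording used by several signal/spike tests (memoized per test run)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- mea_sim_config(n_channels = 6, duration = 10,
                            active_fraction = 0.5, rate_hz = 1,
                            spike_amp = 80, noise_sd = 10, flash_rate = 0.2,
                            seed = 42)
      cache <<- generate_mea_recording(cfg)
    }
    cache
  }
})

# brute-force moving-window mean/SD oracle (independent per-window loop)
oracle_threshold <- function(trace, fs, window_ms = 5, k = 5, mask = NULL,
                             guard_ms = 0, sd_floor = 0) {
  n <- length(trace)
  if (is.null(mask)) mask <- rep(TRUE, n)
  w <- floor(window_ms * fs / 1000)
  g <- if (guard_ms > 0) round(guard_ms * fs / 1000) else -1
  up <- lo <- ctr <- sdv <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    win <- max(1, i - ((w - 1) %/% 2)):min(n, i + (w %/% 2))
    if (g >= 0) win <- setdiff(win, max(1, i - g):min(n, i + g))
    vals <- trace[win][mask[win]]
    if (length(vals) < 2) next
    ctr[i] <- mean(vals)
    sdv[i] <- max(sd(vals), sd_floor)
    up[i] <- ctr[i] + k * sdv[i]
    lo[i] <- ctr[i] - k * sdv[i]
  }
  list(center = ctr, sd = sdv, upper = up, lower = lo)
}

# naive event-count oracle: threshold crossings -> runs -> refractory merge
oracle_event_count <- function(trace, fs, window_ms = 5, k = 5, mask = NULL,
                               refractory_ms = 1, guard_ms = 1,
                               robust_floor = TRUE) {
  n <- length(trace)
  if (is.null(mask)) mask <- rep(TRUE, n)
  fl <- if (robust_floor) mad(trace[mask]) else 0
  thr <- oracle_threshold(trace, fs, window_ms, k, mask, guard_ms, fl)
  exceed <- !is.na(thr$sd) & mask &
    (trace > thr$upper | trace < thr$lower)
  ref <- max(1, round(refractory_ms * fs / 1000))
  count <- 0L
  last_end <- -Inf
  i <- 1
  while (i <= n) {
    if (exceed[i]) {
      j <- i
      while (j < n && exceed[j + 1]) j <- j + 1
      if (i - last_end - 1 < ref && count > 0) {
        # merges into the previous event
      } else count <- count + 1L
      last_end <- j
      i <- j + 1
    } else i <- i + 1
  }
  count
}

# exhaustive hypergeometric upper tail by subset enumeration (N small)
oracle_hyper_tail <- function(x, n1, n2, N) {
  set1 <- seq_len(n1)
  subsets <- utils::combn(N, n2)
  overlaps <- apply(subsets, 2, function(s) sum(s %in% set1))
  mean(overlaps >= x)
}
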