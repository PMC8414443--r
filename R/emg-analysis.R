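#' Condition a raw EMG trace
#'
#' Zero-phase digital equivalent of standard acquisition settings: a 40-4000
#' Hz 4th-order Butterworth band-pass applied forward-backward
#' ([signal::filtfilt()]), followed by a 60 Hz notch (biquad, Q = 30, also
#' zero-phase), then mean-centering. Zero-phase filtering is used so burst
#' onset times are not biased by filter group delay.
#'
#' @param x numeric signal vector.
#' @param sampling_rate_hz sampling rate; must exceed 8000 Hz so the 4000 Hz
#'   band edge is below Nyquist.
#' @param band band-pass edges, Hz.
#' @param notch_hz notch center frequency (default 60); `NULL` disables.
#' @param notch_q notch quality factor (default 30).
#' @return conditioned signal, same length as `x`.
#' @export
condition_signal <- function(x, sampling_rate_hz, band = c(40, 4000),
                             notch_hz = 60, notch_q = 30) {
  if (sampling_rate_hz <= 8000) stop("sampling rate must exceed 8000 Hz")
  if (band[2] >= sampling_rate_hz / 2) {
    stop("band-pass upper edge must be below the Nyquist frequency")
  }
  # reflect the signal at both ends so filter start-up transients fall in
  # the padding, not the data (the notch rings for ~Q/f0 seconds)
  n <- length(x)
  np <- min(n - 1, round(sampling_rate_hz))
  xp <- c(2 * x[1] - x[(np + 1):2], x, 2 * x[n] - x[(n - 1):(n - np)])
  bp <- signal::butter(4, band / (sampling_rate_hz / 2), type = "pass")
  y <- signal::filtfilt(bp, xp)
  if (!is.null(notch_hz)) {
    w0 <- 2 * pi * notch_hz / sampling_rate_hz
    alpha <- sin(w0) / (2 * notch_q)
    b <- c(1, -2 * cos(w0), 1)
    a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
    y <- signal::filtfilt(b / a[1], a / a[1], y)
  }
  y <- y[(np + 1):(np + n)]
  y - mean(y)
}

#' Condition all channels of a recording
#' @param rec an `emg_recording`.
#' @param ... passed to [condition_signal()].
#' @return the recording with every channel conditioned.
#' @export
condition_recording <- function(rec, ...) {
  rec$signals <- apply(rec$signals, 2, condition_signal,
                       sampling_rate_hz = rec$sampling_rate_hz, ...)
  rec
}

#' Per-electrode experimental maximum (EMG_ExpMax)
#'
#' Maximum rectified conditioned amplitude per channel across all trials of
#' one individual: the normalization constant for RIA. Adding a trial can
#' never decrease it.
#'
#' @param trials list of conditioned `emg_recording`s from one individual.
#' @param channels channels to include (default: all in the first trial).
#' @return named numeric vector of per-channel maxima (strictly positive).
#' @export
find_expmax <- function(trials, channels = NULL) {
  if (!length(trials)) stop("need at least one trial")
  channels <- channels %||% colnames(trials[[1]]$signals)
  out <- vapply(channels, function(ch) {
    vals <- vapply(trials, function(rec) {
      if (!ch %in% colnames(rec$signals)) {
        stop(sprintf("channel %s absent from a trial", ch))
      }
      v <- rec$signals[, ch]
      if (!length(v) || all(!is.finite(v))) stop("empty channel ", ch)
      max(abs(v), na.rm = TRUE)
    }, numeric(1))
    max(vals)
  }, numeric(1))
  if (any(out <= 0)) stop("EMG_ExpMax must be strictly positive")
  out
}

#' Normalized rectified integrated area of a burst (RIA %)
#'
#' The trapezoidal integral of the rectified signal over the burst window,
#' expressed as a percentage of the theoretical maximum RIA
#' (EMG_ExpMax x burst duration). A burst that saturates at EMG_ExpMax for
#' its whole duration scores 100%.
#'
#' @param x conditioned signal.
#' @param sampling_rate_hz sampling rate, Hz.
#' @param onset_s,offset_s burst window, seconds from the first sample.
#' @param expmax the channel's EMG_ExpMax (> 0).
#' @return RIA as % of theoretical maximum.
#' @export
compute_ria <- function(x, sampling_rate_hz, onset_s, offset_s, expmax) {
  if (offset_s <= onset_s) stop("zero- or negative-length burst")
  if (expmax <= 0) stop("expmax must be > 0")
  n <- length(x)
  i0 <- floor(onset_s * sampling_rate_hz) + 1
  i1 <- ceiling(offset_s * sampling_rate_hz) + 1
  if (i0 < 1 || i1 > n) stop("burst window outside the recorded signal")
  tt <- (seq(i0, i1) - 1) / sampling_rate_hz
  # clip the end samples to the exact window by linear interpolation
  xa <- abs(x[i0:i1])
  tt[1] <- onset_s; tt[length(tt)] <- offset_s
  100 * trapz(tt, xa) / (expmax * (offset_s - onset_s))
}

#' EMG duty factor
#'
#' Burst duration as a percentage of the tail-beat cycle duration, using the
#' period of the cycle containing the burst onset.
#'
#' @param onset_s,offset_s burst window, s.
#' @param cycle_period_s duration of the cycle containing the onset, s.
#' @return duty factor, % of cycle.
#' @export
duty_factor <- function(onset_s, offset_s, cycle_period_s) {
  if (any(cycle_period_s <= 0)) stop("cycle period must be > 0")
  100 * (offset_s - onset_s) / cycle_period_s
}

#' EMG onset-curvature phase lag
#'
#' Timing of muscle-burst onset relative to the nearest same-side curvature
#' maximum at the electrode's body position, as a percentage of the
#' tail-beat cycle, wrapped into (-50, 50]. Negative = onset precedes
#' maximum curvature. Returns `NA` when no same-side maximum lies within
#' `window` cycles of the onset.
#'
#' @param onset_s burst onset, s.
#' @param curvature_max_times_s times of same-side curvature maxima at the
#'   electrode position (see `max_curvature_per_cycle` columns
#'   `t_max_left` / `t_max_right`).
#' @param cycle_period_s local cycle period, s.
#' @param window search window, in cycles (default 0.75).
#' @return phase lag, % cycle, in (-50, 50], or `NA`.
#' @export
phase_lag <- function(onset_s, curvature_max_times_s, cycle_period_s,
                      window = 0.75) {
  if (!length(curvature_max_times_s)) return(NA_real_)
  d <- onset_s - curvature_max_times_s
  i <- which.min(abs(d))
  if (abs(d[i]) > window * cycle_period_s) return(NA_real_)
  lag <- 100 * d[i] / cycle_period_s
  lag <- ((lag + 50) %% 100) - 50
  if (lag == -50) lag <- 50
  lag
}

#' Annotation-free burst detection
#'
#' Detects bursts from a smoothed rectified envelope (RMS, 10 ms window).
#' The threshold is the baseline median plus 3 MADs, both estimated from
#' the quietest quartile of the envelope. Supra-threshold runs shorter than
#' 15 ms are dropped, runs separated by gaps under 10 ms are merged, runs
#' whose envelope peak does not also clear a 6-MAD confirmation level are
#' discarded (two-threshold detection), and at most one burst is kept per
#' tail-beat cycle (the one with the largest rectified integral). Onset and
#' offset are then refined from each burst's envelope foot. A flat signal
#' yields an empty table.
#'
#' @param rec a conditioned `emg_recording`.
#' @param cycles a `cycle_set` (video time; `rec$sync_offset_s` aligns the
#'   clocks).
#' @param channels channels to scan (default: all).
#' @param rms_window_s,min_duration_s,merge_gap_s detector constants.
#' @return A `burst_table`: data.frame with `channel`, `onset_s`,
#'   `offset_s`, `cycle_index`.
#' @export
detect_bursts <- function(rec, cycles, channels = NULL,
                          rms_window_s = 0.010, min_duration_s = 0.015,
                          merge_gap_s = 0.010) {
  channels <- channels %||% colnames(rec$signals)
  fs <- rec$sampling_rate_hz
  out <- list()
  for (ch in channels) {
    x <- rec$signals[, ch]
    env <- sqrt(moving_average(x^2, round(rms_window_s * fs)))
    if (max(env) - min(env) < 1e-12) next  # flat signal
    # baseline = the quietest quartile of the envelope, located by coarse
    # 50 ms windows so the pooled sample keeps its natural spread
    wlen <- max(1L, round(0.050 * fs))
    nwin <- floor(length(env) / wlen)
    wid <- rep(seq_len(nwin), each = wlen)[seq_len(nwin * wlen)]
    wmed <- tapply(env[seq_len(nwin * wlen)], wid, median)
    quiet <- names(sort(wmed))[seq_len(max(1L, floor(nwin / 4)))]
    base <- env[seq_len(nwin * wlen)][wid %in% as.integer(quiet)]
    base_med <- median(base)
    # floor at 1% of the envelope peak so a noise-free baseline (MAD = 0)
    # does not admit filter-ringing tails
    thr <- max(base_med + 3 * mad(base), base_med + 0.01 * max(env - base_med))
    above <- env > thr
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- data.frame(start = starts[r$values], end = ends[r$values])
    if (!nrow(runs)) next
    # merge runs separated by short gaps
    merged <- runs[1, , drop = FALSE]
    if (nrow(runs) > 1) {
      for (i in 2:nrow(runs)) {
        gap <- (runs$start[i] - merged$end[nrow(merged)]) / fs
        if (gap < merge_gap_s) {
          merged$end[nrow(merged)] <- runs$end[i]
        } else {
          merged <- rbind(merged, runs[i, ])
        }
      }
    }
    dur <- (merged$end - merged$start + 1) / fs
    merged <- merged[dur >= min_duration_s, , drop = FALSE]
    if (!nrow(merged)) next
    # two-threshold confirmation: a genuine burst's envelope peak stands
    # far above baseline, while marginal noise runs do not
    confirm <- base_med + max(6 * mad(base), 0.05 * (max(env) - base_med))
    peak_ok <- vapply(seq_len(nrow(merged)), function(i) {
      max(env[merged$start[i]:merged$end[i]]) >= confirm
    }, logical(1))
    merged <- merged[peak_ok, , drop = FALSE]
    if (!nrow(merged)) next
    # refine each burst's edges: walk out from the envelope peak to the 20%
    # crossing, then extrapolate along the local slope to the envelope foot
    # (removes the threshold-crossing lateness and stray baseline runs)
    edges <- t(vapply(seq_len(nrow(merged)), function(i) {
      refine_burst_edges(env, merged$start[i], merged$end[i], base_med, fs)
    }, numeric(2)))
    dur_total <- (length(env) - 1) / fs
    onset <- pmax(0, edges[, 1]) - rec$sync_offset_s
    offset <- pmin(dur_total, edges[, 2]) - rec$sync_offset_s
    strength <- vapply(seq_len(nrow(merged)), function(i) {
      sum(abs(x[merged$start[i]:merged$end[i]]))
    }, numeric(1))
    ci <- cycle_at(cycles, onset)
    keep <- rep(TRUE, length(onset))
    for (u in unique(ci[!is.na(ci)])) {
      dup <- which(!is.na(ci) & ci == u)
      if (length(dup) > 1) keep[dup[-which.max(strength[dup])]] <- FALSE
    }
    keep <- keep & !is.na(ci)
    if (any(keep)) {
      out[[length(out) + 1L]] <- data.frame(
        channel = ch, onset_s = onset[keep], offset_s = offset[keep],
        cycle_index = ci[keep])
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(channel = character(0), onset_s = numeric(0),
               offset_s = numeric(0), cycle_index = integer(0))
  class(res) <- c("burst_table", "data.frame")
  res
}

# Onset/offset localization for one supra-threshold run. Walking outward
# from the envelope peak, the edge is the first sample below
# base + 0.2 (peak - base); a first-order extrapolation along the local
# envelope slope then projects to the envelope foot. Returns times (s) of
# (onset, offset).
refine_burst_edges <- function(env, i0, i1, base, fs) {
  seg <- env[i0:i1]
  ip <- i0 - 1L + which.max(seg)
  peak <- env[ip]
  level <- base + 0.2 * (peak - base)
  slope_win <- max(2L, round(0.004 * fs))
  edge <- function(dir) {
    i <- ip
    lim <- if (dir < 0) max(1L, i0 - round(0.05 * fs)) else
      min(length(env), i1 + round(0.05 * fs))
    while (i != lim && env[i] > level) i <- i + dir
    # local slope of the envelope just inside the crossing
    j <- i - dir * slope_win
    sl <- abs(env[j] - env[i]) / (slope_win / fs)
    t_cross <- (i - 1) / fs
    t_ex <- if (sl > 0) t_cross + dir * min(2 * (level - base) / sl, 0.015) else
      t_cross
    # never extrapolate past the raw run edge by more than 2 ms: the raw
    # edge is near-exact at low noise, while merged baseline runs push it
    # outward, in which case the extrapolated foot is the better estimate
    t_raw <- (if (dir < 0) i0 - 1 else i1 - 1) / fs + dir * 0.002
    if (dir < 0) max(t_ex, t_raw) else min(t_ex, t_raw)
  }
  c(edge(-1L), edge(+1L))
}

#' Load manually annotated burst windows
#'
#' CSV with columns `channel`, `onset_s`, `offset_s`. Rows are validated
#' (onset < offset, inside the recording, no overlap within a channel) and
#' sorted; violations are reported with the offending row number.
#'
#' @param path CSV path.
#' @param rec optional `emg_recording` to cross-check window ranges against.
#' @return A `burst_table` skeleton (no metrics yet).
#' @export
load_burst_annotations <- function(path, rec = NULL) {
  df <- read.csv(path)
  need <- c("channel", "onset_s", "offset_s")
  if (!all(need %in% names(df))) {
    stop("burst annotation CSV must have columns: ", paste(need, collapse = ", "))
  }
  bad <- which(df$offset_s <= df$onset_s)
  if (length(bad)) stop("offset <= onset in row(s): ", paste(bad, collapse = ", "))
  if (!is.null(rec)) {
    out <- which(df$onset_s < 0 | df$offset_s > rec$duration_s)
    if (length(out)) {
      stop("burst outside the recording in row(s): ", paste(out, collapse = ", "))
    }
  }
  df <- df[order(df$channel, df$onset_s), ]
  for (ch in unique(df$channel)) {
    sub <- df[df$channel == ch, ]
    if (nrow(sub) > 1 && any(sub$onset_s[-1] < sub$offset_s[-nrow(sub)])) {
      stop("overlapping bursts on channel ", ch)
    }
  }
  df$cycle_index <- NA_integer_
  class(df) <- c("burst_table", "data.frame")
  df
}

#' Full burst metrics for a trial
#'
#' Computes duty factor, RIA% and onset-curvature phase lag for every burst
#' in a table, using the recording's electrode map to pick each channel's
#' body position and side for the phase-lag reference.
#'
#' @param bursts a `burst_table` ([detect_bursts()] or
#'   [load_burst_annotations()]).
#' @param rec the conditioned `emg_recording`.
#' @param cf a `curvature_field` for the trial.
#' @param cycles a `cycle_set`.
#' @param expmax named per-channel EMG_ExpMax vector ([find_expmax()]).
#' @return the burst table with `duty_factor_pct`, `ria_pct`,
#'   `phase_lag_pct` columns filled (phase lag `NA` for fin channels).
#' @export
burst_metrics <- function(bursts, rec, cf, cycles, expmax) {
  el <- rec$electrode_map
  n <- nrow(bursts)
  bursts$duty_factor_pct <- NA_real_
  bursts$ria_pct <- NA_real_
  bursts$phase_lag_pct <- NA_real_
  if (!n) return(bursts)
  maxima <- list()
  for (i in seq_len(n)) {
    ch <- bursts$channel[i]
    j <- match(ch, el$channel)
    if (is.na(j)) stop("channel ", ch, " not in electrode map")
    ci <- cycle_at(cycles, bursts$onset_s[i])
    period <- if (!is.na(ci)) cycles$periods_s[ci] else mean(cycles$periods_s)
    bursts$cycle_index[i] <- ci
    bursts$duty_factor_pct[i] <- duty_factor(bursts$onset_s[i],
                                             bursts$offset_s[i], period)
    bursts$ria_pct[i] <- compute_ria(
      rec$signals[, ch], rec$sampling_rate_hz,
      bursts$onset_s[i] + rec$sync_offset_s,
      bursts$offset_s[i] + rec$sync_offset_s, expmax[[ch]])
    if (el$side[j] %in% c("left", "right")) {
      key <- paste(el$position_bl[j], el$side[j])
      if (is.null(maxima[[key]])) {
        maxima[[key]] <- curvature_max_times(cf, el$position_bl[j] * 100,
                                             side = el$side[j])$time
      }
      bursts$phase_lag_pct[i] <- phase_lag(bursts$onset_s[i], maxima[[key]],
                                           period)
    }
  }
  bursts
}
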