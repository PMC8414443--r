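#' Segment tail-beat cycles from tail lateral motion
#'
#' A cycle starts when the tail tip starts moving toward the fish's right
#' (0% of the cycle; 50% is the tail starting back to the left). The tail
#' tip's lateral displacement is measured in a per-frame body frame whose
#' lateral axis is perpendicular to the nose-to-20%-BL chord, positive
#' toward the fish's right; cycle boundaries are the upward zero crossings
#' of its smoothed time derivative. Incomplete cycles at the edges of the
#' recording are discarded, and a trial is rejected unless it contains at
#' least three complete cycles.
#'
#' @param ml a [midline_sequence()].
#' @param smooth_window velocity-smoothing window in frames (default 5,
#'   sized for 250 fps video; scale with frame rate for other cameras).
#' @return Object of class `cycle_set`: list with `boundaries` (1-based
#'   frame indices at/after each cycle start), `times_s` (interpolated
#'   boundary times), `periods_s`, `n_cycles`.
#' @export
segment_cycles <- function(ml, smooth_window = 5) {
  lat <- lateral_displacement(ml, s_point = 1)
  if (sd(lat) < 1e-9) stop("tail does not oscillate; trial rejected")
  t <- frame_times(ml)
  dt <- 1 / ml$frame_rate_hz
  vel <- c(NA, diff(lat)) / dt
  vel[1] <- vel[2]
  vel <- moving_average(vel, smooth_window)
  # upward zero crossings of lateral velocity = tail starts moving right
  n <- length(vel)
  i <- which(vel[-n] < 0 & vel[-1] >= 0)
  times <- t[i] + (0 - vel[i]) / (vel[i + 1] - vel[i]) * dt
  if (length(times) < 4) {
    stop(sprintf(
      "fewer than 3 complete tail-beat cycles (%d boundaries found); trial rejected",
      length(times)))
  }
  structure(list(boundaries = i + 1L, times_s = times,
                 periods_s = diff(times),
                 n_cycles = length(times) - 1L),
            class = "cycle_set")
}

#' @export
print.cycle_set <- function(x, ...) {
  cat(sprintf("<cycle_set> %d complete cycles; mean period %.4f s (f = %.2f Hz)\n",
              x$n_cycles, mean(x$periods_s), 1 / mean(x$periods_s)))
  invisible(x)
}

# Index of the cycle containing time t (NA outside all cycles).
cycle_at <- function(cycles, t) {
  i <- findInterval(t, cycles$times_s)
  ifelse(i >= 1 & i <= cycles$n_cycles, i, NA_integer_)
}
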