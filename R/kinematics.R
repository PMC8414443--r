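#' Per-cycle maximum body curvature at chosen positions
#'
#' For each tail-beat cycle and body position, the maximum of |kappa| over
#' the cycle (value and time, parabolic sub-frame interpolation around the
#' discrete peak), plus the times of the same-side curvature maxima on each
#' side (left: peak of +kappa, right: peak of -kappa) needed by the EMG
#' onset-curvature phase lag. Equal discrete peaks resolve to the earlier
#' one.
#'
#' @param cf a `curvature_field` from [compute_curvature()].
#' @param cycles a `cycle_set` from [segment_cycles()].
#' @param positions_pct body positions, % BL; must lie in the unmasked zone.
#' @return data.frame with columns `cycle`, `position_pct`, `max_abs_kappa`,
#'   `t_max_abs`, `t_max_left`, `t_max_right`.
#' @export
max_curvature_per_cycle <- function(cf, cycles, positions_pct) {
  out <- list()
  for (pos in positions_pct) {
    j <- grid_column(cf, pos)
    kap <- cf$kappa[, j]
    for (ci in seq_len(cycles$n_cycles)) {
      t0 <- cycles$times_s[ci]; t1 <- cycles$times_s[ci + 1]
      inwin <- which(cf$times_s >= t0 & cf$times_s < t1)
      if (length(inwin) < 3) next
      seg <- kap[inwin]; tt <- cf$times_s[inwin]
      pk_abs <- refine_peak(abs(seg), tt)
      pk_l <- refine_peak(seg, tt)
      pk_r <- refine_peak(-seg, tt)
      out[[length(out) + 1L]] <- data.frame(
        cycle = ci, position_pct = pos,
        max_abs_kappa = pk_abs$value, t_max_abs = pk_abs$time,
        t_max_left = pk_l$time, t_max_right = pk_r$time)
    }
  }
  do.call(rbind, out)
}

# Maximum of a short series with parabolic refinement; earliest wins ties.
refine_peak <- function(x, t) {
  i <- which.max(x)
  if (i > 1 && i < length(x)) {
    denom <- x[i - 1] - 2 * x[i] + x[i + 1]
    if (is.finite(denom) && denom < 0) {
      d <- 0.5 * (x[i - 1] - x[i + 1]) / denom
      d <- min(max(d, -0.5), 0.5)
      dt <- (t[length(t)] - t[1]) / (length(t) - 1)
      return(list(time = t[i] + d * dt,
                  value = x[i] - 0.25 * (x[i - 1] - x[i + 1]) * d))
    }
  }
  list(time = t[i], value = x[i])
}

#' Body wave speed from curvature-crest transit through body sections
#'
#' Speed of the traveling wave of maximum body curvature through a body
#' section, per half-cycle. The crest of same-sign curvature passes a body
#' position exactly when the curvature time series at that position peaks,
#' so each transit is timed from the same-sign curvature peak at the
#' section's entry position to the matching peak at its exit position
#' (parabolic sub-frame refinement; the series is smoothed over ~40 ms
#' first, which leaves peak times unbiased). Speed = section width /
#' transit time; the per-cycle value is the mean over the cycle's two
#' half-waves (left- and right-concave crests). Crests that do not
#' traverse the whole section yield `NA` with a warning.
#'
#' When a section endpoint coincides with the edge of the unmasked grid
#' (e.g. 95% BL with the default 5% mask), the nearest unmasked segment
#' center is used and the traversed width shortened accordingly.
#'
#' @param cf a `curvature_field`.
#' @param cycles a `cycle_set`.
#' @param sections list of 2-vectors, % BL (default the three standard
#'   sections 35-55, 55-75, 75-95% BL).
#' @return data.frame with columns `cycle`, `section`, `wave_speed_bl_s`.
#' @export
wave_speed <- function(cf, cycles,
                       sections = list(c(35, 55), c(55, 75), c(75, 95))) {
  usable <- which(!cf$mask)
  glo <- cf$body_grid[usable[1]]
  ghi <- cf$body_grid[usable[length(usable)]]
  dg <- 100 / cf$n_segments
  out <- list()
  for (sec in sections) {
    lab <- sprintf("%g-%g", sec[1], sec[2])
    if (sec[1] < glo - dg / 2 - 1e-9 || sec[2] > ghi + dg / 2 + 1e-9) {
      stop(sprintf("section %s%% BL extends into the masked zone", lab))
    }
    j_lo <- grid_column(cf, max(sec[1], glo))
    j_hi <- grid_column(cf, min(sec[2], ghi))
    width_bl <- (cf$body_grid[j_hi] - cf$body_grid[j_lo]) / 100
    transits <- rbind(
      section_transits(cf, j_lo, j_hi, +1),
      section_transits(cf, j_lo, j_hi, -1))
    for (ci in seq_len(cycles$n_cycles)) {
      t0 <- cycles$times_s[ci]; t1 <- cycles$times_s[ci + 1]
      mid <- (transits$t_lo + transits$t_hi) / 2
      hit <- which(mid >= t0 & mid < t1)
      if (!length(hit)) {
        warning(sprintf(
          "no curvature crest traversed section %s%% BL in cycle %d", lab, ci))
        v <- NA_real_
      } else {
        v <- mean(width_bl / (transits$t_hi[hit] - transits$t_lo[hit]))
      }
      out[[length(out) + 1L]] <- data.frame(
        cycle = ci, section = lab, wave_speed_bl_s = v)
    }
  }
  do.call(rbind, out)
}

# Match same-sign curvature peaks at the entry column to the next peak at
# the exit column; returns one row per completed transit.
section_transits <- function(cf, j_lo, j_hi, sign) {
  p_lo <- robust_peaks(sign * cf$kappa[, j_lo], cf$times_s, cf$frame_rate_hz)
  p_hi <- robust_peaks(sign * cf$kappa[, j_hi], cf$times_s, cf$frame_rate_hz)
  j_mid <- as.integer(round((j_lo + j_hi) / 2))
  p_mid <- robust_peaks(sign * cf$kappa[, j_mid], cf$times_s,
                        cf$frame_rate_hz)
  if (!nrow(p_lo) || !nrow(p_hi)) {
    return(data.frame(t_lo = numeric(0), t_hi = numeric(0)))
  }
  period <- if (nrow(p_lo) > 1) median(diff(p_lo$time)) else Inf
  # a genuine transit takes at least a couple of frames; simultaneous or
  # antiphase peaks (standing waves) are not propagation
  dt_min <- 1.5 / cf$frame_rate_hz
  rows <- list()
  for (i in seq_len(nrow(p_lo))) {
    after <- p_hi$time[p_hi$time > p_lo$time[i]]
    if (!length(after)) next
    dt <- after[1] - p_lo$time[i]
    if (dt < dt_min || dt > 0.9 * period) next
    # the crest must pass the section midpoint at an intermediate time
    if (nrow(p_mid)) {
      mid_dt <- p_mid$time - p_lo$time[i]
      if (!any(mid_dt > 0.2 * dt & mid_dt < 0.8 * dt)) next
    } else next
    rows[[length(rows) + 1L]] <- data.frame(t_lo = p_lo$time[i],
                                            t_hi = after[1])
  }
  if (!length(rows)) data.frame(t_lo = numeric(0), t_hi = numeric(0)) else
    do.call(rbind, rows)
}

#' Body wave frequency at a body position
#'
#' Mean of the reciprocal peak-to-peak intervals of curvature at the given
#' position (same-sign peaks, i.e. successive left-concave maxima), in
#' cycles/s. Returns `NA` when fewer than two same-sign peaks are present.
#'
#' @param cf a `curvature_field`.
#' @param position_pct body position, % BL (unmasked).
#' @return frequency in cycles/s, or `NA`.
#' @export
body_frequency <- function(cf, position_pct) {
  pk <- curvature_max_times(cf, position_pct, side = "left")
  if (nrow(pk) < 2) return(NA_real_)
  mean(1 / diff(pk$time))
}

#' Swim speed over complete tail-beat cycles
#'
#' Net displacement of the 20% BL body point (the approximate pectoral
#' girdle, chosen over the nose to suppress head-yaw oscillation) across an
#' integer number of complete cycles, divided by the elapsed time. BL/s.
#'
#' @param ml a [midline_sequence()].
#' @param cycles a `cycle_set`.
#' @param s_point reference body point (arc fraction; default 0.2).
#' @return swim speed, BL/s.
#' @export
swim_speed <- function(ml, cycles, s_point = 0.2) {
  traj <- body_point_trajectory(ml, s_point)
  t <- frame_times(ml)
  t0 <- cycles$times_s[1]
  t1 <- cycles$times_s[cycles$n_cycles + 1]
  p0 <- c(approx(t, traj[, 1], xout = t0)$y, approx(t, traj[, 2], xout = t0)$y)
  p1 <- c(approx(t, traj[, 1], xout = t1)$y, approx(t, traj[, 2], xout = t1)$y)
  sqrt(sum((p1 - p0)^2)) / (t1 - t0)
}

#' Reynolds number of a swimming fish
#'
#' \eqn{Re = U L / \nu} with \eqn{U} the swim speed in m/s (speed in BL/s
#' times body length) and \eqn{\nu = \mu / \rho} the kinematic viscosity,
#' so \eqn{Re = U_{BL/s} L^2 \rho / (\mu \times 10^{-3})}. Dimensionless;
#' exactly linear in speed and inversely linear in viscosity.
#'
#' @param speed_bl_s swim speed, BL/s (>= 0).
#' @param body_length_m body length, m.
#' @param viscosity_cp dynamic viscosity, cP (1 cP = 1e-3 Pa s).
#' @param density_kg_m3 water density (default 1000).
#' @return Reynolds number.
#' @examples
#' reynolds_number(0.65, 0.13633, 1)   # ~1.2e4 in plain water
#' @export
reynolds_number <- function(speed_bl_s, body_length_m, viscosity_cp,
                            density_kg_m3 = 1000) {
  if (any(speed_bl_s < 0)) stop("speed must be >= 0")
  if (any(body_length_m <= 0) || any(viscosity_cp <= 0) ||
      any(density_kg_m3 <= 0)) {
    stop("body length, viscosity and density must be positive")
  }
  nu <- (viscosity_cp * 1e-3) / density_kg_m3
  speed_bl_s * body_length_m^2 / nu
}

#' Pectoral fin angle
#'
#' The supplement of the angle at the pectoral girdle (20% BL, `skull_xy`)
#' between the rays to the nose and to the fin-lobe tip: a fin folded flat
#' against the body (tip collinear behind the body axis) scores 0; a fin
#' perpendicular to the body axis scores \eqn{\pi/2}. Radians, in
#' \eqn{[0, \pi]}.
#'
#' @param nose_xy,skull_xy,fin_tip_xy length-2 coordinates (any common
#'   frame/unit); must be pairwise distinct.
#' @return fin angle in radians.
#' @export
fin_angle <- function(nose_xy, skull_xy, fin_tip_xy) {
  a <- nose_xy - skull_xy
  b <- fin_tip_xy - skull_xy
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-12 || nb < 1e-12) stop("coincident landmark points")
  included <- acos(min(1, max(-1, sum(a * b) / (na * nb))))
  pi - included
}

#' Pectoral fin beat frequency
#'
#' Mean reciprocal interval between successive adduction starts, cycles/s.
#' Returns `NA` with fewer than two adduction-start events.
#'
#' @param fin_events a `fin_event_table` (see [read_fin_events()]).
#' @param frame_rate_hz video frame rate, Hz.
#' @return fin frequency, cycles/s, or `NA`.
#' @export
fin_frequency <- function(fin_events, frame_rate_hz) {
  f <- sort(fin_events$frame[fin_events$event_type == "adduction_start"])
  if (length(f) < 2) return(NA_real_)
  mean(1 / (diff(f) / frame_rate_hz))
}

#' Trial-level kinematic summary
#'
#' Runs the whole kinematic stage on one trial: cycle segmentation, swim
#' speed, Reynolds number, per-cycle maximum curvature at the requested
#' positions, wave speed per section, body frequency per position, and (when
#' fin events are given) fin frequency and fin angles at adduction /
#' abduction starts. Per-trial values are means over complete cycles.
#'
#' @param ml a [midline_sequence()].
#' @param viscosity_cp water viscosity, cP.
#' @param body_length_m body length, m.
#' @param positions_pct body positions for curvature/frequency, % BL.
#' @param sections wave-speed sections, % BL.
#' @param fin_events optional `fin_event_table`.
#' @param cf optional precomputed `curvature_field`.
#' @return list of class `kinematic_summary` with per-cycle tables and a
#'   tidy `summary` data.frame (one row per variable x position).
#' @export
kinematic_summary <- function(ml, viscosity_cp, body_length_m,
                              positions_pct = c(20.5, 33.8, 47.6, 59.4, 69.2),
                              sections = list(c(35, 55), c(55, 75), c(75, 95)),
                              fin_events = NULL, cf = NULL) {
  cf <- cf %||% compute_curvature(ml)
  cycles <- segment_cycles(ml)
  speed <- swim_speed(ml, cycles)
  re <- reynolds_number(speed, body_length_m, viscosity_cp)
  maxk <- max_curvature_per_cycle(cf, cycles, positions_pct)
  ws <- wave_speed(cf, cycles, sections)
  bf <- data.frame(
    position_pct = positions_pct,
    frequency_hz = vapply(positions_pct, function(p) body_frequency(cf, p),
                          numeric(1)))
  rows <- list(
    data.frame(variable = "swim_speed_bl_s", position = NA_character_,
               value = speed),
    data.frame(variable = "reynolds", position = NA_character_, value = re))
  agg <- stats::aggregate(max_abs_kappa ~ position_pct, maxk, mean)
  rows <- c(rows, list(data.frame(
    variable = "max_curvature_bl", position = sprintf("%g", agg$position_pct),
    value = agg$max_abs_kappa)))
  wsa <- stats::aggregate(wave_speed_bl_s ~ section, ws, mean, na.rm = TRUE)
  rows <- c(rows, list(data.frame(
    variable = "wave_speed_bl_s", position = wsa$section,
    value = wsa$wave_speed_bl_s)))
  rows <- c(rows, list(data.frame(
    variable = "body_frequency_hz", position = sprintf("%g", bf$position_pct),
    value = bf$frequency_hz)))
  fin <- NULL
  if (!is.null(fin_events)) {
    ff <- fin_frequency(fin_events, ml$frame_rate_hz)
    ang <- fin_event_angles(ml, fin_events)
    fin <- ang
    rows <- c(rows, list(
      data.frame(variable = "fin_frequency_hz", position = NA_character_,
                 value = ff),
      data.frame(variable = "fin_angle_adduction_rad",
                 position = NA_character_,
                 value = mean(ang$angle[ang$event_type == "adduction_start"])),
      data.frame(variable = "fin_angle_abduction_rad",
                 position = NA_character_,
                 value = mean(ang$angle[ang$event_type == "abduction_start"]))))
  }
  structure(list(summary = do.call(rbind, rows), cycles = cycles,
                 max_curvature = maxk, wave_speed = ws, body_frequency = bf,
                 fin_angles = fin),
            class = "kinematic_summary")
}

# Fin angle at each annotated event, using the frame's nose and 20% BL point.
fin_event_angles <- function(ml, fin_events) {
  xy <- midline_bl(ml)
  s <- ml$arc
  ev <- fin_events
  ang <- vapply(seq_len(nrow(ev)), function(i) {
    fr <- min(max(ev$frame[i] + 1L, 1L), ml$n_frames)
    nose <- xy[fr, 1, ]
    p20 <- c(approx(s, xy[fr, , 1], xout = 0.2)$y,
             approx(s, xy[fr, , 2], xout = 0.2)$y)
    tip <- c(ev$x[i], ev$y[i])
    if (ml$unit == "px") tip <- c(tip[1] / ml$body_length, -tip[2] / ml$body_length)
    fin_angle(nose, p20, tip)
  }, numeric(1))
  data.frame(frame = ev$frame, event_type = ev$event_type, angle = ang)
}

#' @export
print.kinematic_summary <- function(x, ...) {
  cat("<kinematic_summary>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
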