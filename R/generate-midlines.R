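#' Generate synthetic traveling-wave midlines
#'
#' Forward model of an inextensible undulating body. Lateral displacement
#' follows \eqn{y(s,t) = A(s)\sin(2\pi(f t - s/\lambda))} with \eqn{s} the
#' arc-length fraction from the nose; the longitudinal coordinate is
#' recovered from \eqn{x'(s) = \sqrt{1 - y'(s)^2}} so every frame has total
#' arc length exactly 1 BL, and the whole body is advected forward at
#' \eqn{U} BL/s (the fish swims toward +x, nose leading). Points are equally
#' spaced in arc length.
#'
#' The construction requires \eqn{|dy/ds| < 1} everywhere, which
#' [swimmer_spec()] enforces.
#'
#' @param spec a [swimmer_spec()].
#' @param n_fine fine integration grid size for the arc-length quadrature.
#' @return A [midline_sequence()] in BL units with attributes `truth` (the
#'   spec) and `source = "synthetic"`.
#' @examples
#' ml <- generate_midlines(swimmer_spec(duration_s = 1))
#' ml
#' @export
generate_midlines <- function(spec, n_fine = 4001) {
  spec <- validate_swimmer_spec(spec)
  tn <- n_synthetic_frames(spec)
  np <- spec$n_body_points
  ts <- (seq_len(tn) - 1) / spec$frame_rate_hz
  s_fine <- seq(0, 1, length.out = n_fine)
  s_out <- seq(0, 1, length.out = np)
  A <- amplitude_envelope(spec, s_fine)
  Ap <- amplitude_envelope_deriv(spec, s_fine)
  k <- 2 * pi / spec$wavelength_bl
  xy <- array(NA_real_, dim = c(tn, np, 2))
  for (i in seq_len(tn)) {
    phase <- 2 * pi * spec$wave_frequency_hz * ts[i] - k * s_fine
    y <- A * sin(phase)
    yp <- Ap * sin(phase) - A * k * cos(phase)
    xp <- sqrt(pmax(0, 1 - yp^2))
    x_back <- cumtrapz(s_fine, xp)             # distance behind the nose
    x_nose <- spec$forward_speed_bl_s * ts[i]
    xy[i, , 1] <- x_nose - approx(s_fine, x_back, xout = s_out)$y
    xy[i, , 2] <- approx(s_fine, y, xout = s_out)$y
  }
  ml <- midline_sequence(xy, spec$frame_rate_hz, body_length = 1, unit = "bl")
  attr(ml, "truth") <- spec
  attr(ml, "source") <- "synthetic"
  ml
}

n_synthetic_frames <- function(spec) {
  as.integer(round(spec$duration_s * spec$frame_rate_hz))
}

# Analytic signed curvature of the generated wave at arc fractions s and
# times t (positive = concave toward the fish's left). For the arc-length
# parameterization, kappa = y'' / sqrt(1 - y'^2).
analytic_curvature <- function(spec, s, t) {
  k <- 2 * pi / spec$wavelength_bl
  p <- spec$amplitude_exponent
  outer(s, t, function(ss, tt) {
    phase <- 2 * pi * spec$wave_frequency_hz * tt - k * ss
    AA <- amplitude_envelope(spec, ss)
    AAp <- amplitude_envelope_deriv(spec, ss)
    AApp <- (spec$amplitude_tail_bl - spec$amplitude_head_bl) *
      p * (p - 1) * ifelse(ss > 0, ss^pmax(p - 2, 0), 0)
    ypp <- AApp * sin(phase) - 2 * AAp * k * cos(phase) - AA * k^2 * sin(phase)
    yp <- AAp * sin(phase) - AA * k * cos(phase)
    ypp / sqrt(pmax(1e-12, 1 - yp^2))
  })
}

#' Generate pectoral-fin event annotations for a synthetic swimmer
#'
#' Adduction starts are placed at the fin-beat period `1/fin_frequency_hz`
#' and abduction starts half a fin cycle later, alternating. The fin-tip
#' coordinate at each event is constructed so that the fin angle (the
#' supplement of the nose / 20% BL / fin-tip angle) equals the spec's
#' adduction or abduction start angle; the fin is drawn on the fish's right.
#'
#' @param ml a synthetic [midline_sequence()] (BL units).
#' @param spec the [swimmer_spec()] that generated it.
#' @param fin_length_bl fin lobe length, BL.
#' @return A `fin_event_table`: data.frame with columns `frame` (0-based),
#'   `event_type` (`"adduction_start"` / `"abduction_start"`), `x`, `y`
#'   (fin-tip, same unit/frame as `ml`).
#' @export
generate_fin_events <- function(ml, spec, fin_length_bl = 0.08) {
  fps <- ml$frame_rate_hz
  duration <- ml$n_frames / fps
  period <- 1 / spec$fin_frequency_hz
  t_add <- seq(0, duration - 1e-9, by = period)
  t_abd <- t_add + period / 2
  ev <- rbind(
    data.frame(time = t_add, event_type = "adduction_start",
               angle = spec$fin_angle_adduction_rad),
    data.frame(time = t_abd, event_type = "abduction_start",
               angle = spec$fin_angle_abduction_rad))
  ev <- ev[ev$time < duration - 0.5 / fps, ]
  ev <- ev[order(ev$time), ]
  ev$frame <- round(ev$time * fps)
  xy <- midline_bl(ml)
  s <- ml$arc
  tip <- t(vapply(seq_len(nrow(ev)), function(i) {
    fr <- ev$frame[i] + 1L
    nose <- xy[fr, 1, ]
    p20 <- c(approx(s, xy[fr, , 1], xout = 0.2)$y,
             approx(s, xy[fr, , 2], xout = 0.2)$y)
    u <- nose - p20
    u <- u / sqrt(sum(u^2))
    included <- pi - ev$angle[i]
    # rotate the skull->nose ray clockwise by `included` so the fin tip
    # lies on the fish's right (y-up frame)
    rot <- matrix(c(cos(included), -sin(included),
                    sin(included), cos(included)), 2, 2)
    p20 + fin_length_bl * as.vector(rot %*% u)
  }, numeric(2)))
  out <- data.frame(frame = as.integer(ev$frame),
                    event_type = ev$event_type,
                    x = tip[, 1], y = tip[, 2])
  class(out) <- c("fin_event_table", "data.frame")
  validate_fin_events(out)
}

validate_fin_events <- function(ev) {
  stopifnot(all(c("frame", "event_type", "x", "y") %in% names(ev)))
  ev <- ev[order(ev$frame), ]
  types <- ev$event_type
  if (length(types) > 1 && any(types[-1] == types[-length(types)])) {
    stop("adduction/abduction starts must alternate in time")
  }
  ev
}

#' Read / write fin-event tables
#'
#' CSV with columns `frame`, `event_type`, `x_px`, `y_px`.
#' @param ev a `fin_event_table`.
#' @param path CSV path.
#' @export
write_fin_events <- function(ev, path) {
  df <- data.frame(frame = ev$frame, event_type = ev$event_type,
                   x_px = ev$x, y_px = ev$y)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fin_events
#' @export
read_fin_events <- function(path) {
  df <- read.csv(path)
  need <- c("frame", "event_type", "x_px", "y_px")
  if (!all(need %in% names(df))) {
    stop("fin event CSV must have columns: ", paste(need, collapse = ", "))
  }
  out <- data.frame(frame = as.integer(df$frame), event_type = df$event_type,
                    x = df$x_px, y = df$y_px)
  class(out) <- c("fin_event_table", "data.frame")
  validate_fin_events(out)
}
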