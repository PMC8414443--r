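#' Specification of a synthetic undulatory swimmer
#'
#' Bundles every ground-truth parameter of the forward model: a traveling
#' wave of lateral displacement \eqn{y(s,t) = A(s)\,\sin(2\pi(f t - s/\lambda))}
#' carried by an inextensible body of unit arc length, advected forward at
#' \eqn{U} BL/s. The amplitude envelope grows toward the tail as
#' \eqn{A(s) = A_{head} + (A_{tail}-A_{head})\,s^p}.
#'
#' Defaults describe a sub-adult bichir-like swimmer in plain water: tail-beat
#' frequency 3.7 Hz, swim speed 0.65 BL/s, body length 136.33 mm. Wavelength
#' and amplitude have no published values for this species; the defaults are
#' plausible anguilliform placeholders (see the methods vignette), not
#' species estimates.
#'
#' @param body_length_mm body length, mm.
#' @param n_body_points number of midline points per frame (>= 20).
#' @param frame_rate_hz video frame rate, Hz. Must exceed twice
#'   `wave_frequency_hz`.
#' @param duration_s trial duration, s.
#' @param wave_frequency_hz tail-beat (body wave) frequency f, Hz.
#' @param wavelength_bl body wavelength \eqn{\lambda}, BL. Ground-truth wave
#'   speed is \eqn{c = f \lambda} BL/s.
#' @param amplitude_head_bl,amplitude_tail_bl amplitude envelope endpoints
#'   A(0), A(1), in BL. Require `0 <= A_head <= A_tail < 0.5`.
#' @param amplitude_exponent envelope exponent p (default 2).
#' @param forward_speed_bl_s forward swimming speed U, BL/s.
#' @param body_width_profile function of arc fraction s in \[0,1\] returning
#'   the local half-width in BL (used only for rasterization). The default is
#'   a tapered fusiform profile, zero at nose and tail tip.
#' @param fin_frequency_hz pectoral-fin beat frequency, Hz (adduction starts).
#' @param fin_angle_adduction_rad,fin_angle_abduction_rad fin angles at the
#'   start of adduction / abduction, radians.
#' @param viscosity_cp water dynamic viscosity, cP.
#' @param seed integer seed consumed by the stochastic layers (EMG noise).
#'
#' @return An object of class `swimmer_spec` (a validated list).
#' @seealso [generate_midlines()], [rasterize_frames()], [synthetic_trial()]
#' @export
swimmer_spec <- function(body_length_mm = 136.33,
                         n_body_points = 101,
                         frame_rate_hz = 250,
                         duration_s = 2,
                         wave_frequency_hz = 3.7,
                         wavelength_bl = 0.65,
                         amplitude_head_bl = 0.02,
                         amplitude_tail_bl = 0.08,
                         amplitude_exponent = 2,
                         forward_speed_bl_s = 0.65,
                         body_width_profile = default_width_profile,
                         fin_frequency_hz = 5.7,
                         fin_angle_adduction_rad = 1.48,
                         fin_angle_abduction_rad = 1.25,
                         viscosity_cp = 1,
                         seed = 1L) {
  spec <- list(
    body_length_mm = body_length_mm, n_body_points = as.integer(n_body_points),
    frame_rate_hz = frame_rate_hz, duration_s = duration_s,
    wave_frequency_hz = wave_frequency_hz, wavelength_bl = wavelength_bl,
    amplitude_head_bl = amplitude_head_bl,
    amplitude_tail_bl = amplitude_tail_bl,
    amplitude_exponent = amplitude_exponent,
    forward_speed_bl_s = forward_speed_bl_s,
    body_width_profile = body_width_profile,
    fin_frequency_hz = fin_frequency_hz,
    fin_angle_adduction_rad = fin_angle_adduction_rad,
    fin_angle_abduction_rad = fin_angle_abduction_rad,
    viscosity_cp = viscosity_cp, seed = as.integer(seed))
  class(spec) <- "swimmer_spec"
  validate_swimmer_spec(spec)
}

validate_swimmer_spec <- function(spec) {
  stopifnot(inherits(spec, "swimmer_spec"))
  with(spec, {
    if (wavelength_bl <= 0) stop("wavelength_bl must be > 0")
    if (!(amplitude_head_bl >= 0 && amplitude_head_bl <= amplitude_tail_bl &&
          amplitude_tail_bl < 0.5)) {
      stop("require 0 <= A_head <= A_tail < 0.5 BL")
    }
    if (frame_rate_hz < 2 * wave_frequency_hz) {
      stop("Nyquist violation: frame_rate_hz must be >= 2 * wave_frequency_hz")
    }
    if (n_body_points < 20) stop("n_body_points must be >= 20")
    if (body_length_mm <= 0 || duration_s <= 0 || viscosity_cp <= 0) {
      stop("body_length_mm, duration_s and viscosity_cp must be positive")
    }
    # inextensible construction needs |dy/ds| < 1 everywhere
    slope <- max_wave_slope(spec)
    if (slope >= 0.95) {
      stop(sprintf(
        "amplitude/wavelength combination too steep (max |dy/ds| = %.2f >= 0.95); the inextensible body construction breaks down",
        slope))
    }
  })
  spec
}

# Upper bound on |dy/ds| of the traveling wave over s and phase.
max_wave_slope <- function(spec) {
  s <- seq(0, 1, length.out = 512)
  A <- amplitude_envelope(spec, s)
  Ap <- amplitude_envelope_deriv(spec, s)
  max(sqrt(Ap^2 + (A * 2 * pi / spec$wavelength_bl)^2))
}

amplitude_envelope <- function(spec, s) {
  spec$amplitude_head_bl +
    (spec$amplitude_tail_bl - spec$amplitude_head_bl) * s^spec$amplitude_exponent
}

amplitude_envelope_deriv <- function(spec, s) {
  p <- spec$amplitude_exponent
  (spec$amplitude_tail_bl - spec$amplitude_head_bl) * p * s^(p - 1)
}

#' Default fusiform half-width profile
#'
#' Half-width of the body, in BL, as a function of arc fraction `s` from the
#' nose: a head-heavy fusiform taper (maximum half-width 0.035 BL at about
#' one third of the body, thin caudal peduncle) ending in points at the nose
#' and tail tip so the skeletonizer can follow the silhouette to its ends.
#' The fore-aft asymmetry is what lets the extraction stage tell the head
#' from the tail without a hint.
#'
#' @param s arc-length fraction(s) in \[0, 1\].
#' @return half-width(s) in BL.
#' @export
default_width_profile <- function(s) {
  s <- pmin(pmax(s, 0), 1)
  0.110 * s^0.6 * (1 - s)^1.2
}

#' @export
print.swimmer_spec <- function(x, ...) {
  cat("<swimmer_spec>\n")
  cat(sprintf("  body length  : %.2f mm, %d midline points\n",
              x$body_length_mm, x$n_body_points))
  cat(sprintf("  wave         : f = %.2f Hz, lambda = %.2f BL (c = %.2f BL/s)\n",
              x$wave_frequency_hz, x$wavelength_bl,
              x$wave_frequency_hz * x$wavelength_bl))
  cat(sprintf("  amplitude    : %.3f -> %.3f BL (p = %g)\n",
              x$amplitude_head_bl, x$amplitude_tail_bl, x$amplitude_exponent))
  cat(sprintf("  speed        : %.2f BL/s; viscosity %.1f cP\n",
              x$forward_speed_bl_s, x$viscosity_cp))
  cat(sprintf("  video        : %.0f fps x %.2f s; seed %d\n",
              x$frame_rate_hz, x$duration_s, x$seed))
  invisible(x)
}

#' Specification of a synthetic multichannel EMG recording
#'
#' Describes electrodes (body position and side), per-electrode burst timing
#' relative to the local same-side curvature maximum, burst duration as a
#' percentage of the tail-beat cycle (duty factor), burst peak amplitude, and
#' the baseline noise floor. The default layout mirrors a typical implant
#' scheme for an elongate fish: five left-side body electrodes from just
#' behind the pectoral fin to just ahead of the anal fin, two matching
#' right-side electrodes, and one pectoral-fin adductor electrode.
#'
#' @param electrodes data.frame with columns `channel` (character),
#'   `position_bl` (body position, fraction of BL in (0,1); ignored for fin
#'   electrodes), `side` (one of `"left"`, `"right"`, `"fin"`).
#' @param onset_phase_pct burst onset relative to the same-side curvature
#'   maximum at the electrode position, in % of cycle; negative = onset
#'   earlier than maximum curvature. Recycled across electrodes.
#' @param duty_factor_pct burst duration in % of cycle, in (0, 100).
#' @param burst_peak_amplitude peak of the raised-cosine burst envelope
#'   (arbitrary units). Recycled.
#' @param noise_floor_sd baseline Gaussian noise SD.
#' @param mains_amplitude amplitude of an optional 60 Hz contaminant (for
#'   filter tests); 0 disables it.
#' @param sampling_rate_hz EMG sampling rate (default 10 kHz). Must exceed
#'   twice the 4000 Hz band-pass upper edge.
#' @param seed integer seed for the noise process.
#' @return An object of class `emg_spec`.
#' @export
emg_spec <- function(electrodes = default_electrode_layout(),
                     onset_phase_pct = -8,
                     duty_factor_pct = 35,
                     burst_peak_amplitude = 1,
                     noise_floor_sd = 0.02,
                     mains_amplitude = 0,
                     sampling_rate_hz = 10000,
                     seed = 1L) {
  n <- nrow(electrodes)
  stopifnot(is.data.frame(electrodes),
            all(c("channel", "position_bl", "side") %in% names(electrodes)))
  if (!all(electrodes$side %in% c("left", "right", "fin"))) {
    stop("electrode side must be 'left', 'right' or 'fin'")
  }
  body <- electrodes$side != "fin"
  if (any(body & (electrodes$position_bl <= 0 | electrodes$position_bl >= 1))) {
    stop("electrode body position must lie strictly inside (0, 1) BL")
  }
  spec <- list(
    electrodes = electrodes,
    onset_phase_pct = rep_len(onset_phase_pct, n),
    duty_factor_pct = rep_len(duty_factor_pct, n),
    burst_peak_amplitude = rep_len(burst_peak_amplitude, n),
    noise_floor_sd = noise_floor_sd,
    mains_amplitude = mains_amplitude,
    sampling_rate_hz = sampling_rate_hz,
    seed = as.integer(seed))
  if (any(spec$duty_factor_pct <= 0 | spec$duty_factor_pct >= 100)) {
    stop("duty_factor_pct must lie strictly inside (0, 100)")
  }
  if (sampling_rate_hz <= 2 * 4000) {
    stop("sampling_rate_hz must exceed twice the 4000 Hz band-pass edge")
  }
  class(spec) <- "emg_spec"
  spec
}

#' Default electrode layout
#'
#' Five left-side body electrodes (20.5, 33.8, 47.6, 59.4, 69.2 % BL), two
#' right-side electrodes matching positions 2 and 4 (34.6, 61.2 % BL), and
#' one right pectoral-fin adductor electrode.
#'
#' @return data.frame with columns `channel`, `position_bl`, `side`.
#' @export
default_electrode_layout <- function() {
  data.frame(
    channel = c("L1", "L2", "L3", "L4", "L5", "R2", "R4", "FIN"),
    position_bl = c(0.205, 0.338, 0.476, 0.594, 0.692, 0.346, 0.612, 0.20),
    side = c(rep("left", 5), "right", "right", "fin"),
    stringsAsFactors = FALSE)
}
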