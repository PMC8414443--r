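# Shared fixtures, built once per test run and cached.

fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_env)) {
    assign(key, force(expr), envir = fixture_env)
  }
  get(key, envir = fixture_env)
}

# Default study-condition swimmer (2 s at 250 fps).
default_trial <- function() {
  cached("default_trial", synthetic_trial(swimmer_spec(), emg_spec()))
}

# Flat-envelope traveling wave: the c = f * lambda identity is exact here.
flat_wave_midlines <- function() {
  cached("flat_ml", generate_midlines(
    swimmer_spec(amplitude_head_bl = 0.06, amplitude_tail_bl = 0.06)))
}

# One rasterized + extracted round trip (stationary fish, kept small).
roundtrip_fixture <- function() {
  cached("roundtrip", {
    spec <- swimmer_spec(duration_s = 1.2, frame_rate_hz = 125,
                         forward_speed_bl_s = 0,
                         amplitude_head_bl = 0.06, amplitude_tail_bl = 0.06,
                         seed = 2)
    ml <- generate_midlines(spec)
    fs <- rasterize_frames(ml)
    list(spec = spec, ml = ml, fs = fs, extracted = extract_midline(fs))
  })
}

# True midline of a round-trip fixture in pixel coordinates of its frames.
truth_in_px <- function(rt, t) {
  cbind((rt$ml$xy[t, , 1] - rt$fs$transform$x0_bl) * rt$fs$px_per_bl,
        (rt$fs$transform$y1_bl - rt$ml$xy[t, , 2]) * rt$fs$px_per_bl)
}

# RMS distance (px) from extracted midline points to the true midline curve.
midline_rms_px <- function(rt, frames) {
  vapply(frames, function(t) {
    ex <- cbind(rt$extracted$xy[t, , 1], rt$extracted$xy[t, , 2])
    tr <- undulaflow:::resample_polyline(truth_in_px(rt, t), 2000)
    sqrt(mean(vapply(seq_len(nrow(ex)), function(i) {
      min(colSums((t(tr) - ex[i, ])^2))
    }, numeric(1))))
  }, numeric(1))
}

# Hand-built curvature field (T x S) for estimator unit tests.
make_cf <- function(kappa, frame_rate_hz, body_grid = NULL, mask_ends = 0.05) {
  S <- ncol(kappa)
  grid <- body_grid %||% ((seq_len(S) - 0.5) / S * 100)
  structure(list(
    kappa = kappa, body_grid = grid,
    mask = grid / 100 < mask_ends | grid / 100 > 1 - mask_ends,
    frame_rate_hz = frame_rate_hz,
    times_s = (seq_len(nrow(kappa)) - 1) / frame_rate_hz,
    n_segments = S), class = "curvature_field")
}

make_cycles <- function(times_s) {
  structure(list(boundaries = integer(length(times_s)),
                 times_s = times_s, periods_s = diff(times_s),
                 n_cycles = length(times_s) - 1L), class = "cycle_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Generating cell means in the shape simulate_trial_summary() expects.
speed_effects <- function() {
  data.frame(viscosity_cp = c(1, 5, 10, 40), mean = c(0.65, 0.42, 0.51, 0.59))
}

wave_speed_effects <- function() {
  eff <- expand.grid(viscosity_cp = c(1, 5, 10, 40),
                     body_position = c("35-55", "55-75", "75-95"),
                     stringsAsFactors = FALSE)
  base <- list("35-55" = c(2.63, 2.19, 2.63, 3.19),
               "55-75" = c(1.86, 1.82, 2.27, 3.15),
               "75-95" = c(3.93, 3.61, 4.51, 6.35))
  eff$mean <- mapply(function(p, v) base[[p]][match(v, c(1, 5, 10, 40))],
                     eff$body_position, eff$viscosity_cp)
  eff
}
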