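# Curvature, cycles, wave speed, frequencies, swim speed, Re, fin metrics.

test_that("curvature of a circular arc is 1/R and of a line is 0", {
  th <- seq(0, 1 / 0.2, length.out = 201)     # unit arc length, R = 0.2 BL
  xy <- array(NA_real_, c(1, 201, 2))
  xy[1, , 1] <- 0.2 * sin(th)
  xy[1, , 2] <- 0.2 * (1 - cos(th))
  cf <- compute_curvature(midline_sequence(xy, 100, 1, unit = "bl"))
  expect_equal(abs(cf$kappa[1, !cf$mask]), rep(5, sum(!cf$mask)),
               tolerance = 0.02)
  xy[1, , 1] <- seq(0, 1, length.out = 201)
  xy[1, , 2] <- 0
  cf0 <- compute_curvature(midline_sequence(xy, 100, 1, unit = "bl"))
  expect_lt(max(abs(cf0$kappa)), 1e-9)
})

test_that("curvature of a sine midline matches the analytic formula", {
  x <- seq(0, 1, length.out = 401)
  poly <- cbind(x, 0.05 * sin(2 * pi * x))
  xy <- array(NA_real_, c(1, 401, 2))
  xy[1, , ] <- undulaflow:::resample_polyline(poly, 401)
  bl <- sum(sqrt(rowSums(diff(xy[1, , ])^2)))
  ml <- midline_sequence(xy, 100, body_length = bl, unit = "bl")
  cf <- compute_curvature(ml)
  # analytic curvature at each segment center's x coordinate (in BL^-1 of
  # the normalized body, i.e. scaled by bl)
  sx <- approx(undulaflow:::arclength(xy[1, , ]) / bl, xy[1, , 1],
               xout = (cf$body_grid / 100))$y
  yp <- 0.05 * 2 * pi * cos(2 * pi * sx)
  ypp <- -0.05 * (2 * pi)^2 * sin(2 * pi * sx)
  # this midline's nose is at x = 0 so its heading is the -x direction;
  # "concave toward the fish's left" therefore flips the sign of the
  # function-graph curvature
  kap_true <- -ypp / (1 + yp^2)^1.5 * bl
  err <- abs(cf$kappa[1, !cf$mask] - kap_true[!cf$mask])
  expect_lt(max(err) / max(abs(kap_true)), 0.02)
  # crest value: |kappa| = 0.05 (2 pi)^2 / ... ~ 1.974 at yp = 0
  expect_equal(max(abs(cf$kappa[1, !cf$mask])) / bl,
               0.05 * (2 * pi)^2, tolerance = 0.02)
})

test_that("curvature needs at least 7 points and flags the 5% end zones", {
  xy <- array(0, c(1, 5, 2)); xy[1, , 1] <- seq(0, 1, length.out = 5)
  ml <- midline_sequence(xy, 100, 1, unit = "bl")
  expect_error(compute_curvature(ml), "at least 7")
  cf <- compute_curvature(flat_wave_midlines())
  expect_true(all(cf$mask[cf$body_grid < 5]))
  expect_true(all(cf$mask[cf$body_grid > 95]))
  expect_error(undulaflow:::grid_column(cf, 2), "masked")
})

test_that("cycle segmentation recovers period, count and rejects flat trials", {
  spec <- swimmer_spec(wave_frequency_hz = 3, duration_s = 1.4)
  cyc <- segment_cycles(generate_midlines(spec))
  expect_equal(mean(cyc$periods_s), 1 / 3, tolerance = 0.01)
  expect_lte(abs(cyc$n_cycles - 3 * 1.4), 1)
  spec54 <- swimmer_spec(wave_frequency_hz = 5.4, duration_s = 2)
  cyc54 <- segment_cycles(generate_midlines(spec54))
  expect_equal(mean(cyc54$periods_s), 0.1852, tolerance = 1 / 250 / 0.1852)
  straight <- generate_midlines(swimmer_spec(amplitude_head_bl = 0,
                                             amplitude_tail_bl = 0,
                                             duration_s = 1))
  expect_error(segment_cycles(straight), "reject")
  short <- generate_midlines(swimmer_spec(wave_frequency_hz = 3.7,
                                          duration_s = 0.6))
  expect_error(segment_cycles(short), "fewer than 3")
})

test_that("per-cycle maximum curvature follows the amplitude envelope", {
  # gentle linear envelope so the analytic A(s) (2 pi / lambda)^2 value
  # is accurate to a few percent
  spec <- swimmer_spec(amplitude_head_bl = 0.05, amplitude_tail_bl = 0.08,
                       amplitude_exponent = 1)
  ml <- generate_midlines(spec)
  cf <- compute_curvature(ml)
  cyc <- segment_cycles(ml)
  pos <- c(30, 50, 70, 90)
  mx <- max_curvature_per_cycle(cf, cyc, pos)
  agg <- aggregate(max_abs_kappa ~ position_pct, mx, mean)
  k <- 2 * pi / spec$wavelength_bl
  env <- undulaflow:::amplitude_envelope(spec, agg$position_pct / 100) * k^2
  expect_equal(agg$max_abs_kappa, env, tolerance = 0.03)
  expect_error(max_curvature_per_cycle(cf, cyc, 2), "masked")
})

test_that("equal discrete curvature peaks resolve to the earlier time", {
  kap <- matrix(0, 11, 100)
  kap[c(3, 8), 50] <- 1               # two equal peaks in one cycle
  cf <- make_cf(kap, frame_rate_hz = 100)
  cyc <- make_cycles(c(0, 0.1))
  mx <- max_curvature_per_cycle(cf, cyc, 50)
  expect_equal(mx$t_max_abs, 0.02)    # frame 3 (0-based time 0.02 s)
})

test_that("wave speed recovers a fabricated 4 BL/s crest transit", {
  # crest passes 35% BL at t = 0.10 s and 55% BL at 0.15 s, cycle 0.3 s
  tt <- (0:119) / 200
  S <- 100
  grid <- (seq_len(S) - 0.5)
  kap <- outer(tt, grid, function(t, s) cos(2 * pi * (t - 0.1 - (s - 35) / 400) / 0.3))
  cf <- make_cf(kap, frame_rate_hz = 200)
  cyc <- make_cycles(c(0.0, 0.3, 0.6))
  ws <- wave_speed(cf, cyc, sections = list(c(35, 55)))
  expect_equal(mean(ws$wave_speed_bl_s, na.rm = TRUE), 4.0, tolerance = 0.02)
})

test_that("a standing wave yields missing wave speeds with a warning", {
  tt <- (0:199) / 200
  grid <- (seq_len(100) - 0.5)
  kap <- outer(tt, grid, function(t, s) sin(2 * pi * t / 0.4) * sin(pi * s / 50))
  cf <- make_cf(kap, frame_rate_hz = 200)
  cyc <- make_cycles(c(0, 0.4, 0.8))
  expect_warning(ws <- wave_speed(cf, cyc, sections = list(c(35, 55))),
                 "no curvature crest")
  expect_true(all(is.na(ws$wave_speed_bl_s)))
})

test_that("sections reaching into the masked zone are refused", {
  cf <- compute_curvature(flat_wave_midlines())
  cyc <- segment_cycles(flat_wave_midlines())
  expect_error(wave_speed(cf, cyc, sections = list(c(2, 20))), "masked")
})

test_that("body frequency reads off curvature oscillations per position", {
  kap <- matrix(0, 400, 100)
  tt <- (0:399) / 200
  kap[, 50] <- sin(2 * pi * 4 * tt)
  cf <- make_cf(kap, frame_rate_hz = 200)
  expect_equal(body_frequency(cf, 50), 4.0, tolerance = 0.01)
  expect_true(is.na(body_frequency(make_cf(matrix(1, 50, 100), 200), 50)))
  spec <- swimmer_spec(wave_frequency_hz = 5.4, duration_s = 2)
  cf54 <- compute_curvature(generate_midlines(spec))
  expect_equal(body_frequency(cf54, 47.6), 5.4, tolerance = 0.02 * 5.4)
})

test_that("body frequency is position-independent on synthetic trials", {
  cf <- compute_curvature(generate_midlines(swimmer_spec()))
  f <- vapply(c(20.5, 33.8, 47.6, 59.4, 69.2, 90),
              function(p) body_frequency(cf, p), numeric(1))
  expect_lt(diff(range(f)) / mean(f), 0.02)
})

test_that("swim speed: rigid translation, station-keeping, forward truth", {
  xy0 <- cbind(seq(0, 1, length.out = 51), rep(0, 51))
  xy <- array(NA_real_, c(26, 51, 2))
  for (t in 1:26) {
    xy[t, , 1] <- xy0[, 1] + 0.3 * (t - 1) / 25
    xy[t, , 2] <- 0
  }
  ml <- midline_sequence(xy, 50, 1, unit = "bl")  # 0.3 BL over 0.5 s
  cyc <- make_cycles(c(0, 0.25, 0.5))
  expect_equal(swim_speed(ml, cyc), 0.6, tolerance = 1e-6)
  still <- generate_midlines(swimmer_spec(forward_speed_bl_s = 0))
  expect_lt(swim_speed(still, segment_cycles(still)), 0.02)
  fwd <- generate_midlines(swimmer_spec(forward_speed_bl_s = 0.59))
  expect_equal(swim_speed(fwd, segment_cycles(fwd)), 0.59, tolerance = 0.03)
})

test_that("Reynolds number is U L^2 rho / mu and scales linearly", {
  expect_equal(reynolds_number(0.65, 0.13633, 1), 1.208e4, tolerance = 0.001)
  expect_equal(reynolds_number(0.65, 0.13633, 40),
               reynolds_number(0.65, 0.13633, 1) / 40)
  expect_equal(reynolds_number(0, 0.13633, 1), 0)
  expect_equal(reynolds_number(1.3, 0.1, 5), 2 * reynolds_number(0.65, 0.1, 5))
  expect_error(reynolds_number(0.5, -1, 1), "positive")
})

test_that("fin angle is the supplement of the nose/girdle/tip angle", {
  expect_equal(fin_angle(c(0, 0), c(1, 0), c(2, 0)), 0, tolerance = 1e-9)
  expect_equal(fin_angle(c(0, 0), c(1, 0), c(1, 1)), pi / 2, tolerance = 1e-9)
  expect_equal(fin_angle(c(0, 0), c(1, 0), c(1.5, 0.5)), pi / 4,
               tolerance = 1e-9)
  expect_error(fin_angle(c(0, 0), c(0, 0), c(1, 1)), "coincident")
})

test_that("fin frequency comes from adduction-start intervals", {
  ev <- data.frame(frame = c(0, 25, 50, 100),
                   event_type = c("adduction_start", "abduction_start",
                                  "adduction_start", "adduction_start"),
                   x = 0, y = 0)
  # frames 0, 50, 100 at 250 fps -> 5 cycles/s
  expect_equal(fin_frequency(ev, 250), 5.0)
  expect_true(is.na(fin_frequency(ev[1:2, ], 250)))
  trial <- synthetic_trial(swimmer_spec(fin_frequency_hz = 7, duration_s = 2,
                                        seed = 3))
  expect_equal(fin_frequency(trial$fin_events, 250), 7.0, tolerance = 0.02 * 7)
  # generated fin events alternate and reproduce the spec'd angles
  ang <- undulaflow:::fin_event_angles(trial$midlines, trial$fin_events)
  expect_equal(mean(ang$angle[ang$event_type == "adduction_start"]), 1.48,
               tolerance = 0.02)
  expect_equal(mean(ang$angle[ang$event_type == "abduction_start"]), 1.25,
               tolerance = 0.02)
})

test_that("kinematic_summary assembles a tidy per-trial table", {
  trial <- default_trial()
  ks <- kinematic_summary(trial$midlines, viscosity_cp = 1,
                          body_length_m = 0.13633,
                          fin_events = trial$fin_events, cf = trial$curvature)
  expect_s3_class(ks$summary, "data.frame")
  vars <- unique(ks$summary$variable)
  expect_true(all(c("swim_speed_bl_s", "reynolds", "max_curvature_bl",
                    "wave_speed_bl_s", "body_frequency_hz",
                    "fin_frequency_hz") %in% vars))
  sp <- ks$summary$value[ks$summary$variable == "swim_speed_bl_s"]
  expect_equal(sp, 0.65, tolerance = 0.03)
  re <- ks$summary$value[ks$summary$variable == "reynolds"]
  expect_equal(re, reynolds_number(sp, 0.13633, 1))
})
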