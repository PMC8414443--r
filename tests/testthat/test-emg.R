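# EMG conditioning, ExpMax, RIA, duty factor, phase lag, burst detection.

test_that("conditioning notches 60 Hz, passes 300 Hz, removes DC", {
  fs <- 10000
  t <- seq(0, 5, by = 1 / fs)
  x60 <- sin(2 * pi * 60 * t)
  y60 <- condition_signal(x60, fs)
  expect_lt(sd(y60) / sd(x60), 0.05)
  x300 <- sin(2 * pi * 300 * t)
  y300 <- condition_signal(x300, fs)
  expect_equal(sd(y300) / sd(x300), 1, tolerance = 0.05)
  ydc <- condition_signal(x300 + 1.0, fs)
  expect_lt(abs(mean(ydc)), 1e-6)
  expect_error(condition_signal(x60, 5000), "8000")
  expect_error(condition_signal(x60, 10000, band = c(40, 6000)), "Nyquist")
})

test_that("EMG_ExpMax is the max over trials and never decreases", {
  mk <- function(peak) {
    structure(list(signals = matrix(c(-peak, peak / 2), 2, 1,
                                    dimnames = list(NULL, "L1")),
                   sampling_rate_hz = 10000,
                   electrode_map = data.frame(channel = "L1",
                                              position_bl = 0.4,
                                              side = "left"),
                   sync_offset_s = 0, duration_s = 2e-4),
              class = "emg_recording")
  }
  trials <- lapply(c(3, 5, 4), mk)
  expect_equal(unname(find_expmax(trials)["L1"]), 5)
  expect_equal(unname(find_expmax(trials[1])["L1"]), 3)
  expect_gte(find_expmax(c(trials, list(mk(2))))["L1"],
             find_expmax(trials)["L1"])
  expect_error(find_expmax(list()), "at least one")
})

test_that("RIA closed forms: constant, half-amplitude and half-sine bursts", {
  fs <- 10000
  n <- fs               # 1 s
  x <- rep(2, n)
  expect_equal(compute_ria(x, fs, 0.2, 0.7, expmax = 2), 100,
               tolerance = 1e-6)
  expect_equal(compute_ria(x / 2, fs, 0.2, 0.7, expmax = 2), 50,
               tolerance = 1e-6)
  tt <- (seq_len(n) - 1) / fs
  on <- 0.2; off <- 0.5
  x <- ifelse(tt >= on & tt <= off, 2 * sin(pi * (tt - on) / (off - on)), 0)
  expect_equal(compute_ria(x, fs, on, off, expmax = 2), 200 / pi,
               tolerance = 0.002)
  expect_error(compute_ria(x, fs, 0.5, 0.5, 2), "zero")
  expect_error(compute_ria(x, fs, 0.9, 1.2, 2), "outside")
})

test_that("duty factor is burst duration as % of the containing cycle", {
  expect_equal(duty_factor(0.1, 0.2, 0.3), 100 / 3, tolerance = 1e-9)
  expect_equal(duty_factor(0, 0.3, 0.3), 100)
  expect_error(duty_factor(0, 0.1, 0), "period")
})

test_that("phase lag is signed, wrapped, and windowed", {
  expect_equal(phase_lag(1.0, c(0.7, 1.0, 1.3), 0.3), 0)
  expect_equal(phase_lag(0.97, 1.0, 0.3), -10)   # 30 ms early, 300 ms cycle
  expect_equal(phase_lag(1.03, 1.0, 0.3), 10)
  # wraps into (-50, 50]
  expect_equal(phase_lag(1.0, 0.85, 0.3, window = 0.75), 50)
  expect_true(is.na(phase_lag(1.0, 3.0, 0.3)))
  expect_true(is.na(phase_lag(1.0, numeric(0), 0.3)))
})

test_that("the end-to-end pipeline recovers burst metrics near truth", {
  trial <- default_trial()
  rec <- condition_recording(trial$emg)
  em <- find_expmax(list(rec))
  bm <- burst_metrics(detect_bursts(rec, trial$cycles), rec,
                      trial$curvature, trial$cycles, em)
  body <- bm[bm$channel %in% c("L2", "L3", "L4"), ]
  expect_equal(mean(body$duty_factor_pct), 35, tolerance = 2.5)
  expect_equal(mean(body$phase_lag_pct), -8, tolerance = 1.5)
  # RIA against the value computed from the true windows
  tb <- attr(trial$emg, "truth_bursts")
  tb <- tb[tb$channel == "L3" & tb$onset_s > 0 &
             tb$offset_s < rec$duration_s, ]
  ria_true <- mean(vapply(seq_len(nrow(tb)), function(i) {
    compute_ria(rec$signals[, "L3"], rec$sampling_rate_hz,
                tb$onset_s[i], tb$offset_s[i], em[["L3"]])
  }, numeric(1)))
  ria_det <- mean(bm$ria_pct[bm$channel == "L3"])
  expect_equal(ria_det, ria_true, tolerance = 5)
  # normalization bound: RIA can never exceed 100
  expect_true(all(bm$ria_pct <= 100))
})

test_that("phase-lag sign convention: earlier onset is negative", {
  trial <- default_trial()   # generated with onset_phase -8
  tb <- attr(trial$emg, "truth_bursts")
  sub <- tb[tb$channel == "L4", ]
  mx <- undulaflow:::curvature_max_times(trial$curvature, 59.4, "left")$time
  lags <- vapply(sub$onset_s, function(o) {
    phase_lag(o, mx, mean(sub$period_s))
  }, numeric(1))
  expect_equal(mean(lags, na.rm = TRUE), -8, tolerance = 1)
  expect_true(all(lags < 0, na.rm = TRUE))
})

test_that("contralateral bursts alternate half a cycle apart", {
  trial <- default_trial()
  tb <- attr(trial$emg, "truth_bursts")
  period <- mean(trial$cycles$periods_s)
  l2 <- sort(tb$onset_s[tb$channel == "L2"])
  r2 <- sort(tb$onset_s[tb$channel == "R2"])
  d <- vapply(l2, function(o) min(abs(o - r2)), numeric(1))
  offs <- (d / period * 100) %% 100
  expect_equal(mean(pmin(offs, 100 - offs)), 50, tolerance = 4)
})

test_that("burst detection: noise-free accuracy, noise robustness, merging", {
  trial <- default_trial()
  es <- emg_spec(seed = 9, noise_floor_sd = 0)
  rec <- condition_recording(
    generate_emg(trial$midlines, es, cf = trial$curvature,
                 cycles = trial$cycles, fin_events = trial$fin_events))
  b <- detect_bursts(rec, trial$cycles)
  tb <- attr(rec, "truth_bursts")
  errs <- vapply(seq_len(nrow(b)), function(i) {
    tt <- tb[tb$channel == b$channel[i], ]
    min(abs(tt$onset_s - b$onset_s[i]))
  }, numeric(1))
  # the burst carrier is stochastic even without baseline noise, so single
  # onsets jitter; the mean localization error stays below 5 ms
  expect_lt(mean(errs), 0.005)
  expect_lt(max(errs), 0.010)
  # pure baseline noise: no bursts in >= 95% of seeds
  el <- default_electrode_layout()[3, ]
  hits <- vapply(1:20, function(sd) {
    es <- emg_spec(electrodes = el, burst_peak_amplitude = 0,
                   noise_floor_sd = 0.02, seed = sd)
    rec <- condition_recording(
      generate_emg(trial$midlines, es, cf = trial$curvature,
                   cycles = trial$cycles))
    nrow(detect_bursts(rec, trial$cycles))
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.95)
  # a flat signal yields an empty table
  flat <- trial$emg
  flat$signals[] <- 0
  expect_equal(nrow(detect_bursts(flat, trial$cycles)), 0)
})

test_that("sub-bursts separated by short gaps are merged", {
  fs <- 10000
  n <- 3 * fs
  set.seed(42)
  x <- 0.01 * rnorm(n)
  put <- function(x, on, dur) {
    ii <- round(on * fs):round((on + dur) * fs)
    x[ii] <- x[ii] + rnorm(length(ii))
    x
  }
  # two sub-bursts 5 ms apart, once per "cycle"
  for (c0 in c(0.5, 1.5, 2.5)) {
    x <- put(x, c0, 0.04)
    x <- put(x, c0 + 0.045, 0.04)
  }
  rec <- structure(list(signals = matrix(x, dimnames = list(NULL, "L1")),
                        sampling_rate_hz = fs,
                        electrode_map = data.frame(channel = "L1",
                                                   position_bl = 0.4,
                                                   side = "left"),
                        sync_offset_s = 0, duration_s = 3),
                   class = "emg_recording")
  cyc <- make_cycles(c(0, 1, 2, 3))
  b <- detect_bursts(rec, cyc)
  expect_equal(nrow(b), 3)
  expect_true(all(b$offset_s - b$onset_s > 0.07))
})

test_that("burst annotations are validated on load", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(channel = c("L1", "L1", "L2"),
                   onset_s = c(0.1, 0.5, 0.2), offset_s = c(0.2, 0.6, 0.35))
  utils::write.csv(df, path, row.names = FALSE)
  b <- load_burst_annotations(path)
  expect_equal(nrow(b), 3)
  expect_false(is.unsorted(b$onset_s[b$channel == "L1"]))
  bad <- df; bad$offset_s[2] <- 0.4   # offset before onset
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(load_burst_annotations(path), "row")
  over <- df; over$onset_s[2] <- 0.15 # overlaps burst 1 on L1
  utils::write.csv(over, path, row.names = FALSE)
  expect_error(load_burst_annotations(path), "overlap")
  rec <- default_trial()$emg
  out <- df; out$offset_s[3] <- 99
  utils::write.csv(out, path, row.names = FALSE)
  expect_error(load_burst_annotations(path, rec), "outside")
})

test_that("EMG CSV + JSON sidecar round-trips a recording", {
  rec <- default_trial()$emg
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_emg(rec, csv, js)
  back <- read_emg(csv, js)
  expect_equal(back$sampling_rate_hz, rec$sampling_rate_hz)
  expect_equal(unname(back$signals[, "L3"]), unname(rec$signals[, "L3"]),
               tolerance = 1e-9)
  expect_equal(back$electrode_map$side, rec$electrode_map$side)
})
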