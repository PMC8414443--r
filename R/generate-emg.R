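#' Generate synthetic EMG phase-locked to body curvature
#'
#' Forward model of a multichannel EMG recording. For every body electrode
#' and tail-beat cycle, one burst of amplitude-modulated Gaussian noise is
#' placed so its onset sits `onset_phase_pct` of a cycle relative to the
#' instant of the same-side curvature maximum at the electrode's body
#' position (negative = onset earlier), with duration `duty_factor_pct` of
#' the local cycle. The burst envelope is a raised cosine with peak
#' `burst_peak_amplitude`, giving unambiguous onset/offset instants.
#' Baseline Gaussian noise (`noise_floor_sd`) covers the rest of the trace;
#' an optional 60 Hz sinusoid can be added for filter tests. Fin-adductor
#' electrodes are locked to fin adduction starts instead.
#'
#' @param ml a synthetic [midline_sequence()] (BL units).
#' @param espec an [emg_spec()].
#' @param cf a `curvature_field` derived from `ml` (computed if `NULL`).
#' @param cycles a `cycle_set` (computed if `NULL`).
#' @param fin_events optional `fin_event_table` for fin electrodes;
#'   generated from the midlines' stored spec when absent and needed.
#' @return Object of class `emg_recording`: list with `signals` (n x C
#'   matrix, one column per channel), `sampling_rate_hz`, `electrode_map`,
#'   `sync_offset_s` (0 for synthetic data), `duration_s`. The ground-truth
#'   burst windows are stored in `attr(,"truth_bursts")`.
#' @export
generate_emg <- function(ml, espec, cf = NULL, cycles = NULL,
                         fin_events = NULL) {
  stopifnot(inherits(espec, "emg_spec"))
  cf <- cf %||% compute_curvature(ml)
  cycles <- cycles %||% segment_cycles(ml)
  fs <- espec$sampling_rate_hz
  duration <- ml$n_frames / ml$frame_rate_hz
  n <- round(duration * fs)
  tt <- (seq_len(n) - 1) / fs
  el <- espec$electrodes
  need_fin <- any(el$side == "fin")
  if (need_fin && is.null(fin_events)) {
    spec <- attr(ml, "truth")
    if (is.null(spec)) stop("fin electrodes need fin_events or a spec-bearing midline")
    fin_events <- generate_fin_events(ml, spec)
  }
  sig <- matrix(NA_real_, n, nrow(el))
  colnames(sig) <- el$channel
  truth <- list()
  with_seed(espec$seed, {
    for (j in seq_len(nrow(el))) {
      x <- espec$noise_floor_sd * rnorm(n)
      if (el$side[j] == "fin") {
        t_ref <- fin_events$frame[fin_events$event_type == "adduction_start"] /
          ml$frame_rate_hz
        periods <- rep(mean(diff(t_ref)), length(t_ref))
      } else {
        pk <- curvature_max_times(cf, el$position_bl[j] * 100,
                                  side = el$side[j])
        t_ref <- pk$time
        ci <- cycle_at(cycles, t_ref)
        periods <- ifelse(is.na(ci), mean(cycles$periods_s),
                          cycles$periods_s[pmax(ci, 1L)])
      }
      onset <- t_ref + espec$onset_phase_pct[j] / 100 * periods
      dur <- espec$duty_factor_pct[j] / 100 * periods
      for (b in seq_along(onset)) {
        i0 <- floor(onset[b] * fs) + 1
        i1 <- ceiling((onset[b] + dur[b]) * fs) + 1
        if (i1 < 1 || i0 > n) next
        ii <- max(1, i0):min(n, i1)
        u <- (tt[ii] - onset[b]) / dur[b]
        env <- ifelse(u >= 0 & u <= 1, 0.5 * (1 - cos(2 * pi * u)), 0)
        x[ii] <- x[ii] + espec$burst_peak_amplitude[j] * env * rnorm(length(ii))
        truth[[length(truth) + 1L]] <- data.frame(
          channel = el$channel[j], onset_s = onset[b],
          offset_s = onset[b] + dur[b], period_s = periods[b])
      }
      if (espec$mains_amplitude > 0) {
        x <- x + espec$mains_amplitude * sin(2 * pi * 60 * tt)
      }
      sig[, j] <- x
    }
  })
  rec <- structure(list(
    signals = sig, sampling_rate_hz = fs,
    electrode_map = el, sync_offset_s = 0, duration_s = duration),
    class = "emg_recording")
  attr(rec, "truth_bursts") <- do.call(rbind, truth)
  rec
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d channels x %.2f s @ %.0f Hz\n",
              ncol(x$signals), x$duration_s, x$sampling_rate_hz))
  print(x$electrode_map, row.names = FALSE)
  invisible(x)
}

#' Write / read EMG recordings
#'
#' CSV with a `time_s` column plus one column per channel, and a JSON
#' sidecar holding the sampling rate, sync offset and electrode map.
#'
#' @param rec an `emg_recording`.
#' @param csv_path,json_path output paths.
#' @export
write_emg <- function(rec, csv_path, json_path) {
  df <- data.frame(time_s = (seq_len(nrow(rec$signals)) - 1) / rec$sampling_rate_hz)
  df <- cbind(df, as.data.frame(rec$signals))
  write.csv(df, csv_path, row.names = FALSE)
  side <- list(sampling_rate_hz = rec$sampling_rate_hz,
               sync_offset_s = rec$sync_offset_s,
               electrode_map = rec$electrode_map)
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' @rdname write_emg
#' @export
read_emg <- function(csv_path, json_path) {
  side <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  df <- read.csv(csv_path)
  chans <- setdiff(names(df), "time_s")
  sig <- as.matrix(df[, chans, drop = FALSE])
  structure(list(signals = sig,
                 sampling_rate_hz = side$sampling_rate_hz,
                 electrode_map = as.data.frame(side$electrode_map),
                 sync_offset_s = side$sync_offset_s %||% 0,
                 duration_s = nrow(sig) / side$sampling_rate_hz),
            class = "emg_recording")
}
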