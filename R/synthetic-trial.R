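#' Generate a complete synthetic trial
#'
#' Runs the whole forward model once: traveling-wave midlines, pectoral-fin
#' events, phase-locked EMG, and (optionally) rasterized silhouette frames.
#' Every ground-truth parameter is kept in `$truth`; regenerating with the
#' same specs is bit-identical.
#'
#' @param spec a [swimmer_spec()].
#' @param espec an [emg_spec()] (default layout and timing when missing).
#' @param rasterize also render binary silhouette frames? (slower, off by
#'   default).
#' @param px_per_bl raster scale when `rasterize = TRUE`.
#' @return Object of class `synthetic_trial`: list with `midlines`,
#'   `fin_events`, `emg`, `frames` (or `NULL`), `curvature`, `cycles`,
#'   `truth` (both specs).
#' @export
synthetic_trial <- function(spec = swimmer_spec(), espec = emg_spec(),
                            rasterize = FALSE, px_per_bl = 800) {
  ml <- generate_midlines(spec)
  cf <- compute_curvature(ml)
  cycles <- segment_cycles(ml)
  fin_events <- generate_fin_events(ml, spec)
  emg <- generate_emg(ml, espec, cf = cf, cycles = cycles,
                      fin_events = fin_events)
  frames <- if (rasterize) {
    rasterize_frames(ml, spec$body_width_profile, px_per_bl = px_per_bl)
  } else NULL
  structure(list(midlines = ml, fin_events = fin_events, emg = emg,
                 frames = frames, curvature = cf, cycles = cycles,
                 truth = list(swimmer = spec, emg = espec)),
            class = "synthetic_trial")
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat("<synthetic_trial>\n")
  print(x$truth$swimmer)
  cat(sprintf("  EMG: %d channels; %d cycles; frames %s\n",
              ncol(x$emg$signals), x$cycles$n_cycles,
              if (is.null(x$frames)) "not rendered" else "rendered"))
  invisible(x)
}

#' Write / read ground-truth parameters as JSON
#'
#' Serializes the generating parameters of a synthetic trial (everything
#' except the width-profile function, stored as its sampled values).
#'
#' @param trial a `synthetic_trial` (or its `truth` list).
#' @param path JSON path.
#' @export
write_truth <- function(trial, path) {
  truth <- if (inherits(trial, "synthetic_trial")) trial$truth else trial
  sw <- truth$swimmer
  sw$body_width_profile <- sw$body_width_profile(seq(0, 1, length.out = 101))
  out <- list(swimmer = unclass(sw),
              emg = unclass(truth$emg))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @return `read_truth` returns the truth list (width profile as a sampled
#'   vector).
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
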