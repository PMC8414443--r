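#' Midline sequence container
#'
#' Ordered nose-to-tail midline points per frame, equally spaced in arc
#' length. Point 1 is the nose in every frame. Coordinates are stored in a
#' single world frame whose unit is either body lengths (`"bl"`, synthetic
#' midlines) or pixels (`"px"`, extracted or digitized midlines; image
#' convention, y down).
#'
#' @param xy numeric array `T x N x 2` of coordinates.
#' @param frame_rate_hz frame rate, Hz.
#' @param body_length nominal body length in the same unit as `xy`.
#' @param unit `"bl"` or `"px"`.
#' @param px_per_bl optional scale for pixel-unit sequences.
#' @param resample if `TRUE`, re-resample each frame to uniform arc spacing.
#' @return object of class `midline_sequence` with fields `xy`,
#'   `frame_rate_hz`, `body_length`, `unit`, `arc` (the common arc-length
#'   grid, fractions of BL), `n_frames`, `n_points`.
#' @export
midline_sequence <- function(xy, frame_rate_hz, body_length, unit = c("bl", "px"),
                             px_per_bl = NULL, resample = FALSE) {
  unit <- match.arg(unit)
  stopifnot(length(dim(xy)) == 3, dim(xy)[3] == 2, frame_rate_hz > 0,
            body_length > 0)
  if (resample) {
    for (t in seq_len(dim(xy)[1])) {
      xy[t, , ] <- resample_polyline(xy[t, , , drop = TRUE], dim(xy)[2])
    }
  }
  ml <- structure(list(
    xy = xy,
    frame_rate_hz = frame_rate_hz,
    body_length = body_length,
    unit = unit,
    px_per_bl = px_per_bl,
    arc = seq(0, 1, length.out = dim(xy)[2]),
    n_frames = dim(xy)[1],
    n_points = dim(xy)[2]), class = "midline_sequence")
  validate_midline_sequence(ml)
}

validate_midline_sequence <- function(ml) {
  lens <- vapply(seq_len(ml$n_frames), function(t) {
    xy <- ml$xy[t, , , drop = TRUE]
    sum(sqrt(rowSums(diff(xy)^2)))
  }, numeric(1))
  rel <- lens / ml$body_length
  if (any(rel < 0.97 | rel > 1.03)) {
    bad <- which(rel < 0.97 | rel > 1.03)
    stop(sprintf(
      "midline polyline length deviates >3%% from body length in %d frame(s) (first: frame %d, ratio %.3f)",
      length(bad), bad[1], rel[bad[1]]))
  }
  # arc grid must be uniform (fractions of body length)
  if (max(abs(diff(ml$arc) - 1 / (ml$n_points - 1))) > 1e-6) {
    stop("arc-length grid is not uniform")
  }
  ml
}

#' @export
print.midline_sequence <- function(x, ...) {
  cat(sprintf(
    "<midline_sequence> %d frames x %d points @ %.0f fps, unit = %s (BL = %.4g %s)\n",
    x$n_frames, x$n_points, x$frame_rate_hz, x$unit, x$body_length, x$unit))
  invisible(x)
}

#' @export
plot.midline_sequence <- function(x, frames = NULL, ...) {
  frames <- frames %||% unique(round(seq(1, x$n_frames, length.out = 8)))
  xs <- x$xy[frames, , 1, drop = FALSE]
  ys <- x$xy[frames, , 2, drop = FALSE]
  graphics::plot(range(xs), range(ys), type = "n", asp = 1,
                 xlab = paste0("x (", x$unit, ")"),
                 ylab = paste0("y (", x$unit, ")"), ...)
  for (i in seq_along(frames)) {
    graphics::lines(xs[i, , 1], ys[i, , 1],
                    col = grDevices::grey(0.8 * (i - 1) / max(1, length(frames) - 1)))
  }
  invisible(x)
}

# Times (s) of each frame, 0 at the first frame.
frame_times <- function(ml) (seq_len(ml$n_frames) - 1) / ml$frame_rate_hz

# Coordinates in BL units, y-up. Pixel-unit sequences are divided by body
# length and their y axis flipped (image convention is y-down).
midline_bl <- function(ml) {
  xy <- ml$xy / ml$body_length
  if (ml$unit == "px") xy[, , 2] <- -xy[, , 2]
  xy
}

# Per-frame body frame: origin at the 20% BL point, x = heading (20% BL ->
# nose), lateral positive toward the fish's right. Returns the lateral
# coordinate of the point at arc fraction s_point for every frame.
lateral_displacement <- function(ml, s_point = 1) {
  xy <- midline_bl(ml)
  s <- ml$arc
  interp_pt <- function(t, sp) {
    c(approx(s, xy[t, , 1], xout = sp, ties = "ordered")$y,
      approx(s, xy[t, , 2], xout = sp, ties = "ordered")$y)
  }
  vapply(seq_len(ml$n_frames), function(t) {
    nose <- xy[t, 1, ]
    p20 <- interp_pt(t, 0.2)
    heading <- nose - p20
    heading <- heading / sqrt(sum(heading^2))
    right <- c(heading[2], -heading[1])  # heading rotated -90 deg (y-up)
    p <- interp_pt(t, s_point)
    sum((p - p20) * right)
  }, numeric(1))
}

# Trajectory (BL, y-up) of the body point at arc fraction s_point.
body_point_trajectory <- function(ml, s_point = 0.2) {
  xy <- midline_bl(ml)
  s <- ml$arc
  t(vapply(seq_len(ml$n_frames), function(t) {
    c(approx(s, xy[t, , 1], xout = s_point, ties = "ordered")$y,
      approx(s, xy[t, , 2], xout = s_point, ties = "ordered")$y)
  }, numeric(2)))
}

#' Write / read midline sequences as CSV
#'
#' One row per frame x point with columns `frame` (0-based), `point_index`
#' (0-based, 0 = nose), `x_px`, `y_px`. The column names follow the
#' digitizer convention even when the unit is BL; the unit and scale are
#' restated by the caller on load.
#'
#' @param ml a `midline_sequence`.
#' @param path CSV file path.
#' @export
write_midlines <- function(ml, path) {
  tn <- ml$n_frames; pn <- ml$n_points
  df <- data.frame(
    frame = rep(seq_len(tn) - 1L, each = pn),
    point_index = rep(seq_len(pn) - 1L, times = tn),
    x_px = as.vector(t(ml$xy[, , 1])),
    y_px = as.vector(t(ml$xy[, , 2])))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_midlines
#' @param frame_rate_hz frame rate of the recording, Hz.
#' @param body_length body length in the file's coordinate unit; if `NULL`,
#'   the median per-frame polyline length is used.
#' @param unit coordinate unit of the file (`"px"` default).
#' @param n_points if non-`NULL`, resample each frame to this many points;
#'   otherwise frames are re-resampled to uniform spacing at the stored
#'   point count.
#' @return `read_midlines` returns a `midline_sequence`.
#' @export
read_midlines <- function(path, frame_rate_hz, body_length = NULL,
                          unit = "px", n_points = NULL) {
  df <- read.csv(path)
  need <- c("frame", "point_index", "x_px", "y_px")
  if (!all(need %in% names(df))) {
    stop("midline CSV must have columns: ", paste(need, collapse = ", "))
  }
  fr <- sort(unique(df$frame))
  expect <- seq(min(fr), max(fr))
  if (!identical(as.integer(fr), as.integer(expect))) {
    gaps <- setdiff(expect, fr)
    stop("missing frames in midline CSV: ", paste(gaps, collapse = ", "))
  }
  counts <- table(df$frame)
  if (length(unique(counts)) != 1) stop("unequal point counts across frames")
  np_in <- as.integer(counts[1])
  np <- n_points %||% np_in
  tn <- length(fr)
  xy <- array(NA_real_, dim = c(tn, np, 2))
  df <- df[order(df$frame, df$point_index), ]
  for (i in seq_len(tn)) {
    rows <- ((i - 1) * np_in + 1):(i * np_in)
    pts <- cbind(df$x_px[rows], df$y_px[rows])
    seg <- sqrt(rowSums(diff(pts)^2))
    # chord lengths of an equal-arc polyline vary by O(kappa^2 h^2); only
    # genuinely non-uniform input (> 1%) is re-resampled
    if (np == np_in && diff(range(seg)) <= 0.01 * max(seg)) {
      xy[i, , ] <- pts   # already uniform: keep losslessly
    } else {
      xy[i, , ] <- resample_polyline(pts, np)
    }
  }
  if (is.null(body_length)) {
    body_length <- median(vapply(seq_len(tn), function(t) {
      sum(sqrt(rowSums(diff(xy[t, , , drop = TRUE])^2)))
    }, numeric(1)))
  }
  midline_sequence(xy, frame_rate_hz, body_length, unit = unit)
}
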