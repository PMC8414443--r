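#' Signed body curvature on an equal-length segment grid
#'
#' Computes the parametric signed curvature
#' \eqn{\kappa = (x'y'' - y'x'') / (x'^2 + y'^2)^{3/2}} along each frame's
#' midline, with arc length normalized by body length, sampled at the
#' centers of `n_segments` equal-length body segments. Curvature is in
#' BL\eqn{^{-1}}; positive = concave toward the fish's left. The first and
#' last `mask_ends` fraction of the body is flagged unreliable (curvature at
#' the head and tail tip is dominated by digitizing/skeleton noise and is
#' excluded from downstream analyses).
#'
#' For clean (synthetic or digitized) midlines the derivatives come from an
#' interpolating cubic spline over arc length; for extracted midlines
#' (pixelated input, `source = "extracted"`) a fixed-roughness smoothing
#' spline absorbs sub-pixel skeleton noise first (see `smooth_df`).
#'
#' @param ml a [midline_sequence()] with at least 7 points per frame.
#' @param n_segments number of equal-length body segments (default 100).
#' @param mask_ends fraction of BL masked at each end (default 0.05).
#' @param smoothing `"auto"` (smooth only extracted midlines), `"none"`, or
#'   `"spline"`.
#' @param smooth_df equivalent degrees of freedom of the arc-length
#'   smoothing spline when smoothing is active (default 30; enough to
#'   resolve several body wavelengths once the temporal filter has removed
#'   most frame-independent noise). Cross-validated smoothing is
#'   deliberately not used: it tracks sub-pixel skeleton noise whose second
#'   derivative would dominate the curvature signal.
#' @param time_smooth_s temporal moving-average window (s) applied to each
#'   midline point's coordinates before spatial fitting when smoothing is
#'   active; midline motion is band-limited well below the frame rate while
#'   skeleton noise is frame-independent, so this symmetric filter removes
#'   noise without biasing wave phase. Default 0.04 s.
#' @return Object of class `curvature_field`: list with `kappa` (T x S
#'   matrix, BL^-1), `body_grid` (segment centers, % BL), `mask` (logical S,
#'   `TRUE` = unreliable), `frame_rate_hz`, `times_s`.
#' @export
compute_curvature <- function(ml, n_segments = 100, mask_ends = 0.05,
                              smoothing = c("auto", "none", "spline"),
                              smooth_df = 30, time_smooth_s = 0.04) {
  smoothing <- match.arg(smoothing)
  if (ml$n_points < 7) stop("need at least 7 midline points per frame")
  smooth_it <- switch(smoothing,
    auto = identical(attr(ml, "source"), "extracted"),
    none = FALSE,
    spline = TRUE)
  xy <- midline_bl(ml)
  if (smooth_it && time_smooth_s > 0 && ml$n_frames >= 5) {
    twin <- round(time_smooth_s * ml$frame_rate_hz)
    if (twin >= 2) {
      for (j in seq_len(ml$n_points)) {
        xy[, j, 1] <- moving_average(xy[, j, 1], twin)
        xy[, j, 2] <- moving_average(xy[, j, 2], twin)
      }
    }
  }
  s <- ml$arc
  centers <- (seq_len(n_segments) - 0.5) / n_segments
  kappa <- matrix(NA_real_, ml$n_frames, n_segments)
  for (t in seq_len(ml$n_frames)) {
    kappa[t, ] <- frame_curvature(s, xy[t, , 1], xy[t, , 2], centers,
                                  smooth_it, smooth_df)
  }
  grid_pct <- centers * 100
  mask <- centers < mask_ends | centers > 1 - mask_ends
  structure(list(kappa = kappa, body_grid = grid_pct, mask = mask,
                 frame_rate_hz = ml$frame_rate_hz,
                 times_s = frame_times(ml),
                 n_segments = n_segments),
            class = "curvature_field")
}

frame_curvature <- function(s, x, y, centers, smooth_it, smooth_df) {
  if (smooth_it) {
    smooth_df <- min(smooth_df, length(s) - 2)
    # pad both ends by quadratic extrapolation before fitting, so the
    # spline's free-end bias falls outside the evaluated body
    fx <- padded_smooth_spline(s, x, smooth_df)
    fy <- padded_smooth_spline(s, y, smooth_df)
    d <- function(f, m) predict(f, centers, deriv = m)$y
    x1 <- d(fx, 1); x2 <- d(fx, 2); y1 <- d(fy, 1); y2 <- d(fy, 2)
  } else {
    fx <- splinefun(s, x, method = "fmm")
    fy <- splinefun(s, y, method = "fmm")
    x1 <- fx(centers, deriv = 1); x2 <- fx(centers, deriv = 2)
    y1 <- fy(centers, deriv = 1); y2 <- fy(centers, deriv = 2)
  }
  # parametric curvature is positive for counterclockwise turns along the
  # traversal; traversing nose -> tail, concave-toward-the-fish's-left is a
  # clockwise turn, hence the sign flip
  -(x1 * y2 - y1 * x2) / (x1^2 + y1^2)^1.5
}

# Smoothing spline with quadratic end padding: each end is continued for
# 0.1 BL by a quadratic fitted to its outer 15% of points (locally
# curvature-preserving), so free-end bias does not reach the body.
padded_smooth_spline <- function(s, z, smooth_df, frac = 0.15, pad = 0.1,
                                 npad = 12) {
  iL <- which(s <= s[1] + frac)
  iR <- which(s >= s[length(s)] - frac)
  qL <- stats::lm.fit(cbind(1, s[iL], s[iL]^2), z[iL])$coefficients
  qR <- stats::lm.fit(cbind(1, s[iR], s[iR]^2), z[iR])$coefficients
  sL <- seq(s[1] - pad, s[1] - pad / npad, length.out = npad)
  sR <- seq(s[length(s)] + pad / npad, s[length(s)] + pad, length.out = npad)
  zL <- cbind(1, sL, sL^2) %*% qL
  zR <- cbind(1, sR, sR^2) %*% qR
  smooth.spline(c(sL, s, sR), c(zL, z, zR), df = smooth_df + 4)
}

#' @export
print.curvature_field <- function(x, ...) {
  cat(sprintf(
    "<curvature_field> %d frames x %d segments; masked < %.0f%% and > %.0f%% BL\n",
    nrow(x$kappa), x$n_segments,
    min(x$body_grid[!x$mask]), max(x$body_grid[!x$mask])))
  cat(sprintf("  max |kappa| (unmasked): %.3f BL^-1\n",
              max(abs(x$kappa[, !x$mask]), na.rm = TRUE)))
  invisible(x)
}

# Column of the body grid nearest a position in % BL; errors in the mask.
grid_column <- function(cf, position_pct, allow_masked = FALSE) {
  j <- which.min(abs(cf$body_grid - position_pct))
  if (!allow_masked && cf$mask[j]) {
    stop(sprintf("body position %.1f%% BL lies in the masked head/tail zone",
                 position_pct))
  }
  j
}

# All local-maximum times of side-signed curvature at one body position.
# side "left": peaks of +kappa; "right": peaks of -kappa.
curvature_max_times <- function(cf, position_pct, side = c("left", "right"),
                                min_frac = 0.3) {
  side <- match.arg(side)
  j <- grid_column(cf, position_pct)
  sig <- if (side == "left") cf$kappa[, j] else -cf$kappa[, j]
  robust_peaks(sig, cf$times_s, cf$frame_rate_hz, min_frac = min_frac)
}

# Peak detection robust to frame-to-frame noise: the series is smoothed
# over ~40 ms (symmetric, so peak times are unbiased), the oscillation
# period is estimated from mean-level upward crossings, and peaks closer
# than 0.6 periods are merged (the higher wins).
robust_peaks <- function(x, t, frame_rate, min_frac = 0.3) {
  win <- max(1L, round(0.04 * frame_rate))
  xs <- moving_average(x, win)
  up <- sum(xs[-length(xs)] < mean(xs) & xs[-1] >= mean(xs))
  pk <- find_peaks(xs, t, min_frac = min_frac)
  if (up >= 1 && nrow(pk) > 1) {
    period <- (t[length(t)] - t[1]) / up
    repeat {
      gaps <- diff(pk$time)
      k <- which(gaps < 0.6 * period)
      if (!length(k)) break
      k <- k[1]
      drop <- if (pk$value[k] >= pk$value[k + 1]) k + 1L else k
      pk <- pk[-drop, , drop = FALSE]
    }
  }
  pk
}
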