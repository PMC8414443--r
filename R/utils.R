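# Internal numeric helpers shared by the kinematics and EMG stages.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Cumulative trapezoidal integral of y over x (same length as x, starts at 0).
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(x)))
}

trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

# Polyline cumulative arc length for an n x 2 coordinate matrix.
arclength <- function(xy) {
  d <- sqrt(rowSums(diff(xy)^2))
  c(0, cumsum(d))
}

# Resample an ordered polyline to n points equally spaced in arc length.
resample_polyline <- function(xy, n) {
  s <- arclength(xy)
  total <- s[length(s)]
  if (total <= 0) stop("degenerate polyline: zero length")
  grid <- seq(0, total, length.out = n)
  cbind(approx(s, xy[, 1], xout = grid, ties = "ordered")$y,
        approx(s, xy[, 2], xout = grid, ties = "ordered")$y)
}

# Centered moving average, edges handled by shrinking the window.
moving_average <- function(x, window) {
  window <- max(1L, as.integer(window))
  if (window %% 2 == 0) window <- window + 1L
  if (window == 1L || length(x) < 3L) return(x)
  half <- (window - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Local maxima of x sampled at times t, with parabolic sub-sample refinement.
# Keeps peaks above min_frac of the global maximum. Plateaus and exact ties
# resolve to the earliest sample (first index wins).
find_peaks <- function(x, t, min_frac = 0.25, min_value = NULL) {
  n <- length(x)
  if (n < 3) return(data.frame(time = numeric(0), value = numeric(0)))
  idx <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(idx)) return(data.frame(time = numeric(0), value = numeric(0)))
  thr <- if (is.null(min_value)) min_frac * max(x) else min_value
  idx <- idx[x[idx] >= thr]
  if (!length(idx)) return(data.frame(time = numeric(0), value = numeric(0)))
  tt <- t[idx]
  vv <- x[idx]
  denom <- x[idx - 1L] - 2 * x[idx] + x[idx + 1L]
  ok <- is.finite(denom) & denom < 0
  delta <- ifelse(ok, 0.5 * (x[idx - 1L] - x[idx + 1L]) / denom, 0)
  delta <- pmin(pmax(delta, -0.5), 0.5)
  dt <- if (n > 1) (t[n] - t[1]) / (n - 1) else 0
  tt <- tt + delta * dt
  vv <- vv - 0.25 * (x[idx - 1L] - x[idx + 1L]) * delta
  data.frame(time = tt, value = vv)
}

# Linearly interpolated time at which series y(t) first crosses `level`
# upward at or after t_from. Returns NA if it never does.
first_upcross <- function(t, y, level, t_from = -Inf) {
  ok <- which(t >= t_from)
  if (length(ok) < 2) return(NA_real_)
  t <- t[ok]; y <- y[ok]
  below <- y < level
  i <- which(below[-length(below)] & !below[-1])
  if (!length(i)) return(NA_real_)
  i <- i[1]
  t[i] + (level - y[i]) / (y[i + 1] - y[i]) * (t[i + 1] - t[i])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
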