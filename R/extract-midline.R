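#' Extract ordered midlines from binarized frames
#'
#' Per frame: largest-connected-component selection, Zhang-Suen morphological
#' thinning, longest geodesic path between skeleton endpoints (spurs are
#' dropped by taking the diameter path), endpoint extension to the
#' silhouette tips, light smoothing, and resampling to `n_points` equal
#' arc-length points. The nose is the path endpoint nearest `nose_hint` on
#' the first frame and nearest the previous frame's nose thereafter; with no
#' hint, the endpoint whose surroundings are wider (heads are wider than
#' tail tips) is taken.
#'
#' Errors: a second component at least half the size of the largest
#' ("multiple similar-size components"), a skeleton without an elongated
#' axis (e.g. a disk), or a skeleton shorter than half the expected body
#' length, all reported with the offending frame index (0-based).
#'
#' @param fs a `frame_stack` (see [rasterize_frames()], [read_frames()]).
#' @param n_points points per midline (>= 20; default 100).
#' @param nose_hint optional `c(x_px, y_px)` near the nose in frame 0.
#' @param px_per_bl expected pixels per body length, used for the
#'   short-skeleton check and smoothing scale; taken from `fs` when present.
#' @param smooth_window moving-average window (px) applied along the raw
#'   skeleton path before resampling; `NULL` = scale with `px_per_bl`.
#' @return A [midline_sequence()] in pixel units (image convention), with
#'   `attr(,"source") = "extracted"`.
#' @export
extract_midline <- function(fs, n_points = 100, nose_hint = NULL,
                            px_per_bl = NULL, smooth_window = NULL) {
  if (n_points < 20) stop("n_points must be >= 20")
  px_per_bl <- px_per_bl %||% fs$px_per_bl
  paths <- vector("list", fs$n_frames)
  lens <- numeric(fs$n_frames)
  prev_nose <- NULL
  for (t in seq_len(fs$n_frames)) {
    img <- fs$frames[[t]]
    res <- tryCatch(frame_skeleton_path(img),
                    error = function(e) {
                      stop(sprintf("frame %d: %s", t - 1L, conditionMessage(e)),
                           call. = FALSE)
                    })
    if (!is.null(px_per_bl) && res$length < 0.5 * px_per_bl) {
      stop(sprintf("frame %d: skeleton length %.0f px < 50%% of expected body length (%.0f px)",
                   t - 1L, res$length, px_per_bl))
    }
    path <- res$path  # m x 2 matrix of (x, y) pixel coords, arbitrary order
    ends <- path[c(1, nrow(path)), , drop = FALSE]
    if (t == 1) {
      if (!is.null(nose_hint)) {
        d <- rowSums(sweep(ends, 2, nose_hint)^2)
      } else {
        d <- -endpoint_widths(img, path)  # wider end = nose
      }
    } else {
      d <- rowSums(sweep(ends, 2, prev_nose)^2)
    }
    if (which.min(d) == 2) path <- path[nrow(path):1, , drop = FALSE]
    prev_nose <- path[1, ]
    paths[[t]] <- path
    lens[t] <- sum(sqrt(rowSums(diff(path)^2)))
  }
  win <- smooth_window %||%
    max(3L, round((px_per_bl %||% median(lens)) / 100))
  xy <- array(NA_real_, dim = c(fs$n_frames, n_points, 2))
  for (t in seq_len(fs$n_frames)) {
    p <- paths[[t]]
    p[, 1] <- moving_average(p[, 1], win)
    p[, 2] <- moving_average(p[, 2], win)
    xy[t, , ] <- resample_polyline(p, n_points)
  }
  # body length from the smoothed midlines (the raw 8-connected skeleton
  # path overestimates length by its staircase steps)
  body_length_px <- median(vapply(seq_len(fs$n_frames), function(t) {
    sum(sqrt(rowSums(diff(xy[t, , , drop = TRUE])^2)))
  }, numeric(1)))
  ml <- midline_sequence(xy, fs$frame_rate_hz, body_length = body_length_px,
                         unit = "px", px_per_bl = px_per_bl)
  attr(ml, "source") <- "extracted"
  ml
}

# Skeletonize one frame and return its longest geodesic path (x, y coords).
frame_skeleton_path <- function(img) {
  lab <- label_components(img)
  sizes <- tabulate(lab[lab > 0])
  if (!length(sizes)) stop("no foreground component")
  ord <- order(sizes, decreasing = TRUE)
  if (length(sizes) > 1 && sizes[ord[2]] >= 0.5 * sizes[ord[1]]) {
    stop("multiple similar-size foreground components")
  }
  mask <- matrix(as.integer(lab == ord[1]), nrow(img), ncol(img))
  area <- sum(mask)
  skel <- thin_binary(mask)
  pix <- which(skel == 1, arr.ind = TRUE)  # (row, col)
  if (nrow(pix) < 3) stop("skeleton degenerate (object not elongated)")
  path_rc <- longest_skeleton_path(pix)
  plen <- sum(sqrt(rowSums(diff(path_rc)^2)))
  width_est <- area / max(plen, 1)
  if (plen < 3 * width_est) {
    stop("no unique elongated medial axis (object too round)")
  }
  path_rc <- extend_to_boundary(path_rc, mask)
  plen <- sum(sqrt(rowSums(diff(path_rc)^2)))
  # return as (x, y) = (col, row), 0-based pixel centers
  list(path = cbind(path_rc[, 2] - 1, path_rc[, 1] - 1), length = plen)
}

# Longest weighted geodesic between skeleton endpoints (graph diameter
# restricted to degree-1 nodes; falls back to all nodes if the skeleton has
# no endpoints). pix: (row, col) matrix.
longest_skeleton_path <- function(pix) {
  n <- nrow(pix)
  key <- pix[, 1] * 1e6 + pix[, 2]
  idx <- seq_len(n)
  names(idx) <- as.character(key)
  edges <- integer(0)
  wts <- numeric(0)
  offs <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1))
  for (k in seq_len(nrow(offs))) {
    nb_key <- (pix[, 1] + offs[k, 1]) * 1e6 + (pix[, 2] + offs[k, 2])
    j <- idx[as.character(nb_key)]
    ok <- !is.na(j)
    if (any(ok)) {
      edges <- c(edges, rbind(idx[ok], j[ok]))
      wts <- c(wts, rep(sqrt(sum(offs[k, ]^2)), sum(ok)))
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, edges)
  igraph::E(g)$weight <- wts
  deg <- igraph::degree(g)
  ends <- which(deg == 1)
  if (length(ends) < 2) ends <- seq_len(n)
  if (length(ends) > 40) {
    # keep the endpoints farthest apart in the plane to bound the search
    ends <- ends[order(-apply(pix[ends, , drop = FALSE], 1, function(p) {
      max(abs(p[1] - pix[ends, 1]) + abs(p[2] - pix[ends, 2]))
    }))[1:40]]
  }
  dm <- igraph::distances(g, v = ends, to = ends)
  dm[!is.finite(dm)] <- -1
  best <- arrayInd(which.max(dm), dim(dm))
  from <- ends[best[1]]; to <- ends[best[2]]
  if (from == to) stop("skeleton degenerate (object not elongated)")
  sp <- igraph::shortest_paths(g, from = from, to = to, output = "vpath")
  vp <- as.integer(sp$vpath[[1]])
  pix[vp, , drop = FALSE]
}

# Extend both path ends to the silhouette tips the thinning eroded,
# following the body's curving centerline: each 1 px step advances along
# the current direction, re-centers laterally on the foreground run, and
# updates the direction, so a bent tail is followed around its curve.
# path: (row, col); mask: 0/1 matrix.
extend_to_boundary <- function(path, mask) {
  inside <- function(q) {
    r <- round(q[1]); c <- round(q[2])
    r >= 1 && r <= nrow(mask) && c >= 1 && c <= ncol(mask) && mask[r, c] == 1
  }
  recenter <- function(q, dir) {
    perp <- c(-dir[2], dir[1])
    offs <- seq(-6L, 6L)
    ok <- vapply(offs, function(o) inside(q + o * perp), logical(1))
    z <- which(offs == 0L)
    if (!ok[z]) return(NULL)
    lo <- z; while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
    hi <- z; while (hi < length(offs) && ok[hi + 1L]) hi <- hi + 1L
    q + mean(offs[lo:hi]) * perp
  }
  extend_one <- function(path) {
    m <- nrow(path)
    k <- min(6L, m - 1L)
    dir <- path[1, ] - path[k + 1, ]
    nd <- sqrt(sum(dir^2))
    if (nd < 1e-9) return(path)
    dir <- dir / nd
    p <- path[1, ]
    added <- list()
    for (step in seq_len(200)) {
      q <- p + dir
      if (!inside(q)) break
      qc <- recenter(q, dir)
      if (is.null(qc)) break
      dir2 <- qc - p
      dir2 <- dir2 / sqrt(sum(dir2^2))
      dir <- 0.6 * dir + 0.4 * dir2
      dir <- dir / sqrt(sum(dir^2))
      p <- qc
      added[[step]] <- qc
    }
    if (length(added)) {
      path <- rbind(do.call(rbind, rev(added)), path)
    }
    path
  }
  path <- extend_one(path)
  path <- extend_one(path[nrow(path):1, , drop = FALSE])
  path[nrow(path):1, , drop = FALSE]
}

# Local silhouette width around each of the two path endpoints: foreground
# pixel count in a small disk (wider surroundings = head).
endpoint_widths <- function(img, path) {
  r <- max(4L, round(nrow(path) / 40))
  vapply(c(1L, nrow(path)), function(i) {
    # path stores (x, y); convert back to (row, col)
    cc <- round(path[i, 1]) + 1L
    rr <- round(path[i, 2]) + 1L
    # move a few pixels inward so the tip taper does not dominate
    j <- min(nrow(path), max(1L, if (i == 1L) 1L + 3L * r else nrow(path) - 3L * r))
    cc <- round(path[j, 1]) + 1L
    rr <- round(path[j, 2]) + 1L
    rs <- max(1L, rr - r):min(nrow(img), rr + r)
    cs <- max(1L, cc - r):min(ncol(img), cc + r)
    sum(img[rs, cs])
  }, numeric(1))
}
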