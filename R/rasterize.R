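#' Rasterize midlines into binary silhouette frames
#'
#' Emulates binarized ventral-view video: each frame is the filled silhouette
#' of the body polygon (midline offset by the local half-width along the
#' midline normal, tapered to points at the nose and tail tip), foreground 1
#' on background 0. Image convention: x right, y down, 0-based pixel centers.
#'
#' @param ml a [midline_sequence()] in BL units.
#' @param width_profile function of arc fraction returning half-width in BL
#'   (default [default_width_profile()]); forced to 0 at both ends.
#' @param px_per_bl image scale, pixels per body length (default 800, i.e.
#'   8 px per 1% BL, so skeletonization is not pixel-starved).
#' @param image_size optional `c(height, width)` in pixels. When `NULL`, the
#'   frame is sized to fit the fish in all frames with a margin. If given
#'   and the fish leaves the frame, an error lists the offending frames.
#' @param margin_px margin around the auto-fitted bounding box.
#' @return object of class `frame_stack`: list with `frames` (list of
#'   integer 0/1 matrices, rows = y), `px_per_bl`, `frame_rate_hz`, and
#'   `transform` (`x0_bl`, `y0_bl`: world coordinates of pixel (0,0)) so
#'   pixel and BL coordinates interconvert exactly.
#' @export
rasterize_frames <- function(ml, width_profile = default_width_profile,
                             px_per_bl = 800, image_size = NULL,
                             margin_px = 5) {
  stopifnot(ml$unit == "bl")
  s <- ml$arc
  w <- if (is.function(width_profile)) width_profile(s) else
    rep_len(width_profile, length(s))
  w[c(1, length(w))] <- 0  # taper to points at nose and tail tip
  if (all(w <= 0)) stop("width profile is zero everywhere; frames would be empty")
  wmax <- max(w)
  xr <- range(ml$xy[, , 1]); yr <- range(ml$xy[, , 2])
  x0 <- xr[1] - wmax - margin_px / px_per_bl
  y1 <- yr[2] + wmax + margin_px / px_per_bl  # top of image in world y
  if (is.null(image_size)) {
    nc <- ceiling((xr[2] + wmax - x0) * px_per_bl) + margin_px
    nr <- ceiling((y1 - (yr[1] - wmax)) * px_per_bl) + margin_px
  } else {
    nr <- image_size[1]; nc <- image_size[2]
  }
  frames <- vector("list", ml$n_frames)
  bad <- integer(0)
  for (t in seq_len(ml$n_frames)) {
    xy <- ml$xy[t, , , drop = TRUE]
    poly <- body_polygon(xy, w)
    # world (BL, y-up) -> pixel (x right, y down)
    px <- (poly[, 1] - x0) * px_per_bl
    py <- (y1 - poly[, 2]) * px_per_bl
    if (min(px) < 0 || max(px) > nc - 1 || min(py) < 0 || max(py) > nr - 1) {
      bad <- c(bad, t)
      next
    }
    frames[[t]] <- fill_polygon(px, py, nr, nc)
  }
  if (length(bad)) {
    stop("fish exits the frame in frame(s): ",
         paste(bad - 1L, collapse = ", "))
  }
  if (sum(frames[[1]]) == 0) stop("empty frames: silhouette has zero area")
  structure(list(frames = frames, px_per_bl = px_per_bl,
                 frame_rate_hz = ml$frame_rate_hz,
                 transform = list(x0_bl = x0, y1_bl = y1),
                 n_frames = ml$n_frames, dim = c(nr, nc)),
            class = "frame_stack")
}

# Closed body outline: midline offset +/- half-width along unit normals.
body_polygon <- function(xy, w) {
  n <- nrow(xy)
  tang <- rbind(xy[2, ] - xy[1, ],
                (xy[3:n, ] - xy[1:(n - 2), ]) / 2,
                xy[n, ] - xy[n - 1, ])
  len <- sqrt(rowSums(tang^2))
  tang <- tang / len
  normal <- cbind(-tang[, 2], tang[, 1])
  left <- xy + w * normal
  right <- xy - w * normal
  rbind(left, right[n:1, ])
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("<frame_stack> %d frames of %d x %d px @ %.0f fps (%.0f px/BL)\n",
              x$n_frames, x$dim[1], x$dim[2], x$frame_rate_hz, x$px_per_bl))
  invisible(x)
}

# Map pixel coordinates (x right, y down, 0-based) of a frame_stack back to
# the BL world frame (y-up) of the source midlines.
px_to_bl <- function(fs, x_px, y_px) {
  cbind(fs$transform$x0_bl + x_px / fs$px_per_bl,
        fs$transform$y1_bl - y_px / fs$px_per_bl)
}

#' Write / read binary frame stacks
#'
#' `write_frames` writes either a multi-page 8-bit TIFF (`path` ending in
#' `.tif`/`.tiff`; requires the tiff package) or a directory of numbered
#' PNGs (requires png). Foreground is 255. `read_frames` reads either form
#' back into a `frame_stack` (threshold at 0.5).
#'
#' @param fs a `frame_stack`.
#' @param path output file or directory.
#' @export
write_frames <- function(fs, path) {
  imgs <- lapply(fs$frames, function(m) m * 1.0)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("the tiff package is required to write TIFF stacks")
    }
    tiff::writeTIFF(imgs, path, bits.per.sample = 8L)
  } else {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("the png package is required to write PNG frames")
    }
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(imgs)) {
      png::writePNG(imgs[[i]], file.path(path, sprintf("frame_%05d.png", i - 1)))
    }
  }
  invisible(path)
}

#' @rdname write_frames
#' @param frame_rate_hz frame rate to attach on read.
#' @param px_per_bl optional scale to attach on read.
#' @export
read_frames <- function(path, frame_rate_hz, px_per_bl = NULL) {
  if (dir.exists(path)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("the png package is required to read PNG frames")
    }
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    imgs <- lapply(files, png::readPNG)
  } else {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("the tiff package is required to read TIFF stacks")
    }
    imgs <- tiff::readTIFF(path, all = TRUE)
  }
  frames <- lapply(imgs, function(m) {
    if (length(dim(m)) == 3) m <- m[, , 1]
    matrix(as.integer(m > 0.5), nrow(m), ncol(m))
  })
  structure(list(frames = frames, px_per_bl = px_per_bl,
                 frame_rate_hz = frame_rate_hz, transform = NULL,
                 n_frames = length(frames), dim = dim(frames[[1]])),
            class = "frame_stack")
}
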