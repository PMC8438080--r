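# Temporal fixation-probability maps: per-pixel fraction of video frames on
# which the pixel fell within the gaze disk, group averaging, and pixel-wise
# Welch comparison under BH-FDR control.

#' Per-participant temporal probability map
#'
#' For each pixel of the (optionally downsampled) display grid, the
#' fraction of frames in `frame_range` whose gaze disk (Euclidean distance
#' <= `radius_px`, inclusive) covers the pixel. Gaze is taken from the
#' nearest valid sample within half a frame interval of each frame time;
#' frames with no valid gaze cover no pixels but still count in the
#' denominator.
#'
#' @param recording A `gaze_recording`.
#' @param display A `display_spec`.
#' @param radius_px Gaze disk radius in display pixels (default 75,
#'   accounting for tracker detection resolution).
#' @param frame_range `c(first, last)` frame indices (1-based, inclusive);
#'   defaults to the reach interval, movement onset to grasp.
#' @param downsample Integer grid downsampling factor (default 1 = full
#'   resolution). Pixel centers sit at display coordinates
#'   `(j - 0.5) * downsample`, `(i - 0.5) * downsample`.
#' @return Object of class `prob_map`: list with `grid`
#'   (height x width matrix of values in `[0, 1]`), `frame_range`,
#'   `n_frames`, `downsample`, `radius_px`, `resolution`, `owner`.
#' @export
participant_map <- function(recording, display, radius_px = 75,
                            frame_range = NULL, downsample = 1) {
  if (radius_px <= 0) stopf("participant_map: radius must be > 0")
  if (is.null(frame_range)) {
    frame_range <- c(frame_at_time(display, display$events$movement),
                     frame_at_time(display, display$events$grasp))
  }
  frames <- seq.int(frame_range[1], frame_range[2])
  if (length(frames) < 1L || frame_range[1] < 1 || frame_range[2] > display$n_frames)
    stopf("participant_map: empty or out-of-range frame_range")
  ds <- downsample
  w <- floor(display$resolution[1] / ds)
  h <- floor(display$resolution[2] / ds)
  grid <- matrix(0, h, w)

  half_frame <- 1 / (2 * display$fps)
  vt <- recording$t[recording$valid & !is.na(recording$x)]
  vx <- recording$x[recording$valid & !is.na(recording$x)]
  vy <- recording$y[recording$valid & !is.na(recording$x)]

  for (f in frames) {
    ft <- display$frame_times[f]
    if (!length(vt)) next
    k <- which.min(abs(vt - ft))
    if (abs(vt[k] - ft) > half_frame) next
    gx <- vx[k]; gy <- vy[k]
    # bounding box in grid indices, then exact distance test on centers
    j0 <- max(1L, floor((gx - radius_px) / ds + 0.5))
    j1 <- min(w, ceiling((gx + radius_px) / ds + 0.5))
    i0 <- max(1L, floor((gy - radius_px) / ds + 0.5))
    i1 <- min(h, ceiling((gy + radius_px) / ds + 0.5))
    if (j0 > j1 || i0 > i1) next
    px <- (j0:j1 - 0.5) * ds
    py <- (i0:i1 - 0.5) * ds
    d2 <- outer((py - gy)^2, (px - gx)^2, `+`)
    grid[i0:i1, j0:j1] <- grid[i0:i1, j0:j1] + (d2 <= radius_px^2)
  }
  structure(list(grid = grid / length(frames), frame_range = frame_range,
                 n_frames = length(frames), downsample = ds,
                 radius_px = radius_px, resolution = display$resolution,
                 owner = recording$participant_id),
            class = "prob_map")
}

#' Group-average probability map
#'
#' Element-wise mean of per-participant maps over identical grids.
#'
#' @param maps Non-empty list of `prob_map`s with matching grids.
#' @param owner Label for the averaged map.
#' @return A `prob_map` whose grid is the mean of the inputs.
#' @export
group_map <- function(maps, owner = "group") {
  if (!length(maps)) stopf("group_map: need at least one map")
  d <- dim(maps[[1]]$grid)
  for (m in maps) if (!identical(dim(m$grid), d))
    stopf("group_map: grid shape mismatch")
  g <- Reduce(`+`, lapply(maps, `[[`, "grid")) / length(maps)
  out <- maps[[1]]
  out$grid <- g
  out$owner <- owner
  out
}

#' @export
print.prob_map <- function(x, ...) {
  cat(sprintf("<prob_map> %s: %d x %d grid (downsample %d), frames %d-%d, radius %g px, max p = %.3f\n",
              x$owner, nrow(x$grid), ncol(x$grid), x$downsample,
              x$frame_range[1], x$frame_range[2], x$radius_px, max(x$grid)))
  invisible(x)
}

#' Pixel-wise comparison of two groups of probability maps
#'
#' Welch's unequal-variance t-test at every pixel, two-sided p-values, and
#' a Benjamini-Hochberg rejection mask at level `q`. The FDR family is the
#' full grid. Pixels constant across participants in both groups carry no
#' evidence and get `p = 1` (and `t = 0` when the constants agree).
#'
#' @param group_a_maps,group_b_maps Lists of `prob_map`s (>= 2 each,
#'   identical grids).
#' @param q FDR level (default 0.05).
#' @return Object of class `map_comparison`: list with matrices `t`, `p`,
#'   `mask` (logical), plus `q` and group sizes.
#' @export
compare_maps <- function(group_a_maps, group_b_maps, q = 0.05) {
  if (length(group_a_maps) < 2L || length(group_b_maps) < 2L)
    stopf("compare_maps: need >= 2 maps per group")
  d <- dim(group_a_maps[[1]]$grid)
  stack <- function(maps) {
    for (m in maps) if (!identical(dim(m$grid), d))
      stopf("compare_maps: grid shape mismatch")
    matrix(unlist(lapply(maps, function(m) as.vector(m$grid))),
           nrow = length(maps), byrow = TRUE)
  }
  A <- stack(group_a_maps)
  B <- stack(group_b_maps)
  ma <- colMeans(A); mb <- colMeans(B)
  va <- colMeans(A^2) * nrow(A) / (nrow(A) - 1) - ma^2 * nrow(A) / (nrow(A) - 1)
  vb <- colMeans(B^2) * nrow(B) / (nrow(B) - 1) - mb^2 * nrow(B) / (nrow(B) - 1)
  va <- pmax(va, 0); vb <- pmax(vb, 0)
  res <- welch_t_stats(ma, va, nrow(A), mb, vb, nrow(B))
  mask <- bh_fdr(res$p, q)
  structure(list(t = matrix(res$t, d[1], d[2]),
                 p = matrix(res$p, d[1], d[2]),
                 mask = matrix(mask, d[1], d[2]),
                 q = q, n_a = nrow(A), n_b = nrow(B)),
            class = "map_comparison")
}

#' Render a probability map as a PNG
#'
#' Grayscale image whose opacity encodes the fixation probability: pixels
#' nobody fixated are fully opaque white, pixels everyone fixated are fully
#' transparent (revealing whatever the image is composited over).
#'
#' @param map A `prob_map`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
render_map_png <- function(map, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stopf("render_map_png requires the 'png' package")
  h <- nrow(map$grid); w <- ncol(map$grid)
  img <- array(1, dim = c(h, w, 4))
  img[, , 4] <- 1 - map$grid  # opacity = 1 - probability
  png::writePNG(img, path)
  invisible(path)
}

#' @export
print.map_comparison <- function(x, ...) {
  cat(sprintf("<map_comparison> %d x %d grid, n = %d vs %d, q = %g: %d significant pixels\n",
              nrow(x$t), ncol(x$t), x$n_a, x$n_b, x$q, sum(x$mask)))
  invisible(x)
}
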