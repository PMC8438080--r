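# Gaze-masked "looking videos": schematic rendering of the display, disk
# masking around the gaze point, pluggable frame-feature extraction, and
# per-participant classification of efficient vs inefficient trials.

# schematic palette: column k+1 is the RGB of scene element k
# (0 = masked/black, 1 = background, then the 5 AOIs)
.lv_palette <- local({
  m <- cbind(black = c(0, 0, 0),
             background = c(0.25, 0.25, 0.25),
             hammer = c(0.90, 0.80, 0.10),
             peg = c(0.85, 0.20, 0.15),
             dominant_hand = c(0.90, 0.55, 0.15),
             non_dominant_hand = c(0.20, 0.35, 0.80),
             face = c(0.85, 0.70, 0.55))
  rownames(m) <- c("r", "g", "b")
  m
})

# draw order: static AOIs first, movers last so they appear front-most
.lv_draw_order <- c("face", "peg", "non_dominant_hand", "hammer", "dominant_hand")

#' Render schematic display frames
#'
#' Rasterizes a display specification into per-frame images at a reduced
#' working resolution: flat background with each AOI drawn as a filled
#' rectangle in a distinct color (movers drawn last). These schematic
#' frames stand in for the stimulus video: they carry exactly the
#' information the AOI tracks define, which is what the gaze-contingent
#' classification needs.
#'
#' @param display A `display_spec`.
#' @param width Working render width in pixels (default 96); height follows
#'   the display aspect ratio.
#' @return Object of class `display_frames`: list with `frames` (list of
#'   integer matrices, values 1..6 indexing the palette), `palette`,
#'   `scale` (render px per display px), `resolution` (of the source
#'   display), `frame_times`, `condition`.
#' @export
render_display_frames <- function(display, width = 96) {
  scale <- width / display$resolution[1]
  h <- round(display$resolution[2] * scale)
  frames <- vector("list", display$n_frames)
  for (f in seq_len(display$n_frames)) {
    # values index the palette as (value + 1): 0 = black, 1 = background
    img <- matrix(1L, h, width)
    for (a in .lv_draw_order) {
      r <- display$aoi_tracks[[a]][f, ] * scale
      j0 <- max(1L, floor(r[1]) + 1L); j1 <- min(width, ceiling(r[3]))
      i0 <- max(1L, floor(r[2]) + 1L); i1 <- min(h, ceiling(r[4]))
      if (j0 <= j1 && i0 <= i1)
        img[i0:i1, j0:j1] <- match(a, colnames(.lv_palette)) - 1L
    }
    frames[[f]] <- img
  }
  structure(list(frames = frames, palette = .lv_palette, scale = scale,
                 resolution = display$resolution,
                 frame_times = display$frame_times,
                 condition = display$condition),
            class = "display_frames")
}

#' Gaze disk mask
#'
#' Logical matrix marking pixels whose center lies within `radius`
#' (inclusive, Euclidean) of the gaze point. Pixel `(i, j)` has center
#' `((j - 0.5) / scale, (i - 0.5) / scale)` in display coordinates.
#'
#' @param height,width Mask dimensions in render pixels.
#' @param gx,gy Gaze point in display coordinates.
#' @param radius Disk radius in display pixels.
#' @param scale Render pixels per display pixel (default 1).
#' @return `height x width` logical matrix.
#' @export
gaze_disk_mask <- function(height, width, gx, gy, radius, scale = 1) {
  px <- (seq_len(width) - 0.5) / scale
  py <- (seq_len(height) - 0.5) / scale
  outer((py - gy)^2, (px - gx)^2, `+`) <= radius^2
}

#' Build a gaze-masked looking video
#'
#' For every display frame, gaze is interpolated to the frame time (nearest
#' valid sample within half a frame interval); the frame is kept identical
#' to the rendered display inside the disk of `radius_px` around the gaze
#' point and set to black outside. Frames with no valid gaze are entirely
#' black. Masking is idempotent.
#'
#' @param display_frames A [render_display_frames()] result.
#' @param recording A `gaze_recording` in the same display coordinates; its
#'   samples must span the display duration.
#' @param radius_px Disk radius in display pixels (default 75).
#' @return Object of class `looking_video`: list with `frames` (integer
#'   matrices; 0 = masked black), `palette`, `scale`, `radius_px`,
#'   `gaze` (frame-time gaze points, NA where black), and trial metadata.
#' @export
make_looking_video <- function(display_frames, recording, radius_px = 75) {
  if (!inherits(display_frames, "display_frames"))
    stopf("make_looking_video: display_frames must come from render_display_frames()")
  res <- display_frames$resolution
  ok <- recording$valid & !is.na(recording$x)
  if (any(recording$x[ok] > res[1] + 1e-9) || any(recording$y[ok] > res[2] + 1e-9))
    stopf("make_looking_video: recording coordinates exceed the display resolution")
  dur <- max(display_frames$frame_times)
  if (length(recording$t) && max(recording$t) < dur - 1 / length(display_frames$frames) * dur)
    warnf("make_looking_video: recording is shorter than the display")

  ft <- display_frames$frame_times
  half_frame <- if (length(ft) > 1) diff(ft[1:2]) / 2 else Inf
  vt <- recording$t[ok]; vx <- recording$x[ok]; vy <- recording$y[ok]

  n <- length(display_frames$frames)
  h <- nrow(display_frames$frames[[1]]); w <- ncol(display_frames$frames[[1]])
  frames <- vector("list", n)
  gaze <- matrix(NA_real_, n, 2)
  for (f in seq_len(n)) {
    img <- display_frames$frames[[f]]
    if (length(vt)) {
      k <- which.min(abs(vt - ft[f]))
      if (abs(vt[k] - ft[f]) <= half_frame) {
        m <- gaze_disk_mask(h, w, vx[k], vy[k], radius_px, display_frames$scale)
        img <- img * m  # 0 outside the disk
        gaze[f, ] <- c(vx[k], vy[k])
        frames[[f]] <- img
        next
      }
    }
    frames[[f]] <- matrix(0L, h, w)
  }
  structure(list(frames = frames, palette = display_frames$palette,
                 scale = display_frames$scale, radius_px = radius_px,
                 gaze = gaze,
                 participant_id = recording$participant_id,
                 trial_id = recording$trial_id,
                 condition = recording$condition),
            class = "looking_video")
}

#' Materialize one looking-video frame as an RGB array
#'
#' @param video A `looking_video` (or `display_frames`).
#' @param frame Frame index.
#' @return `height x width x 3` numeric array in `[0, 1]`.
#' @export
lv_frame_array <- function(video, frame) {
  img <- video$frames[[frame]]
  pal <- video$palette
  out <- array(0, dim = c(nrow(img), ncol(img), 3))
  for (ch in 1:3) out[, , ch] <- matrix(pal[ch, img + 1L], nrow(img), ncol(img))
  out
}

# ---- feature extractors -------------------------------------------------

.extractors <- new.env(parent = emptyenv())

#' Register a looking-video feature extractor
#'
#' @param id Extractor identifier.
#' @param fn Function `(video) -> matrix` (frames x feature dimensions).
#' @return `id`, invisibly.
#' @export
register_extractor <- function(id, fn) {
  assign(id, fn, envir = .extractors)
  invisible(id)
}

#' Extract a per-frame feature sequence from a looking video
#'
#' The default extractor (`"grid_pool"`) pools each frame's RGB values over
#' a coarse spatial grid (8 x 8 cells x 3 channels = 192 dimensions of cell
#' means; masked pixels contribute 0). It is deterministic and needs no
#' pretrained weights; alternative extractors (e.g., a pretrained image
#' network) can be plugged in via [register_extractor()].
#'
#' @param video A `looking_video`.
#' @param extractor_id Registered extractor name (default `"grid_pool"`).
#' @return Numeric matrix, frames x dimensions, with attribute
#'   `extractor_id`.
#' @export
extract_features <- function(video, extractor_id = "grid_pool") {
  if (!exists(extractor_id, envir = .extractors))
    stopf("extract_features: unknown extractor '%s'", extractor_id)
  fn <- get(extractor_id, envir = .extractors)
  out <- fn(video)
  attr(out, "extractor_id") <- extractor_id
  out
}

grid_pool_extractor <- function(grid = c(8, 8)) {
  force(grid)
  function(video) {
    h <- nrow(video$frames[[1]]); w <- ncol(video$frames[[1]])
    n_f <- length(video$frames)
    n_cell <- prod(grid)
    # separable pooling: cell sums = A %*% frame %*% B with 0/1 aggregators
    ri <- pmin(floor((seq_len(h) - 1) * grid[1] / h), grid[1] - 1) + 1L
    cj <- pmin(floor((seq_len(w) - 1) * grid[2] / w), grid[2] - 1) + 1L
    A <- matrix(0, grid[1], h); A[cbind(ri, seq_len(h))] <- 1
    B <- matrix(0, w, grid[2]); B[cbind(seq_len(w), cj)] <- 1
    counts <- tabulate(ri, grid[1]) %o% tabulate(cj, grid[2])
    pal <- video$palette
    out <- matrix(0, n_f, 3L * n_cell)
    for (f in seq_len(n_f)) {
      iv <- video$frames[[f]] + 1L
      for (ch in 1:3) {
        M <- matrix(pal[ch, ][iv], h, w)
        out[f, (ch - 1L) * n_cell + seq_len(n_cell)] <- (A %*% M %*% B) / counts
      }
    }
    out
  }
}

register_extractor("grid_pool", grid_pool_extractor(c(8, 8)))

# piecewise temporal pooling: mean feature vector within each of n_segments
# equal video segments, concatenated. Preserves when (not just whether)
# visual information was sampled, which carries the condition signal.
pool_sequence <- function(fs, n_segments = 8) {
  n <- nrow(fs)
  cuts <- floor(seq(0, n, length.out = n_segments + 1))
  unlist(lapply(seq_len(n_segments), function(s)
    colMeans(fs[(cuts[s] + 1):cuts[s + 1], , drop = FALSE])))
}

#' Classify one participant's looking videos
#'
#' Pools each trial's feature sequence over time (piecewise means across 8
#' equal video segments) and runs the repeated leave-one-out LS-SVM of
#' [classify_trials()] with a label-shuffle null ([shuffle_null()]). The
#' temporal-pooling + linear classifier route is deterministic given the
#' seed and needs no pretrained weights.
#'
#' @param trials List of trials; each either a `looking_video` (features
#'   are extracted with `extractor_id`) or a list with elements `features`
#'   (frames x d matrix) and `condition`.
#' @param n_reps Hold-out repetitions for the observed accuracy
#'   (default 500).
#' @param n_shuffles Label shuffles for the null (default 1000).
#' @param n_reps_per_shuffle Repetitions per shuffle (default 50).
#' @param seed Integer seed.
#' @param extractor_id Feature extractor for `looking_video` inputs.
#' @return A `classification_result` (see [shuffle_null()]).
#' @export
classify_participant <- function(trials, n_reps = 500, n_shuffles = 1000,
                                 n_reps_per_shuffle = 50, seed = 1,
                                 extractor_id = "grid_pool") {
  feats <- lapply(trials, function(tr) {
    if (inherits(tr, "looking_video")) extract_features(tr, extractor_id)
    else tr$features
  })
  labels <- vapply(trials, function(tr) tr$condition, character(1))
  X <- t(vapply(feats, pool_sequence, numeric(8 * ncol(feats[[1]]))))
  shuffle_null(X, labels, n_shuffles = n_shuffles,
               n_reps_per_shuffle = n_reps_per_shuffle,
               n_reps = n_reps, seed = seed)
}
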