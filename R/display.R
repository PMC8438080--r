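# Display specifications: per-frame AOI rectangles for the hammer-and-peg
# videos, event times, and the depth-order history used for front-most
# conflict resolution.

# Scene layout in reference 1920 x 1200 coordinates (origin top-left,
# x rightward, y downward). Rectangle sizes approximate the AOI areas of
# the stimulus set (hammer ~12.8k px, peg ~30k px, hands ~13.5k px,
# face ~25.2k px).
.scene <- list(
  face      = list(center = c(960, 280),  size = c(180, 140)),
  peg       = list(center = c(1400, 850), size = c(200, 150)),
  non_dominant_hand = list(center = c(380, 1075), size = c(150, 90)),
  hammer    = list(center = c(620, 875),  size = c(160, 80)),
  dominant_hand = list(center = c(1000, 1080), size = c(150, 90)),
  hammer_at_peg = c(1380, 780),
  hand_offset_at_peg = c(-60, 40)
)

rect_from_center <- function(center, size) {
  c(center[1] - size[1] / 2, center[2] - size[2] / 2,
    center[1] + size[1] / 2, center[2] + size[2] / 2)
}

# piecewise-linear interpolation of a center through (time, x, y) keyframes
interp_center <- function(times, keys_t, keys_xy) {
  x <- stats::approx(keys_t, keys_xy[, 1], xout = times, rule = 2)$y
  y <- stats::approx(keys_t, keys_xy[, 2], xout = times, rule = 2)$y
  cbind(x, y)
}

#' Generate a display specification for one stimulus video
#'
#' Builds per-frame rectangles for the 5 AOIs (hammer, peg, dominant hand,
#' non-dominant hand, face) following the scripted action: hands at rest
#' until movement onset, the dominant hand reaches the hammer by the grasp
#' time, hammer and hand travel to the peg by the hammering time, and pound
#' until the video ends. A depth-order history records every frame at which
#' one AOI's rectangle moves into another's space; the most recent mover is
#' treated as front-most when gaze falls inside overlapping AOIs.
#'
#' @param duration_s Video duration in seconds (default 5.4).
#' @param frame_rate_hz Video frame rate (default 30).
#' @param movement_onset_s Time the actor starts moving (default 2.5).
#' @param grasp_s Time of the initial grip on the hammer (default 3.5).
#' @param hammering_s Time pounding begins at the peg (default 4.0).
#' @param resolution `c(width, height)` in pixels (default 1920 x 1200).
#' @param condition One of `"efficient"`, `"inefficient"`, `"localizer_a"`,
#'   `"localizer_b"`. The AOI kinematics are identical across conditions
#'   (the grip difference lives in the actor's hand posture, not in the
#'   rectangle tracks); the label is carried through to all downstream
#'   bookkeeping.
#' @return Object of class `display_spec`: list with `resolution`, `fps`,
#'   `duration_s`, `n_frames`, `frame_times`, `condition`, `events`,
#'   `aoi_tracks` (per AOI an `n_frames x 4` matrix `x0,y0,x1,y1`), and
#'   `depth_history` (data.frame `frame`, `time`, `mover`, `other`).
#' @export
gen_display_spec <- function(duration_s = 5.4, frame_rate_hz = 30,
                             movement_onset_s = 2.5, grasp_s = 3.5,
                             hammering_s = 4.0,
                             resolution = c(1920, 1200),
                             condition = "efficient") {
  if (!(frame_rate_hz > 0)) stopf("gen_display_spec: frame_rate_hz must be > 0")
  if (!(0 < movement_onset_s && movement_onset_s < grasp_s &&
        grasp_s < hammering_s && hammering_s < duration_s))
    stopf("gen_display_spec: event times must satisfy 0 < movement < grasp < hammering < duration")
  condition <- match.arg(condition, CONDITIONS)

  n_frames <- floor(duration_s * frame_rate_hz)
  frame_times <- (seq_len(n_frames) - 1) / frame_rate_hz
  sx <- resolution[1] / 1920
  sy <- resolution[2] / 1200
  scale_xy <- function(p) c(p[1] * sx, p[2] * sy)
  scale_sz <- function(p) c(p[1] * sx, p[2] * sy)

  pound <- 20 * sy * sin(2 * pi * 2 * pmax(frame_times - hammering_s, 0))

  centers <- list()
  centers$face <- matrix(rep(scale_xy(.scene$face$center), each = n_frames), ncol = 2)
  centers$peg <- matrix(rep(scale_xy(.scene$peg$center), each = n_frames), ncol = 2)
  centers$non_dominant_hand <-
    matrix(rep(scale_xy(.scene$non_dominant_hand$center), each = n_frames), ncol = 2)

  hammer0 <- scale_xy(.scene$hammer$center)
  hand0 <- scale_xy(.scene$dominant_hand$center)
  hammer_peg <- scale_xy(.scene$hammer_at_peg)
  hand_off <- scale_xy(.scene$hand_offset_at_peg)

  centers$hammer <- interp_center(
    frame_times,
    c(0, grasp_s, hammering_s, duration_s),
    rbind(hammer0, hammer0, hammer_peg, hammer_peg))
  centers$hammer[, 2] <- centers$hammer[, 2] + pound

  centers$dominant_hand <- interp_center(
    frame_times,
    c(0, movement_onset_s, grasp_s, hammering_s, duration_s),
    rbind(hand0, hand0, hammer0, hammer_peg + hand_off, hammer_peg + hand_off))
  post <- frame_times >= hammering_s
  centers$dominant_hand[post, 2] <- centers$dominant_hand[post, 2] + pound[post]

  sizes <- list(face = scale_sz(.scene$face$size),
                peg = scale_sz(.scene$peg$size),
                non_dominant_hand = scale_sz(.scene$non_dominant_hand$size),
                hammer = scale_sz(.scene$hammer$size),
                dominant_hand = scale_sz(.scene$dominant_hand$size))

  aoi_tracks <- lapply(AOI_NAMES, function(a) {
    sz <- sizes[[a]]
    cc <- centers[[a]]
    cbind(cc[, 1] - sz[1] / 2, cc[, 2] - sz[2] / 2,
          cc[, 1] + sz[1] / 2, cc[, 2] + sz[2] / 2)
  })
  names(aoi_tracks) <- AOI_NAMES

  spec <- list(resolution = resolution, fps = frame_rate_hz,
               duration_s = duration_s, n_frames = n_frames,
               frame_times = frame_times, condition = condition,
               events = list(onset = 0, movement = movement_onset_s,
                             grasp = grasp_s, hammering = hammering_s,
                             end = duration_s),
               aoi_tracks = aoi_tracks)
  spec$depth_history <- depth_history(spec)
  class(spec) <- "display_spec"
  spec
}

rects_overlap <- function(r1, r2) {
  r1[1] < r2[3] && r2[1] < r1[3] && r1[2] < r2[4] && r2[2] < r1[4]
}

# One row per onset of an overlap between an ordered AOI pair, attributed to
# the AOI that moved into the other's space (the mover). When both moved,
# the larger frame-to-frame displacement wins; a static pair overlapping at
# the first frame yields no event (front-most then falls back to the
# canonical AOI order).
depth_history <- function(spec) {
  tracks <- spec$aoi_tracks
  n <- spec$n_frames
  ev <- list()
  disp <- lapply(tracks, function(m) {
    d <- rbind(0, abs(diff(m[, 1, drop = FALSE])) + abs(diff(m[, 2, drop = FALSE])))
    as.numeric(d)
  })
  pairs <- aoi_pairs()
  for (k in seq_len(nrow(pairs))) {
    a <- pairs$a[k]; b <- pairs$b[k]
    ov <- vapply(seq_len(n), function(f) rects_overlap(tracks[[a]][f, ], tracks[[b]][f, ]),
                 logical(1))
    starts <- which(ov & !c(FALSE, ov[-n]))
    for (f in starts) {
      if (f == 1 && disp[[a]][1] == 0 && disp[[b]][1] == 0) next
      mover <- if (disp[[a]][f] >= disp[[b]][f]) a else b
      other <- if (mover == a) b else a
      ev[[length(ev) + 1L]] <- data.frame(frame = f, time = spec$frame_times[f],
                                          mover = mover, other = other,
                                          stringsAsFactors = FALSE)
    }
  }
  if (!length(ev)) {
    return(data.frame(frame = integer(0), time = numeric(0),
                      mover = character(0), other = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, ev)
  out[order(out$frame), , drop = FALSE]
}

#' @export
print.display_spec <- function(x, ...) {
  cat(sprintf("<display_spec> %s, %dx%d px, %g fps, %.2f s (%d frames)\n",
              x$condition, x$resolution[1], x$resolution[2], x$fps,
              x$duration_s, x$n_frames))
  cat(sprintf("  events: movement %.2fs, grasp %.2fs, hammering %.2fs\n",
              x$events$movement, x$events$grasp, x$events$hammering))
  cat(sprintf("  depth history: %d entry events\n", nrow(x$depth_history)))
  invisible(x)
}

# nearest frame index for a display time (samples are scored against the
# nearest frame's rectangles; no snapping of sample timestamps)
frame_at_time <- function(spec, t_s) {
  if (any(t_s < 0 | t_s > spec$duration_s))
    stopf("sample time outside display duration [0, %g]", spec$duration_s)
  pmin(pmax(round(t_s * spec$fps) + 1L, 1L), spec$n_frames)
}

#' Write / read a display specification as JSON
#'
#' Schema: `events{onset,movement,grasp,hammering,end}`, `fps`,
#' `resolution`, `condition`, `aoi_tracks[name]` (n_frames x 4 arrays of
#' `x0,y0,x1,y1`), `depth_history`.
#'
#' @param spec A `display_spec`.
#' @param path Output / input file path.
#' @return `read_display_json` returns the `display_spec`;
#'   `write_display_json` returns `path` invisibly.
#' @export
write_display_json <- function(spec, path) {
  obj <- list(resolution = spec$resolution, fps = spec$fps,
              duration_s = spec$duration_s, condition = spec$condition,
              events = spec$events,
              aoi_tracks = lapply(spec$aoi_tracks, function(m) unname(m)),
              depth_history = spec$depth_history)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_display_json
#' @export
read_display_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- list(resolution = obj$resolution, fps = obj$fps,
               duration_s = obj$duration_s,
               n_frames = nrow(obj$aoi_tracks[[1]]),
               condition = obj$condition,
               events = as.list(obj$events),
               aoi_tracks = lapply(obj$aoi_tracks, as.matrix))
  spec$frame_times <- (seq_len(spec$n_frames) - 1) / spec$fps
  dh <- obj$depth_history
  if (is.null(dh) || length(dh) == 0 || NROW(dh) == 0) {
    dh <- data.frame(frame = integer(0), time = numeric(0),
                     mover = character(0), other = character(0),
                     stringsAsFactors = FALSE)
  }
  spec$depth_history <- as.data.frame(dh)
  class(spec) <- "display_spec"
  spec
}
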