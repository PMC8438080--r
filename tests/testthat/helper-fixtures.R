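# shared fixtures: hand-built recordings and displays small enough to
# verify by brute force

# a gaze recording from explicit sample vectors
make_recording <- function(t, x, y, pupil = NULL, valid = NULL,
                           condition = "efficient", pid = "t1", trial = 1L) {
  n <- length(t)
  structure(list(participant_id = pid, trial_id = trial, condition = condition,
                 t = t, x = x, y = y,
                 pupil = pupil %||% rep(4, n),
                 valid = valid %||% rep(TRUE, n)),
            class = "gaze_recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# display with static, hand-chosen AOI rectangles (x0, y0, x1, y1)
static_display <- function(rects, resolution = c(400, 300), fps = 30,
                           duration_s = 2, depth = NULL) {
  n_frames <- floor(duration_s * fps)
  tracks <- lapply(aoi_names(), function(a) {
    r <- rects[[a]] %||% c(-10, -10, -5, -5)  # off-screen when unspecified
    matrix(rep(r, each = n_frames), n_frames, 4)
  })
  names(tracks) <- aoi_names()
  structure(list(resolution = resolution, fps = fps, duration_s = duration_s,
                 n_frames = n_frames,
                 frame_times = (seq_len(n_frames) - 1) / fps,
                 condition = "efficient",
                 events = list(onset = 0, movement = duration_s * 0.4,
                               grasp = duration_s * 0.6,
                               hammering = duration_s * 0.8,
                               end = duration_s),
                 aoi_tracks = tracks,
                 depth_history = depth %||%
                   data.frame(frame = integer(0), time = numeric(0),
                              mover = character(0), other = character(0),
                              stringsAsFactors = FALSE)),
            class = "display_spec")
}

# brute-force Benjamini-Hochberg step-up, by direct enumeration
bh_oracle <- function(p, q) {
  m <- length(p)
  if (!m) return(logical(0))
  o <- order(p)
  ps <- p[o]
  k <- suppressWarnings(max(which(ps <= seq_len(m) / m * q)))
  out <- rep(FALSE, m)
  if (is.finite(k)) out[o[seq_len(k)]] <- TRUE
  out
}

# brute-force connected components of negative supra-threshold cells via
# igraph (independent of the package's flood-fill/union-find route)
cluster_oracle <- function(tmap, thresh) {
  supra <- which(tmap < -thresh)
  if (!length(supra)) return(list())
  nr <- nrow(tmap)
  r <- (supra - 1) %% nr + 1
  cc <- (supra - 1) %/% nr + 1
  edges <- c()
  for (i in seq_along(supra)) for (j in seq_along(supra)) {
    if (i < j && abs(r[i] - r[j]) + abs(cc[i] - cc[j]) == 1)
      edges <- c(edges, i, j)
  }
  g <- igraph::make_empty_graph(n = length(supra), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  unname(split(supra, comp))
}

# canonical form for comparing cluster partitions
canon_clusters <- function(cl) {
  if (!length(cl)) return(list())
  cl <- lapply(cl, sort)
  cl[order(vapply(cl, min, numeric(1)))]
}
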