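# Synthetic gaze + pupil recordings: piecewise-constant fixation targets
# with Gaussian jitter and instantaneous saccades, a smooth pupil baseline
# with an optional condition-dependent dilation bump, and blink injection.

# Raised-cosine-tapered plateau (Tukey window) on [t0, t1]; `taper` is the
# fraction of the window ramped at each edge.
tukey_bump <- function(t, t0, t1, taper = 0.25) {
  w <- t1 - t0
  u <- (t - t0) / w
  out <- numeric(length(t))
  inside <- u >= 0 & u <= 1
  ui <- u[inside]
  v <- rep(1, length(ui))
  lo <- ui < taper
  hi <- ui > 1 - taper
  v[lo] <- 0.5 * (1 - cos(pi * ui[lo] / taper))
  v[hi] <- 0.5 * (1 - cos(pi * (1 - ui[hi]) / taper))
  out[inside] <- v
  out
}

aoi_center_at <- function(spec, aoi, frames) {
  r <- spec$aoi_tracks[[aoi]][frames, , drop = FALSE]
  cbind((r[, 1] + r[, 3]) / 2, (r[, 2] + r[, 4]) / 2)
}

# Fixation schedule: data.frame(start, end, aoi, ox, oy). Gaze follows the
# (possibly moving) AOI center plus a within-AOI offset; condition terms are
# all scaled by the profile's gaze_condition_effect so a zero effect makes
# the two test conditions exchangeable.
scanpath_schedule <- function(display, profile, condition) {
  ev <- display$events
  eff <- profile$gaze_condition_effect
  sgn <- switch(condition, inefficient = 1, efficient = -1, 0)
  dur_end <- display$duration_s
  sx <- display$resolution[1] / 1920

  draw_dur <- function(mean_s) stats::rlnorm(1, log(mean_s), 0.30)
  segs <- list()
  t <- 0
  push <- function(t0, t1, aoi, ox = 0, oy = 0) {
    segs[[length(segs) + 1L]] <<- data.frame(start = t0, end = t1, aoi = aoi,
                                             ox = ox, oy = oy,
                                             stringsAsFactors = FALSE)
  }

  # pre-movement: face-dominated scanning for both profiles
  while (t < ev$movement) {
    aoi <- sample(c("face", "hammer", "peg"), 1, prob = c(0.6, 0.25, 0.15))
    d <- draw_dur(0.40)
    push(t, min(t + d, ev$movement), aoi)
    t <- t + d
  }
  t <- ev$movement

  if (profile$label == "adult_like") {
    # reach: strict hand<->hammer alternation; the condition shifts how the
    # dwell splits between the grip (hammer handle) and the moving hand,
    # and pulls gaze toward the grip point on the handle
    bias <- 0.5 * tanh(eff) * sgn
    grip_oy <- -30 * sx * eff * sgn
    aoi <- "dominant_hand"
    while (t < ev$grasp) {
      aoi <- if (aoi == "hammer") "dominant_hand" else "hammer"
      d <- draw_dur(0.25 * (1 + if (aoi == "hammer") bias else -bias))
      push(t, min(t + d, ev$grasp), aoi,
           oy = if (aoi == "hammer") grip_oy else 0)
      t <- t + d
    }
    t <- ev$grasp
    # grip-to-transport: inefficient re-grips hold gaze on the hand
    while (t < ev$hammering) {
      aoi <- if (aoi == "dominant_hand") "hammer" else "dominant_hand"
      d <- draw_dur(0.22 * (1 + if (aoi == "dominant_hand") bias else -bias))
      push(t, min(t + d, ev$hammering), aoi, oy = if (aoi == "hammer") grip_oy else 0)
      t <- t + d
    }
    t <- ev$hammering
    # pounding: rapid hammer<->peg alternation
    while (t < dur_end) {
      aoi <- if (stats::runif(1) < 0.5) "hammer" else "peg"
      d <- draw_dur(0.22)
      push(t, min(t + d, dur_end), aoi)
      t <- t + d
    }
  } else {
    # child-like: brief carry-over, then an early anticipatory jump to the
    # peg regardless of condition
    jump <- min(ev$movement + profile$anticipation_latency, dur_end)
    if (jump > t) push(t, jump, "face")
    t <- jump
    while (t < dur_end) {
      aoi <- sample(c("peg", "face", "hammer"), 1,
                    prob = c(0.85, 0.12, 0.03 + 0.05 * eff * abs(sgn)))
      d <- draw_dur(0.45)
      push(t, min(t + d, dur_end), aoi)
      t <- t + d
    }
  }
  do.call(rbind, segs)
}

#' Generate one synthetic gaze + pupil recording
#'
#' Samples a fixation scanpath against a display specification at the
#' tracker rate: piecewise-constant fixation targets (AOI centers plus
#' within-AOI offsets) with additive Gaussian jitter and instantaneous
#' saccades. Adult-like profiles fixate the hammer/hand during the reach
#' with condition-dependent dwell and grip-point offsets scaled by
#' `gaze_condition_effect`; child-like profiles jump to the peg
#' `anticipation_latency` seconds after movement onset regardless of
#' condition. A pupil channel is included, with an optional dilation bump
#' (percent of baseline, Tukey-windowed over 0.7-1.4 s after the grasp) on
#' inefficient trials. Blinks are injected as contiguous invalid runs.
#'
#' @param display A [gen_display_spec()] result.
#' @param profile A [sim_profile()].
#' @param condition Trial condition; defaults to the display's.
#' @param sampling_hz Tracker rate (default 120).
#' @param seed Integer seed; the same seed reproduces the recording bit for
#'   bit.
#' @param participant_id,trial_id Metadata carried into the recording.
#' @param noise_sd Per-fixation gaze placement jitter SD in px (default
#'   15): each fixation lands at a jittered offset from its target.
#' @param tracker_noise_sd Per-sample measurement noise SD in px (default
#'   5), the tracker's sample-to-sample precision.
#' @param blink_rate Expected fraction of samples lost to blinks
#'   (default 0.02); set 0 to disable.
#' @return Object of class `gaze_recording`: list with `participant_id`,
#'   `trial_id`, `condition`, `t`, `x`, `y`, `pupil`, `valid`.
#' @export
gen_gaze_recording <- function(display, profile, condition = display$condition,
                               sampling_hz = 120, seed = 1,
                               participant_id = "p1", trial_id = 1L,
                               noise_sd = 15, tracker_noise_sd = 5,
                               blink_rate = 0.02) {
  if (!(sampling_hz > 0)) stopf("gen_gaze_recording: sampling_hz must be > 0")
  condition <- match.arg(condition, CONDITIONS)
  with_seed(seed, {
    n <- floor(display$duration_s * sampling_hz)
    t <- (seq_len(n) - 1) / sampling_hz
    sched <- scanpath_schedule(display, profile, condition)
    seg <- findInterval(t, sched$start)
    seg[seg < 1L] <- 1L
    frames <- frame_at_time(display, t)

    x <- numeric(n); y <- numeric(n)
    for (s in unique(seg)) {
      idx <- which(seg == s)
      ctr <- aoi_center_at(display, sched$aoi[s], frames[idx])
      x[idx] <- ctr[, 1] + sched$ox[s] + stats::rnorm(1, 0, noise_sd)
      y[idx] <- ctr[, 2] + sched$oy[s] + stats::rnorm(1, 0, noise_sd)
    }
    x <- x + stats::rnorm(n, 0, tracker_noise_sd)
    y <- y + stats::rnorm(n, 0, tracker_noise_sd)
    x <- pmin(pmax(x, 0), display$resolution[1])
    y <- pmin(pmax(y, 0), display$resolution[2])

    # pupil: smooth baseline with drift, measurement noise, and the
    # inefficiency-triggered dilation bump
    base <- 4 * exp(stats::rnorm(1, 0, 0.05))
    drift <- 0.005 * sin(2 * pi * 0.15 * t + stats::runif(1, 0, 2 * pi))
    bump_amp <- (profile$pupil_effect / 100) * (condition == "inefficient")
    bump <- bump_amp * tukey_bump(t, display$events$grasp + 0.7,
                                  display$events$grasp + 1.4)
    pupil <- base * (1 + drift + bump + stats::rnorm(n, 0, 0.02))

    valid <- rep(TRUE, n)
    if (blink_rate > 0) {
      mean_blink_s <- 0.175
      n_blinks <- stats::rpois(1, blink_rate * display$duration_s / mean_blink_s)
      if (n_blinks > 0) {
        starts <- stats::runif(n_blinks, 0, display$duration_s)
        lens <- stats::runif(n_blinks, 0.10, 0.25)
        for (k in seq_len(n_blinks)) {
          valid[t >= starts[k] & t < starts[k] + lens[k]] <- FALSE
        }
      }
    }
    x[!valid] <- NA_real_; y[!valid] <- NA_real_; pupil[!valid] <- NA_real_

    structure(list(participant_id = participant_id, trial_id = trial_id,
                   condition = condition, t = t, x = x, y = y,
                   pupil = pupil, valid = valid),
              class = "gaze_recording")
  })
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf("<gaze_recording> %s trial %s (%s): %d samples @ %.0f Hz, %.1f%% valid\n",
              x$participant_id, x$trial_id, x$condition, length(x$t),
              1 / stats::median(diff(x$t)), 100 * mean(x$valid)))
  invisible(x)
}

#' Write / read gaze recordings as tidy CSV
#'
#' Columns: `participant`, `trial`, `condition`, `t_s`, `x_px`, `y_px`,
#' `pupil`, `valid` (0/1). Invalid samples carry empty position/pupil
#' fields.
#'
#' @param recordings A `gaze_recording` or list of them.
#' @param path File path.
#' @return `read_gaze_csv` returns a list of `gaze_recording`s;
#'   `write_gaze_csv` returns `path` invisibly.
#' @export
write_gaze_csv <- function(recordings, path) {
  if (inherits(recordings, "gaze_recording")) recordings <- list(recordings)
  rows <- lapply(recordings, function(r) {
    data.frame(participant = r$participant_id, trial = r$trial_id,
               condition = r$condition, t_s = r$t, x_px = r$x, y_px = r$y,
               pupil = r$pupil, valid = as.integer(r$valid))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_gaze_csv
#' @export
read_gaze_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  key <- interaction(df$participant, df$trial, drop = TRUE)
  lapply(split(df, key), function(d) {
    d <- d[order(d$t_s), ]
    structure(list(participant_id = as.character(d$participant[1]),
                   trial_id = d$trial[1], condition = d$condition[1],
                   t = d$t_s, x = d$x_px, y = d$y_px, pupil = d$pupil,
                   valid = d$valid == 1L),
              class = "gaze_recording")
  })
}
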