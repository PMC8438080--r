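# Dynamic AOI assignment, dispersion-based fixation detection, and the
# dwell / fixation / revisit / gaze-shift measures.

#' Assign gaze samples to AOIs with front-most conflict resolution
#'
#' For each sample, finds the AOI rectangle(s) containing the point at the
#' nearest video frame (inclusive bounds). When several AOIs contain the
#' point, the conflict is resolved by depth order: the AOI that most
#' recently moved into the space of another AOI (per the display's depth
#' history, up to the sample's frame) is front-most. If no containing AOI
#' has a recorded entry event, the first in the canonical AOI order wins
#' (deterministic tie-break).
#'
#' @param x,y Sample coordinates in display pixels (may be vectors).
#' @param t_s Sample times in seconds from display onset; must lie within
#'   the display duration.
#' @param display A `display_spec`.
#' @return Character vector of AOI names, `NA` where the point is outside
#'   all AOIs.
#' @export
assign_aoi <- function(x, y, t_s, display) {
  frames <- frame_at_time(display, t_s)
  n <- length(x)
  contains <- matrix(FALSE, n, length(AOI_NAMES),
                     dimnames = list(NULL, AOI_NAMES))
  for (a in AOI_NAMES) {
    r <- display$aoi_tracks[[a]][frames, , drop = FALSE]
    contains[, a] <- !is.na(x) & x >= r[, 1] & x <= r[, 3] &
      y >= r[, 2] & y <= r[, 4]
  }
  out <- rep(NA_character_, n)
  cnt <- rowSums(contains)
  single <- which(cnt == 1L)
  if (length(single))
    out[single] <- AOI_NAMES[max.col(contains[single, , drop = FALSE])]
  multi <- which(cnt > 1L)
  if (length(multi)) {
    dh <- display$depth_history
    for (i in multi) {
      cand <- AOI_NAMES[contains[i, ]]
      last_entry <- vapply(cand, function(a) {
        fr <- dh$frame[dh$mover == a & dh$frame <= frames[i]]
        if (length(fr)) max(fr) else -Inf
      }, numeric(1))
      out[i] <- cand[which.max(last_entry)]  # ties: earliest canonical AOI
    }
  }
  out
}

#' Detect fixations with the dispersion (I-DT) algorithm
#'
#' Groups consecutive valid samples whose dispersion
#' (`(max(x) - min(x)) + (max(y) - min(y))`) stays within
#' `dispersion_px`, growing each group greedily; groups shorter than
#' `min_dur_s` are discarded. Runs are broken at invalid samples. Each
#' fixation is labeled with the majority AOI of its per-sample assignments
#' (ties broken by the canonical AOI order; `NA` when most samples fall
#' outside all AOIs).
#'
#' @param recording A `gaze_recording`.
#' @param display A `display_spec` (used for AOI labeling; `NULL` leaves
#'   labels `NA`).
#' @param min_dur_s Minimum fixation duration in seconds (default 0.100).
#' @param dispersion_px Dispersion threshold in pixels (default 50, chosen
#'   for 120 Hz recordings on a 1920 x 1200 display).
#' @return data.frame of class `fixations` with columns `start_s`, `end_s`,
#'   `x`, `y` (centroid), `aoi`. The end time extends one sample interval
#'   past the last sample so durations equal covered time.
#' @export
detect_fixations <- function(recording, display = NULL, min_dur_s = 0.100,
                             dispersion_px = 50) {
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      x = numeric(0), y = numeric(0), aoi = character(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("fixations", "data.frame")
  v <- which(recording$valid & !is.na(recording$x))
  if (!length(v)) return(empty)
  dt <- stats::median(diff(recording$t))
  runs <- split(v, cumsum(c(TRUE, diff(v) > 1L)))

  fixes <- list()
  for (run in runs) {
    t <- recording$t[run]; x <- recording$x[run]; y <- recording$y[run]
    n <- length(run)
    i <- 1L
    while (i <= n) {
      j <- i
      xmin <- x[i]; xmax <- x[i]; ymin <- y[i]; ymax <- y[i]
      while (j < n) {
        nxmin <- min(xmin, x[j + 1]); nxmax <- max(xmax, x[j + 1])
        nymin <- min(ymin, y[j + 1]); nymax <- max(ymax, y[j + 1])
        if ((nxmax - nxmin) + (nymax - nymin) > dispersion_px) break
        xmin <- nxmin; xmax <- nxmax; ymin <- nymin; ymax <- nymax
        j <- j + 1L
      }
      dur <- t[j] - t[i] + dt
      if (dur >= min_dur_s) {
        fixes[[length(fixes) + 1L]] <-
          data.frame(start_s = t[i], end_s = t[j] + dt,
                     x = mean(x[i:j]), y = mean(y[i:j]),
                     i0 = run[i], i1 = run[j], stringsAsFactors = FALSE)
      }
      i <- j + 1L
    }
  }
  if (!length(fixes)) return(empty)
  fx <- do.call(rbind, fixes)

  fx$aoi <- NA_character_
  if (!is.null(display)) {
    for (k in seq_len(nrow(fx))) {
      idx <- fx$i0[k]:fx$i1[k]
      labs <- assign_aoi(recording$x[idx], recording$y[idx],
                         recording$t[idx], display)
      labs <- labs[!is.na(labs)]
      if (length(labs) > (fx$i1[k] - fx$i0[k] + 1L) / 2) {
        tab <- table(factor(labs, levels = AOI_NAMES))
        fx$aoi[k] <- AOI_NAMES[which.max(tab)]
      }
    }
  }
  fx$i0 <- NULL; fx$i1 <- NULL
  class(fx) <- c("fixations", "data.frame")
  fx
}

#' Per-trial looking measures
#'
#' Percent dwell time (AOI sample time / total tracked time), percent
#' fixation time (AOI fixation time / total fixation time), and revisit
#' counts (entries into the AOI from outside it; the first entry counts).
#' Invalid samples are excluded from both numerator and denominator of
#' dwell.
#'
#' @param recording A `gaze_recording`.
#' @param display A `display_spec`.
#' @param fixations Result of [detect_fixations()] on the same recording.
#' @return data.frame with one row per AOI: `aoi`, `pct_dwell`,
#'   `pct_fixation`, `revisits`; attribute `pct_off_aoi` carries the dwell
#'   share outside all AOIs so AOI dwell + off-AOI dwell = 100.
#' @export
looking_measures <- function(recording, display, fixations) {
  v <- recording$valid & !is.na(recording$x)
  if (!any(v)) stopf("looking_measures: zero tracked time")
  labs <- assign_aoi(recording$x[v], recording$y[v], recording$t[v], display)
  n_tracked <- sum(v)
  dwell <- 100 * as.numeric(table(factor(labs, levels = AOI_NAMES))) / n_tracked

  fix_time <- setNames(numeric(length(AOI_NAMES)), AOI_NAMES)
  total_fix <- 0
  if (nrow(fixations)) {
    durs <- fixations$end_s - fixations$start_s
    total_fix <- sum(durs)
    on <- !is.na(fixations$aoi)
    if (any(on)) {
      agg <- tapply(durs[on], factor(fixations$aoi[on], levels = AOI_NAMES), sum)
      fix_time[] <- ifelse(is.na(agg), 0, agg)
    }
  }
  pct_fix <- if (total_fix > 0) 100 * fix_time / total_fix else rep(0, length(AOI_NAMES))

  revisits <- vapply(AOI_NAMES, function(a) {
    inside <- !is.na(labs) & labs == a
    sum(inside & !c(FALSE, inside[-length(inside)]))
  }, numeric(1))

  out <- data.frame(aoi = AOI_NAMES, pct_dwell = dwell,
                    pct_fixation = as.numeric(pct_fix),
                    revisits = as.integer(revisits),
                    stringsAsFactors = FALSE)
  attr(out, "pct_off_aoi") <- 100 * sum(is.na(labs)) / n_tracked
  out
}

#' Gaze-shift transition matrix
#'
#' A gaze shift occurs when two consecutive fixations land on different
#' AOIs with an inter-fixation gap of at most `max_gap_s`. Shifts in both
#' directions between a pair are pooled, yielding counts over the 10
#' unordered AOI pairs.
#'
#' @param fixations A time-ordered [detect_fixations()] result.
#' @param max_gap_s Maximum gap between fixations (default 0.100 s).
#' @return Object of class `transition_matrix`: list with `pairs`
#'   (data.frame `a`, `b`, `count`) and `matrix` (symmetric 5 x 5 with zero
#'   diagonal).
#' @export
gaze_shifts <- function(fixations, max_gap_s = 0.100) {
  m <- matrix(0L, length(AOI_NAMES), length(AOI_NAMES),
              dimnames = list(AOI_NAMES, AOI_NAMES))
  if (nrow(fixations) >= 2L) {
    for (k in seq_len(nrow(fixations) - 1L)) {
      a <- fixations$aoi[k]; b <- fixations$aoi[k + 1L]
      gap <- fixations$start_s[k + 1L] - fixations$end_s[k]
      if (!is.na(a) && !is.na(b) && a != b && gap <= max_gap_s) {
        m[a, b] <- m[a, b] + 1L
        m[b, a] <- m[b, a] + 1L
      }
    }
  }
  pairs <- aoi_pairs()
  pairs$count <- m[cbind(pairs$a, pairs$b)]
  structure(list(pairs = pairs, matrix = m), class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("<transition_matrix> pooled gaze-shift counts over 10 AOI pairs\n")
  print(x$pairs[x$pairs$count > 0, , drop = FALSE], row.names = FALSE)
  invisible(x)
}

#' Write looking measures or transitions as tidy CSV
#'
#' One row per participant x trial x AOI (measures) or x pair
#' (transitions).
#'
#' @param rows A data.frame accumulated from [looking_measures()] or
#'   `transition_matrix$pairs` results (caller adds participant/trial
#'   columns).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_measures_csv <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
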