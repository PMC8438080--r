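# Pupillometry: artifact cleaning, baseline normalization to percent of
# baseline, and time-resolved condition comparison with FDR control.

#' Clean a pupil trace
#'
#' Vendor-independent artifact rule: samples are flagged when already
#' invalid in the recording, when pupil size is non-positive, or when it
#' deviates more than `mad_k` MADs from the trial median; flags are
#' expanded by `margin_s` on each side (blink edges). Gaps no longer than
#' `max_gap_s` are bridged by linear interpolation; longer gaps stay
#' missing. Trials with more than half the samples missing after cleaning
#' are flagged unusable (with a warning) and excluded downstream.
#'
#' @param recording A `gaze_recording` with a pupil channel.
#' @param max_gap_s Longest gap bridged by interpolation (default 0.3 s).
#' @param mad_k Outlier threshold in MADs (default 5).
#' @param margin_s Margin added around flagged runs (default 0.05 s).
#' @return Object of class `pupil_clean`: list with `t`, `pupil` (NA in
#'   unbridged gaps), `usable`, `frac_missing`, and trial metadata.
#' @export
preprocess_pupil <- function(recording, max_gap_s = 0.3, mad_k = 5,
                             margin_s = 0.05) {
  if (is.null(recording$pupil)) stopf("preprocess_pupil: recording has no pupil channel")
  t <- recording$t
  p <- recording$pupil
  bad <- !recording$valid | is.na(p) | p <= 0
  med <- stats::median(p[!bad])
  md <- stats::mad(p[!bad])
  if (is.finite(md) && md > 0) bad <- bad | (!is.na(p) & abs(p - med) > mad_k * md)
  # expand flagged runs by the margin
  if (any(bad) && margin_s > 0) {
    bt <- t[bad]
    near <- vapply(t, function(ti) any(abs(bt - ti) <= margin_s), logical(1))
    bad <- bad | near
  }
  p[bad] <- NA_real_

  # bridge short gaps only
  if (any(bad) && any(!bad)) {
    interp <- stats::approx(t[!bad], p[!bad], xout = t, rule = 1)$y
    runs <- rle(bad)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    dt <- stats::median(diff(t))
    for (k in which(runs$values)) {
      gap_len <- (runs$lengths[k]) * dt
      if (gap_len <= max_gap_s) {
        idx <- starts[k]:ends[k]
        p[idx] <- interp[idx]
      }
    }
  }
  frac_missing <- mean(is.na(p))
  usable <- frac_missing <= 0.5
  if (!usable)
    warnf("preprocess_pupil: trial %s/%s unusable (%.0f%% missing)",
          recording$participant_id, recording$trial_id, 100 * frac_missing)
  structure(list(t = t, pupil = p, usable = usable,
                 frac_missing = frac_missing,
                 participant_id = recording$participant_id,
                 trial_id = recording$trial_id,
                 condition = recording$condition),
            class = "pupil_clean")
}

#' Normalize a cleaned pupil trace to percent of baseline
#'
#' Baseline pupil size is the mean over the first `baseline_window` of
#' display time (default the first 1250 ms, before the actor moves). The
#' trace is mean-binned down to `out_hz` and re-expressed as
#' `100 * raw / baseline`, with times relative to movement onset.
#' Bins with no surviving samples stay `NA` (gaps remain marked).
#'
#' @param cleaned A [preprocess_pupil()] result.
#' @param events Display event list (needs `movement` and `end`), e.g.,
#'   `display$events`.
#' @param out_hz Output rate (default 30).
#' @param baseline_window `c(start, end)` seconds of display time
#'   (default `c(0, 1.25)`); must contain tracked samples.
#' @return Object of class `pupil_trace`: list with `t` (s relative to
#'   movement onset), `value` (% of baseline), `baseline_mean`,
#'   `baseline_window`, `usable`, and trial metadata.
#' @export
normalize_trace <- function(cleaned, events, out_hz = 30,
                            baseline_window = c(0, 1.25)) {
  if (baseline_window[2] > events$movement + 1e-9)
    stopf("normalize_trace: baseline window must precede movement onset")
  in_base <- cleaned$t >= baseline_window[1] & cleaned$t <= baseline_window[2]
  base_vals <- cleaned$pupil[in_base]
  if (!length(base_vals) || all(is.na(base_vals)))
    stopf("normalize_trace: empty baseline window")
  baseline <- mean(base_vals, na.rm = TRUE)

  rel <- cleaned$t - events$movement
  bins <- floor(rel * out_hz)
  bin_levels <- seq(min(bins), max(bins))
  means <- tapply(cleaned$pupil, factor(bins, levels = bin_levels),
                  function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  structure(list(t = (bin_levels + 0.5) / out_hz,
                 value = 100 * as.numeric(means) / baseline,
                 baseline_mean = baseline, baseline_window = baseline_window,
                 usable = cleaned$usable,
                 participant_id = cleaned$participant_id,
                 trial_id = cleaned$trial_id,
                 condition = cleaned$condition),
            class = "pupil_trace")
}

#' Average pupil traces to one participant-level trace per condition
#'
#' @param traces List of `pupil_trace`s from one participant and condition
#'   on a common time base; unusable trials are dropped.
#' @return Numeric vector (mean % of baseline per timepoint) with attribute
#'   `t`, or `NULL` when no usable trial remains.
#' @export
mean_pupil_trace <- function(traces) {
  traces <- Filter(function(tr) tr$usable, traces)
  if (!length(traces)) return(NULL)
  tt <- traces[[1]]$t
  for (tr in traces) if (length(tr$t) != length(tt) || max(abs(tr$t - tt)) > 1e-9)
    stopf("mean_pupil_trace: traces are not on a common time base")
  m <- colMeans(do.call(rbind, lapply(traces, `[[`, "value")), na.rm = TRUE)
  attr(m, "t") <- tt
  m
}

#' Time-resolved comparison of pupil traces between conditions
#'
#' At each timepoint an unequal-variance (Welch) t-test compares
#' participant-mean traces between the two conditions; Benjamini-Hochberg
#' FDR is applied across the timepoints from movement onset to the end of
#' the trace (the pre-movement baseline is not part of the tested family).
#' Contiguous significant timepoints are returned as windows.
#'
#' @param traces_by_condition Named list of two matrices
#'   (participants x timepoints) of participant-mean traces on a common
#'   time base.
#' @param times Timepoints in seconds relative to movement onset (length =
#'   ncol of each matrix).
#' @param q FDR level (default 0.05).
#' @return Object of class `pupil_comparison`: list with `times`, `t`,
#'   `p`, `mask`, `windows` (data.frame `start_s`, `end_s`), `q`,
#'   `conditions`.
#' @export
compare_conditions <- function(traces_by_condition, times, q = 0.05) {
  if (length(traces_by_condition) != 2L)
    stopf("compare_conditions: need exactly two conditions")
  A <- as.matrix(traces_by_condition[[1]])
  B <- as.matrix(traces_by_condition[[2]])
  if (ncol(A) != ncol(B) || ncol(A) != length(times))
    stopf("compare_conditions: unequal time bases")
  if (nrow(A) < 2L || nrow(B) < 2L)
    stopf("compare_conditions: need >= 2 participants per condition")
  ma <- colMeans(A); mb <- colMeans(B)
  va <- apply(A, 2, stats::var); vb <- apply(B, 2, stats::var)
  res <- welch_t_stats(ma, va, nrow(A), mb, vb, nrow(B))
  fam <- times >= 0
  mask <- rep(FALSE, length(times))
  mask[fam] <- bh_fdr(res$p[fam], q)

  windows <- data.frame(start_s = numeric(0), end_s = numeric(0))
  if (any(mask)) {
    r <- rle(mask)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    on <- which(r$values)
    dt <- stats::median(diff(times))
    windows <- data.frame(start_s = times[starts[on]] - dt / 2,
                          end_s = times[ends[on]] + dt / 2)
  }
  structure(list(times = times, t = res$t, p = res$p, mask = mask,
                 windows = windows, q = q,
                 conditions = names(traces_by_condition)),
            class = "pupil_comparison")
}

#' @export
print.pupil_comparison <- function(x, ...) {
  cat(sprintf("<pupil_comparison> %s vs %s, q = %g: %d significant window(s)\n",
              x$conditions[1], x$conditions[2], x$q, nrow(x$windows)))
  if (nrow(x$windows)) print(x$windows, row.names = FALSE)
  invisible(x)
}

#' Write pupil traces as tidy CSV
#'
#' Columns: `participant`, `trial`, `condition`, `t_s`, `pct_baseline`.
#'
#' @param traces List of `pupil_trace`s.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_pupil_csv <- function(traces, path) {
  rows <- lapply(traces, function(tr) {
    data.frame(participant = tr$participant_id, trial = tr$trial_id,
               condition = tr$condition, t_s = tr$t, pct_baseline = tr$value)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}
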