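# EEG preprocessing (band-pass, mastoid re-reference, epoching), Morlet
# event-related spectral perturbation, and suppression indices.

#' Wrap a continuous EEG recording
#'
#' @param data Channels x samples matrix (microvolts).
#' @param sfreq Sampling rate, Hz.
#' @param channel_names Channel labels (extended 10-20 + mastoids).
#' @return Object of class `eeg_continuous`.
#' @export
eeg_continuous <- function(data, sfreq, channel_names) {
  stopifnot(nrow(data) == length(channel_names))
  structure(list(data = data, sfreq = sfreq, channel_names = channel_names),
            class = "eeg_continuous")
}

butter_bandpass <- function(x, band, sfreq, order = 4) {
  bf <- signal::butter(order, band / (sfreq / 2), type = "pass")
  signal::filtfilt(bf, x)  # zero-phase (forward-backward)
}

#' Preprocess EEG: band-pass, mastoid re-reference, epoch
#'
#' Applies a zero-phase 4th-order Butterworth band-pass (default 1-45 Hz)
#' to every channel, re-references to the digital average of the two
#' mastoids, and (for continuous input) segments epochs around
#' movement-onset events. Epochs exceeding the recording bounds are
#' dropped with a warning. An optional artifact hook (e.g., externally
#' supplied ICA component removal or a visual-rejection mask) is applied to
#' the epoched data.
#'
#' @param x An `eeg_epochs` (already segmented, e.g., from the simulator)
#'   or an `eeg_continuous`.
#' @param band `c(low, high)` Hz pass band (default `c(1, 45)`).
#' @param reref `"mastoid_average"` (default) or `"none"`.
#' @param events Movement-onset sample times in seconds (continuous input
#'   only).
#' @param epoch_window `c(start, end)` seconds around each event
#'   (default `c(-1.5, 2.9)`).
#' @param labels Condition label per event (continuous input only).
#' @param artifact_hook Optional `function(eeg_epochs) -> eeg_epochs`.
#' @return An `eeg_epochs`.
#' @export
eeg_preprocess <- function(x, band = c(1, 45), reref = "mastoid_average",
                           events = NULL, epoch_window = c(-1.5, 2.9),
                           labels = NULL, artifact_hook = NULL) {
  if (inherits(x, "eeg_continuous")) {
    if (is.null(events)) stopf("eeg_preprocess: continuous input needs event times")
    dat <- x$data
    for (c in seq_len(nrow(dat))) dat[c, ] <- butter_bandpass(dat[c, ], band, x$sfreq)
    dat <- reref_mastoids(dat, x$channel_names, reref)
    n_samp <- round(diff(epoch_window) * x$sfreq) + 1L
    off0 <- round(epoch_window[1] * x$sfreq)
    keep <- vapply(events, function(ev) {
      s <- round(ev * x$sfreq) + 1L + off0
      s >= 1L && (s + n_samp - 1L) <= ncol(dat)
    }, logical(1))
    if (any(!keep)) warnf("eeg_preprocess: dropped %d epoch(s) exceeding recording bounds",
                          sum(!keep))
    events <- events[keep]
    if (!is.null(labels)) labels <- labels[keep]
    data <- array(0, dim = c(length(events), nrow(dat), n_samp))
    for (e in seq_along(events)) {
      s <- round(events[e] * x$sfreq) + 1L + off0
      data[e, , ] <- dat[, s:(s + n_samp - 1L)]
    }
    ep <- structure(list(data = data, sfreq = x$sfreq,
                         times = epoch_window[1] + (seq_len(n_samp) - 1) / x$sfreq,
                         channel_names = x$channel_names,
                         labels = labels %||% rep(NA_character_, length(events)),
                         meta = list(band = band)),
                    class = "eeg_epochs")
  } else if (inherits(x, "eeg_epochs")) {
    ep <- x
    d <- dim(ep$data)
    for (e in seq_len(d[1])) for (c in seq_len(d[2]))
      ep$data[e, c, ] <- butter_bandpass(ep$data[e, c, ], band, ep$sfreq)
    for (e in seq_len(d[1]))
      ep$data[e, , ] <- reref_mastoids(ep$data[e, , ], ep$channel_names, reref)
    ep$meta$band <- band
  } else stopf("eeg_preprocess: unsupported input")
  if (!is.null(artifact_hook)) ep <- artifact_hook(ep)
  ep
}

reref_mastoids <- function(dat, channel_names, reref) {
  if (identical(reref, "none")) return(dat)
  mi <- match(MASTOIDS, channel_names)
  if (anyNA(mi)) stopf("eeg_preprocess: mastoid channels (%s) missing, cannot re-reference",
                       paste(MASTOIDS, collapse = ", "))
  ref <- colMeans(dat[mi, , drop = FALSE])
  sweep(dat, 2, ref)
}

# complex Morlet wavelet FFTs for a set of frequencies, padded to length L
morlet_ffts <- function(freqs, sfreq, n_cycles, L) {
  lapply(freqs, function(f) {
    sigma_t <- n_cycles / (2 * pi * f)
    half <- ceiling(4 * sigma_t * sfreq)
    tt <- (-half:half) / sfreq
    w <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sigma_t^2))
    w <- w / sqrt(sum(Mod(w)^2))  # unit energy (cancels in the ratio)
    wp <- complex(L)
    wp[1:length(w)] <- w
    list(fft = stats::fft(wp), half = half)
  })
}

#' Morlet event-related spectral perturbation
#'
#' Convolves every epoch and channel with complex Morlet wavelets (fixed
#' `n_cycles` across frequencies), averages power across epochs, and
#' expresses it as `log10(mean power(t, f) / mean baseline power(f))`
#' where the baseline is the pre-onset window. Negative values mark
#' suppression relative to baseline. Time-frequency cells within 3 wavelet
#' standard deviations of an epoch edge are flagged and excluded from
#' baseline means and suppression indices.
#'
#' @param epochs An `eeg_epochs`.
#' @param freqs Analysis frequencies in Hz (must lie below Nyquist).
#' @param n_cycles Morlet cycles (default 7, constant across frequencies).
#' @param baseline `c(start, end)` s of the baseline window
#'   (default `c(-1.5, 0)`).
#' @param decim Keep every `decim`-th sample of the power time course
#'   (default 10).
#' @param channels Channel names to analyze (default: all non-mastoid).
#' @param keep_epochs If `TRUE`, also return per-epoch log-ratios
#'   (epoch x channel x frequency x time), needed by the localizer and the
#'   single-trial classifier.
#' @return Object of class `ersp_map`: list with `values`
#'   (channel x frequency x time log10 ratios), `freqs`, `times`,
#'   `channels`, `edge` (frequency x time logical), `n_epochs`, `labels`,
#'   `params`, and optionally `epochs` (per-epoch log-ratios).
#' @export
compute_ersp <- function(epochs, freqs, n_cycles = 7, baseline = c(-1.5, 0),
                         decim = 10, channels = NULL, keep_epochs = FALSE) {
  if (any(freqs <= 0) || any(freqs >= epochs$sfreq / 2))
    stopf("compute_ersp: frequencies must lie in (0, Nyquist = %g Hz)", epochs$sfreq / 2)
  chans <- channels %||% setdiff(epochs$channel_names, MASTOIDS)
  ci <- match(chans, epochs$channel_names)
  if (anyNA(ci)) stopf("compute_ersp: unknown channel '%s'", chans[which(is.na(ci))[1]])
  d <- dim(epochs$data)
  n_e <- d[1]; n_s <- d[3]
  t_idx <- seq(1L, n_s, by = decim)
  times <- epochs$times[t_idx]

  wl <- morlet_ffts(freqs, epochs$sfreq, n_cycles, L = stats::nextn(n_s + 2 * ceiling(4 * n_cycles / (2 * pi * min(freqs)) * epochs$sfreq), 2))
  L <- length(wl[[1]]$fft)

  # edge mask: within 3 sigma_t of either epoch edge, per frequency
  edge <- matrix(FALSE, length(freqs), length(t_idx))
  for (fi in seq_along(freqs)) {
    guard <- 3 * n_cycles / (2 * pi * freqs[fi])
    edge[fi, ] <- times < epochs$times[1] + guard | times > epochs$times[n_s] - guard
  }

  pow <- array(0, dim = c(n_e, length(ci), length(freqs), length(t_idx)))
  xp <- complex(L)
  for (e in seq_len(n_e)) {
    for (c in seq_along(ci)) {
      xp[] <- 0
      xp[1:n_s] <- epochs$data[e, ci[c], ]
      X <- stats::fft(xp)
      for (fi in seq_along(freqs)) {
        conv <- stats::fft(X * wl[[fi]]$fft, inverse = TRUE) / L
        amp <- conv[wl[[fi]]$half + t_idx]  # center-aligned
        pow[e, c, fi, ] <- Mod(amp)^2
      }
    }
  }

  base_cols <- which(times >= baseline[1] & times <= baseline[2])
  if (!length(base_cols)) stopf("compute_ersp: baseline window contains no samples")
  # mean baseline power per channel x frequency, excluding edge cells
  baseline_pow <- matrix(0, length(ci), length(freqs))
  for (fi in seq_along(freqs)) {
    ok <- base_cols[!edge[fi, base_cols]]
    if (!length(ok)) ok <- base_cols
    baseline_pow[, fi] <- apply(pow[, , fi, ok, drop = FALSE], 2, mean)
  }

  mean_pow <- apply(pow, c(2, 3, 4), mean)
  values <- log10(sweep(mean_pow, c(1, 2), baseline_pow, "/"))

  out <- list(values = values, freqs = freqs, times = times,
              channels = chans, edge = edge, n_epochs = n_e,
              labels = epochs$labels,
              params = list(n_cycles = n_cycles, baseline = baseline,
                            decim = decim))
  if (keep_epochs) {
    # per-epoch log-ratio: log power minus the same epoch's mean log
    # baseline power. Subtracting in log space makes the per-epoch value
    # exactly zero-mean under stationarity (log of a noisy power estimate
    # is biased low; the bias cancels between analysis and baseline cells),
    # which the sign-flip localizer and the single-trial classifier rely on.
    lr <- array(0, dim = dim(pow))
    for (fi in seq_along(freqs)) {
      ok <- base_cols[!edge[fi, base_cols]]
      if (!length(ok)) ok <- base_cols
      lp <- log10(pow[, , fi, , drop = FALSE])
      dim(lp) <- dim(pow)[c(1, 2, 4)]
      base_lp <- apply(lp[, , ok, drop = FALSE], c(1, 2), mean)
      lr[, , fi, ] <- sweep(lp, c(1, 2), base_lp)
    }
    out$epochs <- lr
  }
  structure(out, class = "ersp_map")
}

#' @export
print.ersp_map <- function(x, ...) {
  cat(sprintf("<ersp_map> %d channels x %d freqs (%g-%g Hz) x %d times (%.2f-%.2f s), %d epochs%s\n",
              length(x$channels), length(x$freqs), min(x$freqs), max(x$freqs),
              length(x$times), min(x$times), max(x$times), x$n_epochs,
              if (!is.null(x$epochs)) ", per-epoch log-ratios kept" else ""))
  invisible(x)
}

#' Suppression index: mean ERSP log-ratio over a box
#'
#' Average of the ERSP log-ratio over the selected channels, frequency
#' band, and time window, excluding edge-flagged cells. Negative values
#' indicate suppression relative to baseline (event-related
#' desynchronization).
#'
#' @param ersp An `ersp_map`.
#' @param freq_band `c(low, high)` Hz (inclusive).
#' @param time_window `c(start, end)` s (inclusive).
#' @param channels Channel subset (default: all in the map).
#' @return Mean log10 power ratio (scalar).
#' @export
suppression_index <- function(ersp, freq_band, time_window, channels = NULL) {
  chans <- channels %||% ersp$channels
  ci <- match(chans, ersp$channels)
  if (anyNA(ci)) stopf("suppression_index: unknown channel '%s'", chans[which(is.na(ci))[1]])
  fi <- which(ersp$freqs >= freq_band[1] & ersp$freqs <= freq_band[2])
  ti <- which(ersp$times >= time_window[1] & ersp$times <= time_window[2])
  if (!length(fi) || !length(ti) || !length(ci))
    stopf("suppression_index: empty selection")
  sel <- ersp$values[ci, fi, ti, drop = FALSE]
  keep <- !ersp$edge[fi, ti, drop = FALSE]
  if (!any(keep)) stopf("suppression_index: selection contains only edge cells")
  vals <- apply(sel, 1, function(m) mean(m[keep]))
  mean(vals)
}
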