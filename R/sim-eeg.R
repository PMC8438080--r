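# Synthetic EEG epochs: 1/f background noise plus a mu-band oscillation at
# sensorimotor channels whose post-onset amplitude is scaled to a target
# log10 power ratio.

# extended 10-20 labels of a 32-channel cap; two mastoids appended
CHANNELS_32 <- c("Fp1", "Fp2", "AF3", "AF4", "F7", "F3", "Fz", "F4", "F8",
                 "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
                 "CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8",
                 "PO3", "PO4", "O1", "Oz", "O2")
MASTOIDS <- c("M1", "M2")

# default localizer search set: bilateral sensorimotor (frontocentral,
# central, centroparietal) plus occipital sites present on the 32-ch cap
SENSORIMOTOR_OCCIPITAL <- c("FC5", "FC1", "FC2", "FC6", "C3", "C4",
                            "CP5", "CP1", "CP2", "CP6", "O1", "O2")

# channels carrying the simulated mu oscillation
MU_CHANNELS <- c("FC1", "FC2", "C3", "C4", "CP1", "CP2")

# 1/f-shaped Gaussian noise of length n at rate sfreq, sd `sd`; for mu
# channels the band [notch_lo, notch_hi] is attenuated so the oscillation
# dominates the measured mu power and the injected power ratio is exact.
pink_noise <- function(n, sfreq, sd = 2, notch = NULL) {
  z <- stats::rnorm(n)
  Z <- stats::fft(z)
  f <- seq(0, sfreq, length.out = n + 1)[1:n]
  f <- pmin(f, sfreq - f)  # fold to physical frequency
  shape <- 1 / sqrt(pmax(f, 1))
  if (!is.null(notch)) shape[f >= notch[1] & f <= notch[2]] <- shape[f >= notch[1] & f <= notch[2]] * 0.02
  x <- Re(stats::fft(Z * shape, inverse = TRUE)) / n
  x * (sd / stats::sd(x))
}

# band-limited Gaussian noise (unit SD): the mu rhythm is modeled as
# stochastic band-limited activity, so every frequency cell inside the band
# carries the injected post/pre power ratio
band_noise <- function(n, sfreq, band) {
  z <- stats::rnorm(n)
  Z <- stats::fft(z)
  f <- seq(0, sfreq, length.out = n + 1)[1:n]
  f <- pmin(f, sfreq - f)
  Z[f < band[1] | f > band[2]] <- 0
  x <- Re(stats::fft(Z, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate synthetic EEG epochs
#'
#' Each epoch is 1/f background noise on every channel plus band-limited
#' mu-band activity on the sensorimotor channels (`FC1`, `FC2`, `C3`,
#' `C4`, `CP1`, `CP2`). The mu amplitude steps at time 0 (movement onset)
#' from its baseline value to a value chosen so the expected log10 post/pre
#' power ratio equals the profile's `mu_suppression_logratio`, shifted by
#' `-eeg_condition_effect/2` on inefficient and `+eeg_condition_effect/2`
#' on efficient trials (inefficient = more suppressed). Per-epoch lognormal
#' amplitude jitter (independently on the baseline and post-onset segments)
#' provides realistic single-trial variability without biasing the
#' across-epoch power ratio. The background is band-stopped in the mu band
#' at oscillation channels so the injected ratio holds at every in-band
#' frequency. Two mastoid channels of low-amplitude noise are appended for
#' re-referencing.
#'
#' @param profile A [sim_profile()].
#' @param condition Trial condition label applied to all epochs.
#' @param n_epochs Number of epochs.
#' @param n_channels Number of scalp channels (default 32; labels from the
#'   extended 10-20 scheme).
#' @param sfreq Sampling rate in Hz (default 500).
#' @param epoch_window `c(start, end)` seconds relative to movement onset;
#'   must span negative (baseline) and positive (analysis) time.
#' @param seed Integer seed (bit-reproducible output).
#' @param osc_amp_uv Baseline mu oscillation amplitude, microvolts.
#' @param bg_sd_uv Background noise SD, microvolts.
#' @param amp_jitter_sd SD of the per-epoch lognormal amplitude jitter.
#' @return Object of class `eeg_epochs`: list with `data`
#'   (epoch x channel x sample array, microvolts), `sfreq`, `times`,
#'   `channel_names`, `labels` (condition per epoch), `meta`.
#' @export
gen_eeg_epochs <- function(profile, condition = "efficient", n_epochs = 24,
                           n_channels = 32, sfreq = 500,
                           epoch_window = c(-1.5, 2.9), seed = 1,
                           osc_amp_uv = 8, bg_sd_uv = 2,
                           amp_jitter_sd = 0.15) {
  condition <- match.arg(condition, CONDITIONS)
  if (!(epoch_window[1] < 0 && epoch_window[2] > 0))
    stopf("gen_eeg_epochs: epoch_window must span negative and positive time")
  if (profile$mu_band[2] >= sfreq / 2)
    stopf("gen_eeg_epochs: mu band exceeds the Nyquist frequency (%g Hz)", sfreq / 2)
  chans <- c(CHANNELS_32[seq_len(min(n_channels, length(CHANNELS_32)))], MASTOIDS)
  n_samp <- round(diff(epoch_window) * sfreq) + 1L
  times <- epoch_window[1] + (seq_len(n_samp) - 1) / sfreq
  mu_idx <- which(chans %in% MU_CHANNELS)
  mastoid_idx <- which(chans %in% MASTOIDS)

  sgn <- switch(condition, inefficient = 1, efficient = -1, 0)
  target <- profile$mu_suppression_logratio - sgn * profile$eeg_condition_effect / 2
  notch <- profile$mu_band + c(-1.5, 1.5)

  with_seed(seed, {
    data <- array(0, dim = c(n_epochs, length(chans), n_samp))
    post <- times >= 0
    for (e in seq_len(n_epochs)) {
      for (c in seq_along(chans)) {
        sd_c <- if (c %in% mastoid_idx) 0.5 else bg_sd_uv
        data[e, c, ] <- pink_noise(n_samp, sfreq, sd = sd_c,
                                   notch = if (c %in% mu_idx) notch else NULL)
      }
      for (c in mu_idx) {
        a_pre <- osc_amp_uv * exp(stats::rnorm(1, 0, amp_jitter_sd))
        a_post <- osc_amp_uv * 10^(target / 2) * exp(stats::rnorm(1, 0, amp_jitter_sd))
        amp <- ifelse(post, a_post, a_pre)
        data[e, c, ] <- data[e, c, ] +
          amp * band_noise(n_samp, sfreq, profile$mu_band)
      }
    }
    structure(list(data = data, sfreq = sfreq, times = times,
                   channel_names = chans,
                   labels = rep(condition, n_epochs),
                   meta = list(profile = profile$label,
                               target_logratio = target, seed = seed)),
              class = "eeg_epochs")
  })
}

#' Concatenate EEG epoch sets
#'
#' @param ... `eeg_epochs` objects with identical channels, times, and
#'   sampling rate.
#' @return A combined `eeg_epochs`.
#' @export
bind_epochs <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !inherits(sets[[1]], "eeg_epochs"))
    sets <- sets[[1]]
  ref <- sets[[1]]
  for (s in sets[-1]) {
    if (!identical(s$channel_names, ref$channel_names) ||
        !isTRUE(all.equal(s$times, ref$times)) || s$sfreq != ref$sfreq)
      stopf("bind_epochs: incompatible epoch sets")
  }
  data <- do.call(abind3, lapply(sets, `[[`, "data"))
  structure(list(data = data, sfreq = ref$sfreq, times = ref$times,
                 channel_names = ref$channel_names,
                 labels = unlist(lapply(sets, `[[`, "labels")),
                 meta = ref$meta),
            class = "eeg_epochs")
}

# bind 3-d arrays along the first dimension
abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  out <- array(0, dim = c(sum(vapply(arrs, function(a) dim(a)[1], numeric(1))), d[2], d[3]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d epochs x %d channels x %d samples @ %g Hz, t in [%.2f, %.2f] s\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$sfreq,
              min(x$times), max(x$times)))
  cat("  labels:", paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Write / read EEG epochs as long-format CSV
#'
#' Plain-text round trip for small epoch sets (column per metadata field,
#' one row per epoch x channel x sample). Intended for fixtures and audits,
#' not bulk storage.
#'
#' @param epochs An `eeg_epochs`.
#' @param path File path.
#' @return `read_eeg_csv` returns the `eeg_epochs`; `write_eeg_csv` returns
#'   `path` invisibly.
#' @export
write_eeg_csv <- function(epochs, path) {
  d <- dim(epochs$data)
  df <- data.frame(
    epoch = rep(seq_len(d[1]), times = d[2] * d[3]),
    channel = rep(rep(epochs$channel_names, each = d[1]), times = d[3]),
    t_s = rep(epochs$times, each = d[1] * d[2]),
    label = rep(epochs$labels, times = d[2] * d[3]),
    uv = as.vector(epochs$data))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_eeg_csv
#' @export
read_eeg_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  chans <- unique(df$channel)
  times <- sort(unique(df$t_s))
  n_e <- max(df$epoch)
  data <- array(0, dim = c(n_e, length(chans), length(times)))
  ci <- match(df$channel, chans)
  ti <- match(df$t_s, times)
  data[cbind(df$epoch, ci, ti)] <- df$uv
  labels <- df$label[match(seq_len(n_e), df$epoch)]
  sfreq <- round(1 / stats::median(diff(times)))
  structure(list(data = data, sfreq = sfreq, times = times,
                 channel_names = chans, labels = labels, meta = list()),
            class = "eeg_epochs")
}
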