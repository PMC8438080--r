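# Observer profiles and seeded-stream utilities for the cohort simulator.

#' Observer simulation profile
#'
#' Bundles the parameters that distinguish adult-like (condition-sensitive)
#' from child-like (condition-insensitive) observers. Defaults encode the
#' study conditions: adults carry their mu rhythm at 8-13 Hz with a mean
#' suppression log-ratio of -0.42 and condition-dependent gaze, pupil, and
#' EEG responses; preschool children carry a 6-9 Hz mu rhythm with stronger
#' overall suppression (-0.94) but no condition dependence, and shift gaze
#' to the goal target (peg) early in the action.
#'
#' @param label `"adult_like"` or `"child_like"`.
#' @param gaze_condition_effect Dimensionless >= 0; strength of
#'   condition-dependent looking at the hammer/hand during the reach. The
#'   magnitude is a free parameter of the simulator (not an empirical
#'   quantity); 1 marks a clearly separable observer, 0 an exchangeable one.
#' @param pupil_effect Amplitude of the pupil dilation bump on inefficient
#'   trials, in percent of baseline pupil size.
#' @param mu_band `c(low, high)` Hz of the observer's mu rhythm.
#' @param mu_suppression_logratio Target log10 post/pre power ratio of the
#'   mu oscillation after movement onset (negative = suppression).
#' @param eeg_condition_effect Difference in suppression log-ratio between
#'   inefficient and efficient trials (inefficient is the more suppressed).
#' @param anticipation_latency Seconds after movement onset at which a
#'   child-like observer's gaze jumps to the peg.
#' @return Object of class `sim_profile`.
#' @export
sim_profile <- function(label = c("adult_like", "child_like"),
                        gaze_condition_effect = NULL,
                        pupil_effect = NULL,
                        mu_band = NULL,
                        mu_suppression_logratio = NULL,
                        eeg_condition_effect = NULL,
                        anticipation_latency = NULL) {
  label <- match.arg(label)
  def <- if (label == "adult_like") {
    list(gaze_condition_effect = 1, pupil_effect = 8,
         mu_band = c(8, 13), mu_suppression_logratio = -0.42,
         eeg_condition_effect = 0.4, anticipation_latency = 1.2)
  } else {
    list(gaze_condition_effect = 0, pupil_effect = 0,
         mu_band = c(6, 9), mu_suppression_logratio = -0.94,
         eeg_condition_effect = 0, anticipation_latency = 0.3)
  }
  p <- list(label = label,
            gaze_condition_effect = gaze_condition_effect %||% def$gaze_condition_effect,
            pupil_effect = pupil_effect %||% def$pupil_effect,
            mu_band = mu_band %||% def$mu_band,
            mu_suppression_logratio = mu_suppression_logratio %||% def$mu_suppression_logratio,
            eeg_condition_effect = eeg_condition_effect %||% def$eeg_condition_effect,
            anticipation_latency = anticipation_latency %||% def$anticipation_latency)
  if (!(p$mu_band[1] < p$mu_band[2]) || p$mu_band[1] < 1 || p$mu_band[2] > 45)
    stopf("sim_profile: mu_band must satisfy 1 <= low < high <= 45")
  if (p$gaze_condition_effect < 0)
    stopf("sim_profile: gaze_condition_effect must be >= 0")
  stopifnot(all(vapply(p[-1], function(x) all(is.finite(x)), logical(1))))
  class(p) <- "sim_profile"
  p
}

#' @export
print.sim_profile <- function(x, ...) {
  cat(sprintf("<sim_profile> %s: mu %g-%g Hz (logratio %.2f, cond effect %.2f), gaze effect %.2f, pupil bump %g%%\n",
              x$label, x$mu_band[1], x$mu_band[2], x$mu_suppression_logratio,
              x$eeg_condition_effect, x$gaze_condition_effect, x$pupil_effect))
  invisible(x)
}

#' Cohort configuration for the simulator
#'
#' @param n_participants Number of simulated observers.
#' @param n_trials_per_condition Trials per condition (default 24; the
#'   experiment uses 48 test videos, half efficient, half inefficient, plus
#'   48 localizer videos). Must be >= 2 so leave-one-out keeps at least one
#'   training trial per condition.
#' @param seed Integer; together with the profile fully determines all
#'   generated data.
#' @param profile A [sim_profile()].
#' @param display Display parameters, as a named list of arguments to
#'   [gen_display_spec()] (condition is filled per trial).
#' @return Object of class `sim_cohort_config`.
#' @export
sim_cohort_config <- function(n_participants, n_trials_per_condition = 24,
                              seed = 1, profile = sim_profile("adult_like"),
                              display = list()) {
  if (n_trials_per_condition < 2)
    stopf("sim_cohort_config: need >= 2 trials per condition for leave-one-out")
  structure(list(n_participants = n_participants,
                 n_trials_per_condition = n_trials_per_condition,
                 seed = as.integer(seed), profile = profile,
                 display = display),
            class = "sim_cohort_config")
}

#' Videos watched per participant under a cohort configuration
#'
#' Each participant watches test videos (efficient + inefficient) and an
#' equal number of localizer videos, so the total is
#' `4 * n_trials_per_condition` (96 under the default 24).
#'
#' @param config A [sim_cohort_config()].
#' @return Integer count of videos per participant.
#' @export
videos_per_participant <- function(config) {
  4L * as.integer(config$n_trials_per_condition)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Derive a stage seed from a global seed and a tag
#'
#' Deterministic polynomial hash of the tag folded into the global seed,
#' reduced modulo a Mersenne prime so every stochastic stage of a run gets
#' an independent, reproducible stream.
#'
#' @param seed Integer global seed.
#' @param tag Character stage tag (e.g., `"gaze/p3/trial12"`).
#' @return Integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, tag) {
  m <- 2147483629
  h <- as.numeric(seed) %% m
  for (c in utf8ToInt(as.character(tag))) h <- (h * 31 + c) %% m
  as.integer(h + 1)
}
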