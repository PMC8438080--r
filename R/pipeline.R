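# End-to-end orchestration: simulate a cohort, run every analysis family,
# and summarize per-participant significance. All stage seeds derive
# deterministically from the global seed.

#' Build a pipeline configuration
#'
#' Returns the full configuration for [run_pipeline()] with scale presets:
#' `"desk"` (single-CPU friendly: reduced classifier repetitions, shuffle
#' counts, permutations, map downsampling, and render resolution) or
#' `"full"` (repetition counts of the original analyses: 500 hold-out reps,
#' 1000 shuffles, 1000 permutations, full-resolution maps). Any field can
#' be overridden via `...` (nested lists are merged shallowly per section).
#'
#' @param seed Global seed; every stochastic stage derives its own stream
#'   from it.
#' @param scale `"desk"` or `"full"`.
#' @param ... Section overrides, e.g.,
#'   `groups = list(adult = list(profile = "adult_like", n = 4))`.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, scale = c("desk", "full"), ...) {
  scale <- match.arg(scale)
  desk <- scale == "desk"
  cfg <- list(
    seed = as.integer(seed),
    scale = scale,
    groups = list(adult = list(profile = "adult_like", n = if (desk) 4L else 22L),
                  child = list(profile = "child_like", n = if (desk) 4L else 22L)),
    trials_per_condition = 24L,
    display = list(),
    gaze = list(sampling_hz = 120, min_fix_dur_s = 0.100, dispersion_px = 50),
    probmap = list(radius_px = 75, downsample = if (desk) 8L else 1L),
    lookvid = list(render_width = if (desk) 96L else 192L, radius_px = 75,
                   extractor = "grid_pool",
                   n_reps = if (desk) 200L else 500L,
                   n_shuffles = if (desk) 200L else 1000L,
                   n_reps_per_shuffle = if (desk) 20L else 50L),
    pupil = list(out_hz = 30, baseline_window = c(0, 1.25), max_gap_s = 0.3),
    eeg = list(n_channels = 32L, sfreq = 500, epoch_window = c(-1.5, 2.9),
               band = c(1, 45),
               freqs = if (desk) seq(6, 20, by = 1) else seq(4, 25, by = 1),
               n_cycles = 7,
               decim = if (desk) 20L else 10L,
               channel_set = SENSORIMOTOR_OCCIPITAL,
               search_freqs = c(6, 20),
               n_perm = if (desk) 200L else 1000L,
               n_reps = if (desk) 200L else 500L,
               n_shuffles = if (desk) 200L else 1000L,
               n_reps_per_shuffle = if (desk) 20L else 50L,
               mu_band = list(adult = c(8, 13), child = c(6, 9)),
               index_window = c(0.5, 2.0)),
    alpha = 0.05,
    q_fdr = 0.05,
    modules = c("gaze", "probmap", "lookvid", "pupil", "eeg"))
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]]) && nm != "groups") {
      for (k in names(over[[nm]])) cfg[[nm]][[k]] <- over[[nm]][[k]]
    } else cfg[[nm]] <- over[[nm]]
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; top-level keys override [pipeline_config()]
#'   defaults (a `scale` key selects the preset first).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- c(list(seed = y$seed %||% 1, scale = y$scale %||% "desk"),
            y[setdiff(names(y), c("seed", "scale"))])
  do.call(pipeline_config, args)
}

config_hash <- function(cfg) {
  derive_seed(0, paste(deparse(unclass(cfg)), collapse = ""))
}

# keep only the named channels (mastoids retained for re-referencing)
subset_channels <- function(epochs, channels) {
  keep <- match(unique(c(channels, intersect(MASTOIDS, epochs$channel_names))),
                epochs$channel_names)
  epochs$data <- epochs$data[, keep, , drop = FALSE]
  epochs$channel_names <- epochs$channel_names[keep]
  epochs
}

sim_test_recordings <- function(displays, profile, n_trials, pid, seed, gaze_cfg) {
  recs <- list()
  for (cond in c("efficient", "inefficient")) {
    for (k in seq_len(n_trials)) {
      tid <- length(recs) + 1L
      recs[[tid]] <- gen_gaze_recording(
        displays[[cond]], profile, condition = cond,
        sampling_hz = gaze_cfg$sampling_hz,
        seed = derive_seed(seed, sprintf("gaze/%s/%s/%d", pid, cond, k)),
        participant_id = pid, trial_id = tid)
    }
  }
  recs
}

participant_gaze_analysis <- function(recs, displays, gaze_cfg) {
  measures <- list(); shifts <- list()
  for (r in recs) {
    d <- displays[[r$condition]]
    fx <- detect_fixations(r, d, min_dur_s = gaze_cfg$min_fix_dur_s,
                           dispersion_px = gaze_cfg$dispersion_px)
    lm_ <- looking_measures(r, d, fx)
    lm_$participant <- r$participant_id; lm_$trial <- r$trial_id
    lm_$condition <- r$condition
    measures[[length(measures) + 1L]] <- lm_
    tm <- gaze_shifts(fx)$pairs
    tm$participant <- r$participant_id; tm$trial <- r$trial_id
    tm$condition <- r$condition
    shifts[[length(shifts) + 1L]] <- tm
  }
  list(measures = do.call(rbind, measures), shifts = do.call(rbind, shifts))
}

participant_probmap <- function(recs, displays, pm_cfg, pid) {
  maps <- lapply(recs, function(r)
    participant_map(r, displays[[r$condition]], radius_px = pm_cfg$radius_px,
                    downsample = pm_cfg$downsample))
  group_map(maps, owner = pid)
}

participant_lookvid <- function(recs, frames_by_cond, lv_cfg, seed, pid) {
  trials <- lapply(recs, function(r)
    make_looking_video(frames_by_cond[[r$condition]], r,
                       radius_px = lv_cfg$radius_px))
  classify_participant(trials, n_reps = lv_cfg$n_reps,
                       n_shuffles = lv_cfg$n_shuffles,
                       n_reps_per_shuffle = lv_cfg$n_reps_per_shuffle,
                       seed = derive_seed(seed, paste0("lookvid/", pid)),
                       extractor_id = lv_cfg$extractor)
}

participant_pupil <- function(recs, displays, pupil_cfg) {
  by_cond <- list()
  for (cond in c("efficient", "inefficient")) {
    traces <- lapply(Filter(function(r) r$condition == cond, recs), function(r) {
      cl <- suppressWarnings(preprocess_pupil(r, max_gap_s = pupil_cfg$max_gap_s))
      normalize_trace(cl, displays[[cond]]$events, out_hz = pupil_cfg$out_hz,
                      baseline_window = pupil_cfg$baseline_window)
    })
    by_cond[[cond]] <- mean_pupil_trace(traces)
  }
  by_cond
}

participant_eeg <- function(profile, n_trials, eeg_cfg, seed, pid, events,
                            mu_band, index_window, alpha) {
  gen <- function(cond, tag) gen_eeg_epochs(
    profile, condition = cond, n_epochs = n_trials,
    n_channels = eeg_cfg$n_channels, sfreq = eeg_cfg$sfreq,
    epoch_window = eeg_cfg$epoch_window,
    seed = derive_seed(seed, sprintf("eeg/%s/%s", pid, tag)))
  loc_ep <- bind_epochs(gen("localizer_a", "loca"), gen("localizer_b", "locb"))
  test_ep <- bind_epochs(gen("efficient", "eff"), gen("inefficient", "ineff"))
  loc_ep <- subset_channels(loc_ep, eeg_cfg$channel_set)
  test_ep <- subset_channels(test_ep, eeg_cfg$channel_set)
  loc_ep <- eeg_preprocess(loc_ep, band = eeg_cfg$band)
  test_ep <- eeg_preprocess(test_ep, band = eeg_cfg$band)

  search_times <- c(0, events$hammering - events$movement)
  loc_ersp <- compute_ersp(loc_ep, freqs = eeg_cfg$freqs,
                           n_cycles = eeg_cfg$n_cycles,
                           baseline = c(eeg_cfg$epoch_window[1], 0),
                           decim = eeg_cfg$decim,
                           channels = eeg_cfg$channel_set, keep_epochs = TRUE)
  loc <- run_localizer(loc_ersp, channel_set = eeg_cfg$channel_set,
                       search_freqs = eeg_cfg$search_freqs,
                       search_times = search_times,
                       n_perm = eeg_cfg$n_perm, alpha = alpha,
                       seed = derive_seed(seed, paste0("localizer/", pid)))
  # mu suppression at the sites the localizer marked action-sensitive
  # (falling back to the whole search set when the localizer is empty)
  sup_ch <- unique(vapply(loc$clusters, `[[`, character(1), "channel"))
  if (!length(sup_ch)) sup_ch <- NULL
  suppression <- suppression_index(loc_ersp, mu_band, index_window,
                                   channels = sup_ch)

  res <- tryCatch({
    test_ersp <- compute_ersp(test_ep, freqs = eeg_cfg$freqs,
                              n_cycles = eeg_cfg$n_cycles,
                              baseline = c(eeg_cfg$epoch_window[1], 0),
                              decim = eeg_cfg$decim,
                              channels = eeg_cfg$channel_set,
                              keep_epochs = TRUE)
    feats <- extract_suppression_features(test_ersp, loc)
    classify_eeg(feats, n_reps = eeg_cfg$n_reps,
                 n_shuffles = eeg_cfg$n_shuffles,
                 n_reps_per_shuffle = eeg_cfg$n_reps_per_shuffle,
                 seed = derive_seed(seed, paste0("eegclf/", pid)))
  }, observa_not_classifiable = function(e) NULL)
  list(result = res, localizer = localizer_summary(loc),
       suppression = suppression)
}

#' Run the full simulate-and-analyze pipeline
#'
#' Simulates the configured cohort (display specs, gaze + pupil recordings,
#' EEG epochs per participant) and runs the enabled analysis modules:
#' AOI looking measures and gaze shifts, per-participant and group
#' probability maps (with an adult-vs-child pixel-wise comparison when both
#' groups have >= 2 participants), looking-video classification, pupil
#' condition comparison per group, and the EEG localizer + classifier with
#' mu suppression indices. Every stage seed derives from the global seed,
#' so a rerun with the same configuration reproduces the report exactly.
#'
#' @param config A [pipeline_config()], or path to a YAML file for
#'   [read_pipeline_config()].
#' @param out_dir Optional directory; when given, `report.json` and tidy
#'   CSV tables are written there.
#' @param verbose Print stage progress.
#' @return Report list of class `pipeline_report`: per-participant results
#'   by group, group-level comparisons, a significance summary, the
#'   configuration, and its hash.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         verbose = TRUE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- config
  say <- function(...) if (verbose) message(sprintf(...))
  t_start <- Sys.time()

  displays <- lapply(setNames(CONDITIONS, CONDITIONS), function(cond)
    do.call(gen_display_spec, c(cfg$display, list(condition = cond))))
  frames_by_cond <- if ("lookvid" %in% cfg$modules)
    lapply(displays[c("efficient", "inefficient")],
           render_display_frames, width = cfg$lookvid$render_width)

  report <- list(config = unclass(cfg), config_hash = config_hash(cfg),
                 seed = cfg$seed, groups = list())
  rows_sig <- list()
  maps_by_group <- list()
  pupil_by_group <- list()

  for (g in names(cfg$groups)) {
    grp <- cfg$groups[[g]]
    profile <- sim_profile(grp$profile)
    mu_band <- cfg$eeg$mu_band[[g]] %||% profile$mu_band
    g_out <- list(profile = grp$profile, participants = list())
    maps <- list()
    pupil_eff <- list(); pupil_ineff <- list()
    measures_all <- list(); shifts_all <- list()

    for (i in seq_len(grp$n)) {
      pid <- sprintf("%s%02d", g, i)
      say("[%s] participant %s", g, pid)
      recs <- sim_test_recordings(displays, profile, cfg$trials_per_condition,
                                  pid, cfg$seed, cfg$gaze)
      p_out <- list(id = pid)

      if ("gaze" %in% cfg$modules) {
        ga <- participant_gaze_analysis(recs, displays, cfg$gaze)
        measures_all[[pid]] <- ga$measures
        shifts_all[[pid]] <- ga$shifts
      }
      if ("probmap" %in% cfg$modules)
        maps[[pid]] <- participant_probmap(recs, displays, cfg$probmap, pid)
      if ("lookvid" %in% cfg$modules) {
        lv <- participant_lookvid(recs, frames_by_cond, cfg$lookvid, cfg$seed, pid)
        p_out$lookvid <- list(accuracy = lv$accuracy, p = lv$p_value)
        rows_sig[[length(rows_sig) + 1L]] <-
          data.frame(participant = pid, group = g, modality = "lookvid",
                     p = lv$p_value, accuracy = lv$accuracy)
      }
      if ("pupil" %in% cfg$modules) {
        pt <- participant_pupil(recs, displays, cfg$pupil)
        pupil_eff[[pid]] <- pt$efficient
        pupil_ineff[[pid]] <- pt$inefficient
      }
      if ("eeg" %in% cfg$modules) {
        ee <- participant_eeg(profile, cfg$trials_per_condition, cfg$eeg,
                              cfg$seed, pid, displays$efficient$events,
                              mu_band, cfg$eeg$index_window, cfg$alpha)
        p_out$eeg <- list(localizer = ee$localizer,
                          suppression_index = ee$suppression,
                          classifiable = !is.null(ee$result))
        if (!is.null(ee$result)) {
          p_out$eeg$accuracy <- ee$result$accuracy
          p_out$eeg$p <- ee$result$p_value
          rows_sig[[length(rows_sig) + 1L]] <-
            data.frame(participant = pid, group = g, modality = "eeg",
                       p = ee$result$p_value, accuracy = ee$result$accuracy)
        }
      }
      g_out$participants[[pid]] <- p_out
    }

    if (length(measures_all)) {
      g_out$measures <- do.call(rbind, measures_all)
      g_out$shifts <- do.call(rbind, shifts_all)
    }
    if (length(maps)) {
      maps_by_group[[g]] <- maps
      g_out$group_map_max <- max(group_map(maps, owner = g)$grid)
    }
    if (length(pupil_eff) >= 2 && length(pupil_ineff) >= 2) {
      tt <- attr(pupil_eff[[1]], "t")
      cmp <- compare_conditions(
        list(efficient = do.call(rbind, pupil_eff),
             inefficient = do.call(rbind, pupil_ineff)),
        times = tt, q = cfg$q_fdr)
      g_out$pupil <- cmp
      pupil_by_group[[g]] <- cmp
    }
    report$groups[[g]] <- g_out
  }

  # cross-group factorial ANOVAs on the trial-level looking measures
  # (group x condition x AOI) and gaze shifts (group x pair)
  groups_with_measures <- Filter(function(g) !is.null(report$groups[[g]]$measures),
                                 names(report$groups))
  if (length(groups_with_measures) >= 2) {
    meas <- do.call(rbind, lapply(groups_with_measures, function(g) {
      m <- report$groups[[g]]$measures; m$group <- g; m
    }))
    report$anova_looking <- lapply(
      setNames(c("pct_fixation", "pct_dwell", "revisits"),
               c("pct_fixation", "pct_dwell", "revisits")),
      function(resp) factorial_anova(meas, resp, c("group", "condition", "aoi")))
    sh <- do.call(rbind, lapply(groups_with_measures, function(g) {
      s <- report$groups[[g]]$shifts; s$group <- g; s
    }))
    sh$pair <- paste(sh$a, sh$b, sep = "-")
    report$anova_shifts <- factorial_anova(sh, "count", c("group", "pair"))
  }

  if (length(maps_by_group) >= 2) {
    gs <- names(maps_by_group)[1:2]
    if (length(maps_by_group[[gs[1]]]) >= 2 && length(maps_by_group[[gs[2]]]) >= 2) {
      say("comparing probability maps: %s vs %s", gs[1], gs[2])
      report$map_comparison <- compare_maps(maps_by_group[[gs[1]]],
                                            maps_by_group[[gs[2]]],
                                            q = cfg$q_fdr)
    }
  }

  sig_table <- if (length(rows_sig)) do.call(rbind, rows_sig) else NULL
  report$significance <- if (!is.null(sig_table))
    summarize_significance(sig_table, alpha = cfg$alpha)
  report$classification <- sig_table
  report$elapsed_s <- as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  class(report) <- c("pipeline_report", "list")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Count significant participants per group and modality
#'
#' @param results data.frame with columns `participant`, `group`,
#'   `modality`, `p` (e.g., the `classification` table of a pipeline
#'   report), or a list of `classification_result`s plus `group`/`modality`
#'   vectors.
#' @param alpha Significance level (default 0.05).
#' @return data.frame with `group`, `modality`, `n`, `n_significant`,
#'   `fraction`.
#' @export
summarize_significance <- function(results, alpha = 0.05) {
  if (!is.data.frame(results)) {
    results <- data.frame(
      participant = seq_along(results),
      group = attr(results, "group") %||% "all",
      modality = attr(results, "modality") %||% "classifier",
      p = vapply(results, `[[`, numeric(1), "p_value"))
  }
  if (!nrow(results)) stopf("summarize_significance: no results")
  agg <- aggregate(p ~ group + modality, data = results,
                   FUN = function(p) c(n = length(p), k = sum(p < alpha)))
  data.frame(group = agg$group, modality = agg$modality,
             n = agg$p[, "n"], n_significant = agg$p[, "k"],
             fraction = agg$p[, "k"] / agg$p[, "n"])
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> seed %d, hash %d, %.1f s\n",
              x$seed, x$config_hash, x$elapsed_s))
  if (!is.null(x$significance)) {
    cat("significant participants (p <", x$config$alpha, "):\n")
    print(x$significance, row.names = FALSE)
  }
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  slim <- list(seed = report$seed, config_hash = report$config_hash,
               significance = report$significance,
               classification = report$classification,
               elapsed_s = report$elapsed_s,
               groups = lapply(report$groups, function(g)
                 list(profile = g$profile,
                      participants = g$participants,
                      pupil_windows = if (!is.null(g$pupil)) g$pupil$windows)))
  jsonlite::write_json(slim, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  for (g in names(report$groups)) {
    gr <- report$groups[[g]]
    if (!is.null(gr$measures))
      utils::write.csv(gr$measures, file.path(out_dir, paste0("measures_", g, ".csv")),
                       row.names = FALSE)
    if (!is.null(gr$shifts))
      utils::write.csv(gr$shifts, file.path(out_dir, paste0("shifts_", g, ".csv")),
                       row.names = FALSE)
  }
  invisible(out_dir)
}
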