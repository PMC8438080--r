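test_that("gaze generation is bit-reproducible under a fixed seed", {
  d <- gen_display_spec()
  p <- sim_profile("adult_like")
  r1 <- gen_gaze_recording(d, p, seed = 77)
  r2 <- gen_gaze_recording(d, p, seed = 77)
  expect_identical(r1, r2)
  r3 <- gen_gaze_recording(d, p, seed = 78)
  expect_false(identical(r1$x, r3$x))
})

test_that("zero condition effects make conditions trace-identical at equal seeds", {
  de <- gen_display_spec(condition = "efficient")
  di <- gen_display_spec(condition = "inefficient")
  p0 <- sim_profile("adult_like", gaze_condition_effect = 0, pupil_effect = 0)
  r_eff <- gen_gaze_recording(de, p0, seed = 5)
  r_ineff <- gen_gaze_recording(di, p0, seed = 5)
  expect_identical(r_eff$x, r_ineff$x)
  expect_identical(r_eff$y, r_ineff$y)
  expect_identical(r_eff$pupil, r_ineff$pupil)
})

test_that("adult reach dwell on the hammer differs between conditions (brute force)", {
  p <- sim_profile("adult_like")
  dwell <- function(cond, seed) {
    d <- gen_display_spec(condition = cond)
    r <- gen_gaze_recording(d, p, seed = seed, blink_rate = 0)
    reach <- r$t >= d$events$movement & r$t < d$events$grasp
    # brute-force containment in the hammer rectangle, bypassing assign_aoi
    f <- pmin(pmax(round(r$t[reach] * d$fps) + 1L, 1L), d$n_frames)
    rect <- d$aoi_tracks$hammer[f, , drop = FALSE]
    mean(r$x[reach] >= rect[, 1] & r$x[reach] <= rect[, 3] &
         r$y[reach] >= rect[, 2] & r$y[reach] <= rect[, 4])
  }
  eff <- vapply(1:12, function(s) dwell("efficient", s), numeric(1))
  ineff <- vapply(1:12, function(s) dwell("inefficient", 100 + s), numeric(1))
  expect_gt(mean(ineff) - mean(eff), 0.15)
})

test_that("child-like gaze anticipates the peg regardless of condition", {
  p <- sim_profile("child_like")
  peg_frac <- function(cond, seed) {
    d <- gen_display_spec(condition = cond)
    r <- gen_gaze_recording(d, p, seed = seed, blink_rate = 0)
    late <- r$t >= d$events$movement + p$anticipation_latency + 0.2
    labs <- assign_aoi(r$x[late], r$y[late], r$t[late], d)
    mean(labs == "peg", na.rm = TRUE)
  }
  fr <- vapply(1:8, function(s) peg_frac(c("efficient", "inefficient")[1 + s %% 2], s),
               numeric(1))
  expect_gt(mean(fr), 0.6)
})

test_that("blink injection produces roughly the requested loss in contiguous runs", {
  d <- gen_display_spec()
  p <- sim_profile("adult_like")
  loss <- vapply(1:30, function(s)
    mean(!gen_gaze_recording(d, p, seed = s, blink_rate = 0.05)$valid),
    numeric(1))
  expect_gt(mean(loss), 0.015)
  expect_lt(mean(loss), 0.12)
  r <- gen_gaze_recording(d, p, seed = 4, blink_rate = 0)
  expect_true(all(r$valid))
})

test_that("gaze recordings survive a CSV round trip", {
  d <- gen_display_spec()
  p <- sim_profile("child_like")
  recs <- lapply(1:2, function(k)
    gen_gaze_recording(d, p, seed = k, participant_id = "p7", trial_id = k))
  path <- tempfile(fileext = ".csv")
  write_gaze_csv(recs, path)
  back <- read_gaze_csv(path)
  expect_length(back, 2)
  r1 <- back[[which(vapply(back, `[[`, integer(1), "trial_id") == 1L)]]
  expect_equal(r1$x, recs[[1]]$x, tolerance = 1e-9)
  expect_equal(r1$valid, recs[[1]]$valid)
  expect_equal(r1$condition, recs[[1]]$condition)
})

test_that("EEG generation is seed-reproducible and validates its inputs", {
  p <- sim_profile("adult_like")
  e1 <- gen_eeg_epochs(p, "efficient", n_epochs = 3, seed = 9)
  e2 <- gen_eeg_epochs(p, "efficient", n_epochs = 3, seed = 9)
  expect_identical(e1$data, e2$data)
  expect_equal(dim(e1$data), c(3, 34, 2201))
  expect_true(all(c("C3", "C4", "M1", "M2") %in% e1$channel_names))
  expect_error(gen_eeg_epochs(p, "efficient", sfreq = 20), "Nyquist")
  expect_error(gen_eeg_epochs(p, "efficient", epoch_window = c(0.5, 2)),
               "negative and positive")
})

test_that("a null EEG profile yields near-zero ERSP in the mu band", {
  p0 <- sim_profile("adult_like", mu_suppression_logratio = 0,
                    eeg_condition_effect = 0)
  ep <- gen_eeg_epochs(p0, "efficient", n_epochs = 30, seed = 13)
  er <- compute_ersp(ep, freqs = 8:13, channels = c("C3", "C4"))
  expect_lt(abs(suppression_index(er, c(8, 13), c(0.5, 2))), 0.06)
})

test_that("EEG epoch sets bind and round-trip through CSV", {
  p <- sim_profile("child_like")
  a <- gen_eeg_epochs(p, "efficient", n_epochs = 2, n_channels = 4, seed = 1)
  b <- gen_eeg_epochs(p, "inefficient", n_epochs = 3, n_channels = 4, seed = 2)
  ab <- bind_epochs(a, b)
  expect_equal(dim(ab$data)[1], 5)
  expect_equal(ab$labels, c(rep("efficient", 2), rep("inefficient", 3)))
  path <- tempfile(fileext = ".csv")
  write_eeg_csv(a, path)
  back <- read_eeg_csv(path)
  expect_equal(back$data, a$data, tolerance = 1e-9)
  expect_identical(back$channel_names, a$channel_names)
  expect_equal(back$times, a$times, tolerance = 1e-12)
  expect_identical(back$labels, a$labels)
})

test_that("profiles validate their parameters and carry group defaults", {
  expect_equal(sim_profile("adult_like")$mu_band, c(8, 13))
  expect_equal(sim_profile("child_like")$mu_band, c(6, 9))
  expect_lt(sim_profile("child_like")$mu_suppression_logratio,
            sim_profile("adult_like")$mu_suppression_logratio)
  expect_error(sim_profile("adult_like", mu_band = c(13, 8)), "mu_band")
  expect_error(sim_profile("adult_like", gaze_condition_effect = -1), ">= 0")
  expect_error(sim_cohort_config(4, n_trials_per_condition = 1), "leave-one-out")
})

test_that("stage seeds derive deterministically and stay in integer range", {
  expect_identical(derive_seed(5, "a/b"), derive_seed(5, "a/b"))
  expect_false(derive_seed(5, "a") == derive_seed(5, "b"))
  expect_false(derive_seed(5, "a") == derive_seed(6, "a"))
  s <- vapply(1:100, function(i) derive_seed(i, "stage/tag"), integer(1))
  expect_true(all(s >= 1 & s <= 2147483629))
})
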