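test_that("assign_aoi handles single containment, none, and out-of-range", {
  d <- static_display(list(peg = c(100, 100, 200, 200),
                           hammer = c(250, 100, 350, 200)))
  expect_equal(assign_aoi(150, 150, 0.5, d), "peg")
  expect_equal(assign_aoi(300, 150, 0.5, d), "hammer")
  expect_true(is.na(assign_aoi(50, 50, 0.5, d)))
  expect_equal(assign_aoi(c(150, 300), c(150, 150), c(0.5, 0.5), d),
               c("peg", "hammer"))
  expect_error(assign_aoi(150, 150, 5, d), "outside")
})

test_that("overlap conflicts resolve to the most recent mover", {
  # hand overlaps hammer; depth history says the hand entered last
  d <- static_display(list(hammer = c(100, 100, 200, 200),
                           dominant_hand = c(150, 100, 250, 200)),
                      depth = data.frame(frame = 5L, time = 5 / 30,
                                         mover = "dominant_hand",
                                         other = "hammer",
                                         stringsAsFactors = FALSE))
  expect_equal(assign_aoi(175, 150, 0.5, d), "dominant_hand")
  # in the generated display the hand reaches the hammer and is front-most
  g <- gen_display_spec()
  f <- observa:::frame_at_time(g, g$events$grasp)
  rh <- g$aoi_tracks$hammer[f, ]; rd <- g$aoi_tracks$dominant_hand[f, ]
  px <- (max(rh[1], rd[1]) + min(rh[3], rd[3])) / 2
  py <- (max(rh[2], rd[2]) + min(rh[4], rd[4])) / 2
  expect_equal(assign_aoi(px, py, g$events$grasp, g), "dominant_hand")
})

test_that("I-DT detects a stationary fixation with its full duration", {
  hz <- 120
  t <- (0:59) / hz  # 500 ms
  d <- static_display(list(hammer = c(100, 100, 200, 200)))
  r <- make_recording(t, rep(150, 60), rep(150, 60))
  fx <- detect_fixations(r, d)
  expect_equal(nrow(fx), 1)
  expect_equal(fx$end_s - fx$start_s, 0.5, tolerance = 1e-9)
  expect_equal(fx$aoi, "hammer")
  expect_equal(fx$x, 150, tolerance = 1e-9)
})

test_that("dwells shorter than 100 ms yield no fixation", {
  hz <- 120
  t <- (0:9) / hz  # ~83 ms
  r <- make_recording(t, rep(150, 10), rep(150, 10))
  fx <- detect_fixations(r, static_display(list(hammer = c(100, 100, 200, 200))))
  expect_equal(nrow(fx), 0)
})

test_that("a scripted 3-fixation scanpath yields exactly 3 labeled fixations", {
  hz <- 120
  d <- static_display(list(hammer = c(100, 100, 200, 200),
                           peg = c(250, 100, 350, 200),
                           face = c(100, 250, 200, 350)))
  # 300 ms on each target, instantaneous saccades
  t <- (0:107) / hz
  x <- c(rep(150, 36), rep(300, 36), rep(150, 36))
  y <- c(rep(150, 36), rep(150, 36), rep(300, 36))
  fx <- detect_fixations(make_recording(t, x, y), d)
  expect_equal(nrow(fx), 3)
  expect_equal(fx$aoi, c("hammer", "peg", "face"))
  expect_equal(fx$end_s - fx$start_s, rep(0.3, 3), tolerance = 1e-9)
})

test_that("all-invalid recordings give an empty fixation list, not an error", {
  r <- make_recording((0:20) / 120, rep(NA_real_, 21), rep(NA_real_, 21),
                      valid = rep(FALSE, 21))
  expect_equal(nrow(detect_fixations(r)), 0)
})

test_that("dwell percentages follow sample counts exactly", {
  d <- static_display(list(hammer = c(100, 100, 200, 200),
                           peg = c(250, 100, 350, 200)))
  t <- (0:119) / 120
  r <- make_recording(t, c(rep(150, 60), rep(300, 60)), rep(150, 120))
  fx <- detect_fixations(r, d)
  lm_ <- looking_measures(r, d, fx)
  expect_equal(lm_$pct_dwell[lm_$aoi == "hammer"], 50)
  expect_equal(lm_$pct_dwell[lm_$aoi == "peg"], 50)
  expect_equal(sum(lm_$pct_dwell) + attr(lm_, "pct_off_aoi"), 100)
})

test_that("a trial spent entirely in one AOI dwells 100% with one revisit", {
  d <- static_display(list(hammer = c(100, 100, 200, 200)))
  t <- (0:59) / 120
  r <- make_recording(t, rep(150, 60), rep(150, 60))
  lm_ <- looking_measures(r, d, detect_fixations(r, d))
  expect_equal(lm_$pct_dwell[lm_$aoi == "hammer"], 100)
  expect_equal(sum(lm_$pct_dwell[lm_$aoi != "hammer"]), 0)
  expect_equal(lm_$revisits[lm_$aoi == "hammer"], 1L)
  expect_equal(lm_$pct_fixation[lm_$aoi == "hammer"], 100)
})

test_that("re-entering an AOI counts as a new revisit", {
  d <- static_display(list(peg = c(100, 100, 200, 200)))
  t <- (0:89) / 120
  x <- c(rep(150, 30), rep(400, 30), rep(150, 30))
  r <- make_recording(t, x, rep(150, 90))
  lm_ <- looking_measures(r, d, detect_fixations(r, d))
  expect_equal(lm_$revisits[lm_$aoi == "peg"], 2L)
})

test_that("zero tracked time is an error", {
  r <- make_recording((0:9) / 120, rep(NA_real_, 10), rep(NA_real_, 10),
                      valid = rep(FALSE, 10))
  d <- static_display(list(peg = c(100, 100, 200, 200)))
  expect_error(looking_measures(r, d, detect_fixations(r, d)), "zero tracked")
})

test_that("invalid samples are excluded from dwell numerator and denominator", {
  d <- static_display(list(hammer = c(100, 100, 200, 200)))
  t <- (0:59) / 120
  valid <- rep(c(TRUE, FALSE), 30)
  x <- ifelse(valid, 150, NA)
  r <- make_recording(t, x, x, valid = valid)
  lm_ <- looking_measures(r, d, detect_fixations(r, d))
  expect_equal(lm_$pct_dwell[lm_$aoi == "hammer"], 100)
})

test_that("gaze shifts pool directions and respect the 100 ms gap", {
  fx <- data.frame(start_s = c(0, 0.35, 0.70),
                   end_s = c(0.3, 0.65, 1.0),
                   x = 0, y = 0,
                   aoi = c("dominant_hand", "hammer", "dominant_hand"),
                   stringsAsFactors = FALSE)
  tm <- gaze_shifts(fx)
  expect_equal(tm$pairs$count[tm$pairs$a == "hammer" &
                              tm$pairs$b == "dominant_hand"], 2L)
  expect_equal(sum(tm$pairs$count), 2L)
  expect_true(isSymmetric(tm$matrix))
  # a 150 ms gap breaks the shift
  fx2 <- fx[1:2, ]; fx2$start_s[2] <- 0.45
  expect_equal(sum(gaze_shifts(fx2)$pairs$count), 0L)
  # single fixation: all pairs zero
  expect_equal(sum(gaze_shifts(fx[1, ])$pairs$count), 0L)
})

test_that("pair counts equal a direct scan of the fixation list", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(2:12, 1)
    aois <- sample(c(aoi_names(), NA), n, replace = TRUE)
    starts <- cumsum(runif(n, 0.15, 0.4))
    ends <- starts + runif(n, 0.1, 0.2)
    starts[-1] <- ends[-n] + runif(n - 1, 0, 0.2)  # gaps 0..200 ms
    ends <- starts + runif(n, 0.1, 0.2)
    fx <- data.frame(start_s = starts, end_s = ends, x = 0, y = 0,
                     aoi = aois, stringsAsFactors = FALSE)
    expected <- 0L
    for (k in seq_len(n - 1))
      if (!is.na(aois[k]) && !is.na(aois[k + 1]) && aois[k] != aois[k + 1] &&
          starts[k + 1] - ends[k] <= 0.1)
        expected <- expected + 1L
    expect_equal(sum(gaze_shifts(fx)$pairs$count), expected)
  }
})

test_that("with 5 AOIs there are exactly 10 unordered pairs", {
  pr <- aoi_pairs()
  expect_equal(nrow(pr), 10)
  expect_equal(nrow(unique(pr)), 10)
  expect_true(all(pr$a != pr$b))
})

test_that("measures are invariant to a uniform time shift", {
  d <- static_display(list(hammer = c(100, 100, 200, 200),
                           peg = c(250, 100, 350, 200)), duration_s = 4)
  t <- (0:119) / 120
  x <- c(rep(150, 60), rep(300, 60))
  r1 <- make_recording(t, x, rep(150, 120))
  r2 <- make_recording(t + 1.0, x, rep(150, 120))
  lm1 <- looking_measures(r1, d, detect_fixations(r1, d))
  lm2 <- looking_measures(r2, d, detect_fixations(r2, d))
  expect_equal(lm1$pct_dwell, lm2$pct_dwell)
  expect_equal(lm1$revisits, lm2$revisits)
  expect_equal(lm1$pct_fixation, lm2$pct_fixation, tolerance = 1e-9)
})
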