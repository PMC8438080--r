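test_that("gaze disk masking matches the per-pixel distance oracle", {
  d <- gen_display_spec(resolution = c(192, 120))
  fr <- render_display_frames(d, width = 192)  # scale 1
  set.seed(14)
  for (k in 1:4) {
    gx <- runif(1, 20, 170); gy <- runif(1, 20, 100)
    tt <- runif(1, 0, 5.3)
    r <- make_recording(seq(0, 5.4, by = 1 / 120),
                        rep(gx, 649), rep(gy, 649))
    lv <- make_looking_video(fr, r, radius_px = 40)
    f <- round(tt * 30) + 1
    img <- lv$frames[[f]]
    orig <- fr$frames[[f]]
    for (i in seq(1, 120, by = 7)) for (j in seq(1, 192, by = 11)) {
      inside <- (j - 0.5 - gx)^2 + (i - 0.5 - gy)^2 <= 40^2
      expect_identical(img[i, j], if (inside) orig[i, j] else 0L)
    }
  }
})

test_that("pixels at exactly the mask radius are retained", {
  m <- gaze_disk_mask(100, 100, gx = 50.5, gy = 50.5, radius = 20)
  expect_true(m[51, 71])    # center (70.5, 50.5): distance exactly 20
  expect_false(m[51, 72])
})

test_that("masking is idempotent", {
  d <- gen_display_spec(resolution = c(192, 120))
  fr <- render_display_frames(d, width = 96)
  r <- make_recording(seq(0, 5.4, by = 1 / 120), rep(96, 649), rep(60, 649))
  lv1 <- make_looking_video(fr, r, radius_px = 40)
  fr2 <- fr; fr2$frames <- lv1$frames
  lv2 <- make_looking_video(fr2, r, radius_px = 40)
  expect_identical(lv2$frames, lv1$frames)
})

test_that("all-invalid recordings give an all-black looking video", {
  d <- gen_display_spec(resolution = c(192, 120))
  fr <- render_display_frames(d, width = 96)
  n <- 649
  r <- make_recording(seq(0, 5.4, by = 1 / 120), rep(NA_real_, n),
                      rep(NA_real_, n), valid = rep(FALSE, n))
  lv <- make_looking_video(fr, r)
  expect_true(all(vapply(lv$frames, function(f) all(f == 0L), logical(1))))
  ft <- extract_features(lv)
  expect_true(all(ft == 0))  # black frames pool to zero vectors
})

test_that("coordinates exceeding the display resolution are rejected", {
  d <- gen_display_spec(resolution = c(192, 120))
  fr <- render_display_frames(d, width = 96)
  r <- make_recording(seq(0, 5.4, by = 1 / 120), rep(500, 649), rep(60, 649))
  expect_error(make_looking_video(fr, r), "resolution")
})

test_that("grid pooling recovers a uniform gray level exactly", {
  g <- 0.37
  video <- structure(list(
    frames = list(matrix(1L, 40, 64)),
    palette = cbind(black = c(0, 0, 0), gray = c(g, g, g))),
    class = "looking_video")
  ft <- extract_features(video)
  expect_equal(as.numeric(ft), rep(g, 192), tolerance = 1e-12)
  expect_identical(extract_features(video), extract_features(video))
  expect_error(extract_features(video, "no_such_extractor"), "unknown extractor")
})

test_that("pooled features equal direct pixel averaging on a rendered frame", {
  d <- gen_display_spec(resolution = c(192, 120))
  fr <- render_display_frames(d, width = 64)
  video <- structure(list(frames = fr$frames[1], palette = fr$palette),
                     class = "looking_video")
  ft <- extract_features(video)
  arr <- lv_frame_array(video, 1)
  h <- nrow(fr$frames[[1]]); w <- ncol(fr$frames[[1]])
  ri <- pmin(floor((seq_len(h) - 1) * 8 / h), 7) + 1
  cj <- pmin(floor((seq_len(w) - 1) * 8 / w), 7) + 1
  for (cell in c(1, 23, 64)) {
    i <- which(ri == (cell - 1) %% 8 + 1)
    j <- which(cj == (cell - 1) %/% 8 + 1)
    expect_equal(ft[1, cell], mean(arr[i, j, 1]), tolerance = 1e-12)
    expect_equal(ft[1, 64 + cell], mean(arr[i, j, 2]), tolerance = 1e-12)
  }
})

test_that("a constant feature offset between conditions classifies perfectly", {
  set.seed(3)
  X <- matrix(rnorm(20 * 6, sd = 0.01), 20, 6)
  X[11:20, 1] <- X[11:20, 1] + 5
  labels <- rep(c("efficient", "inefficient"), each = 10)
  res <- shuffle_null(X, labels, n_shuffles = 99, n_reps_per_shuffle = 10,
                      n_reps = 50, seed = 2)
  expect_equal(res$accuracy, 100)
  expect_equal(res$p_value, 1 / 100)
  expect_equal(res$meta$train_size, 18)
})

test_that("label-independent features stay inside the central null range", {
  set.seed(4)
  X <- matrix(rnorm(24 * 10), 24, 10)
  labels <- rep(c("efficient", "inefficient"), each = 12)
  res <- shuffle_null(X, labels, n_shuffles = 200, n_reps_per_shuffle = 20,
                      n_reps = 100, seed = 6)
  qs <- quantile(res$null_distribution, c(0.025, 0.975))
  expect_gte(res$accuracy, qs[1])
  expect_lte(res$accuracy, qs[2])
  expect_gt(res$p_value, 0.05)
})

test_that("classification is stable under trial reordering", {
  set.seed(5)
  X <- matrix(rnorm(24 * 8, sd = 0.4), 24, 8)
  X[13:24, ] <- X[13:24, ] + 1.2
  labels <- rep(c("a", "b"), each = 12)
  a1 <- classify_trials(X, labels, n_reps = 300, seed = 9)
  o <- sample(24)
  a2 <- classify_trials(X[o, ], labels[o], n_reps = 300, seed = 10)
  expect_lt(abs(as.numeric(a1) - as.numeric(a2)), 8)  # Monte-Carlo error only
})

test_that("classifier input contracts are enforced", {
  X <- matrix(rnorm(8), 4, 2)
  expect_error(classify_trials(X, c("a", "a", "a", "b")), ">= 2 trials")
  expect_error(classify_trials(X, rep("a", 4)), "2 condition labels")
  expect_error(shuffle_null(X, rep(c("a", "b"), 2), n_shuffles = 0), ">= 1")
})

test_that("the dual LS-SVM solution matches an independent primal solve", {
  # primal route: minimize ||w||^2/2 + C/2 * sum((y - Xw - b)^2), whose
  # normal equations are solved directly here -- independent of the
  # package's dual (Gram/KKT) formulation
  set.seed(12)
  for (rep in 1:5) {
    n <- sample(10:30, 1); d <- sample(2:6, 1); C <- sample(c(0.5, 1, 2), 1)
    X <- matrix(rnorm(n * d), n, d)
    y <- sample(c(-1, 1), n, replace = TRUE)
    A <- rbind(cbind(crossprod(X) + diag(d) / C, colSums(X)),
               c(colSums(X), n))
    sol <- solve(A, c(crossprod(X, y), sum(y)))
    w <- sol[1:d]; b <- sol[d + 1]
    Xtest <- matrix(rnorm(4 * d), 4, d)
    primal_dec <- as.numeric(Xtest %*% w + b)
    fit <- observa:::lssvm_fit(tcrossprod(X), y, C = C)
    dual_dec <- observa:::lssvm_decision(fit, Xtest %*% t(X))
    expect_equal(dual_dec, primal_dec, tolerance = 1e-8)
  }
})
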