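test_that("connected-component clustering matches the igraph oracle", {
  set.seed(17)
  for (i in 1:25) {
    tm <- matrix(rnorm(15 * 20, sd = 2), 15, 20)
    got <- canon_clusters(observa:::negative_clusters(tm, 2))
    want <- canon_clusters(cluster_oracle(tm, 2))
    expect_identical(got, want)
  }
})

test_that("the localizer recovers injected suppression on the mu channels", {
  p <- sim_profile("adult_like")
  cs <- c("FC1", "C3", "C4", "O1", "O2")
  loc <- bind_epochs(gen_eeg_epochs(p, "localizer_a", 24, seed = 1),
                     gen_eeg_epochs(p, "localizer_b", 24, seed = 2))
  er <- compute_ersp(loc, freqs = 6:20, channels = cs, keep_epochs = TRUE)
  res <- run_localizer(er, channel_set = cs, n_perm = 200, seed = 3)
  hit <- vapply(res$clusters, `[[`, character(1), "channel")
  expect_true(all(c("FC1", "C3", "C4") %in% hit))
  expect_false(any(c("O1", "O2") %in% hit))  # no rhythm injected there
  for (cl in res$clusters) {
    expect_lt(cl$mass, 0)
    expect_lt(cl$p, res$alpha)
    # injected band 8-13 Hz overlaps every recovered cluster
    expect_true(cl$freq_range[1] <= 13 && cl$freq_range[2] >= 8)
  }
  # observed clusters equal brute-force thresholding + components on the
  # t-maps recomputed here from the per-epoch log-ratios
  fi <- match(res$freqs, er$freqs); ti <- match(res$times, er$times)
  n_e <- dim(er$epochs)[1]
  tcrit <- qt(1 - res$alpha / 2, n_e - 1)
  for (ch in c("C3", "O1")) {
    ci <- match(ch, er$channels)
    E <- er$epochs[, ci, fi, ti]
    tm <- apply(E, c(2, 3), function(v) mean(v) / (sd(v) / sqrt(n_e)))
    tm[er$edge[fi, ti]] <- 0
    oracle <- canon_clusters(cluster_oracle(tm, tcrit))
    got <- canon_clusters(lapply(Filter(function(cl) cl$channel == ch,
                                        res$clusters), `[[`, "cells"))
    # every significant cluster must be one of the oracle's components
    for (g in got) expect_true(any(vapply(oracle, identical, logical(1), g)))
  }
})

test_that("localizer input contracts are enforced", {
  p <- sim_profile("adult_like")
  ep <- gen_eeg_epochs(p, "localizer_a", 4, seed = 1)
  er <- compute_ersp(ep, freqs = 8:12, channels = c("C3"), keep_epochs = TRUE)
  expect_error(run_localizer(er, channel_set = character(0)), "empty channel")
  expect_error(run_localizer(er, channel_set = "Pz"), "not in the ERSP map")
  er2 <- compute_ersp(ep, freqs = 8:12, channels = c("C3"))
  expect_error(run_localizer(er2, channel_set = "C3"), "keep_epochs")
})

test_that("white-noise data rarely produce significant clusters", {
  p0 <- sim_profile("adult_like", mu_suppression_logratio = 0,
                    eeg_condition_effect = 0)
  any_cluster <- vapply(1:10, function(s) {
    # F3/F4 carry no rhythm at all: pure 1/f background
    ep <- gen_eeg_epochs(p0, "localizer_a", 20, n_channels = 8, seed = 100 + s)
    er <- compute_ersp(ep, freqs = seq(6, 20, by = 2), channels = c("F3", "F4"),
                       keep_epochs = TRUE, decim = 20)
    res <- run_localizer(er, channel_set = c("F3", "F4"), n_perm = 100,
                         seed = s)
    length(res$clusters) > 0
  }, logical(1))
  expect_lte(sum(any_cluster), 3)  # ~alpha of simulations, loose binomial bound
})

fake_ersp_epochs <- function(lr, freqs, times, channels, labels) {
  structure(list(values = apply(lr, c(2, 3, 4), mean), freqs = freqs,
                 times = times, channels = channels,
                 edge = matrix(FALSE, length(freqs), length(times)),
                 n_epochs = dim(lr)[1], labels = labels,
                 params = list(), epochs = lr),
            class = "ersp_map")
}

fake_localizer <- function(clusters, freqs, times) {
  structure(list(clusters = clusters, freqs = freqs, times = times,
                 channels_searched = unique(vapply(clusters, `[[`,
                                                   character(1), "channel")),
                 n_perm = 0, alpha = 0.05),
            class = "localizer_result")
}

test_that("suppression features are window means in localizer order", {
  freqs <- 8:10; times <- c(0.5, 1.0)
  lr <- array(0, dim = c(4, 2, 3, 2))
  lr[, 1, , ] <- -0.4                  # constant on channel C3
  lr[, 2, 1, 1] <- c(1, 2, 3, 4)       # one cell on C4
  er <- fake_ersp_epochs(lr, freqs, times, c("C3", "C4"),
                         rep(c("efficient", "inefficient"), 2))
  loc <- fake_localizer(list(
    list(channel = "C3", cells = 1:6, freq_range = c(8, 10),
         time_range = c(0.5, 1), mass = -10, p = 0.01),
    list(channel = "C4", cells = 1L, freq_range = c(8, 8),
         time_range = c(0.5, 0.5), mass = -5, p = 0.02)), freqs, times)
  X <- extract_suppression_features(er, loc)
  expect_equal(dim(X), c(4, 2))
  expect_equal(X[, 1], rep(-0.4, 4))
  expect_equal(X[, 2], c(1, 2, 3, 4))
  expect_identical(attr(X, "labels"), er$labels)
})

test_that("an empty localizer marks the participant not classifiable", {
  er <- fake_ersp_epochs(array(0, dim = c(2, 1, 2, 2)), 8:9, c(0.5, 1),
                         "C3", c("a", "b"))
  loc <- structure(list(clusters = list(), freqs = 8:9, times = c(0.5, 1)),
                   class = "localizer_result")
  expect_error(extract_suppression_features(er, loc),
               class = "observa_not_classifiable")
  expect_equal(localizer_summary(loc)$n_channels, 0)
})

test_that("condition-dependent suppression appears in features at the injected size", {
  p <- sim_profile("adult_like")  # eeg_condition_effect 0.4
  cs <- c("C3", "C4")
  loc_ep <- bind_epochs(gen_eeg_epochs(p, "localizer_a", 20, seed = 31),
                        gen_eeg_epochs(p, "localizer_b", 20, seed = 32))
  tst_ep <- bind_epochs(gen_eeg_epochs(p, "efficient", 20, seed = 33),
                        gen_eeg_epochs(p, "inefficient", 20, seed = 34))
  ler <- compute_ersp(loc_ep, freqs = 6:16, channels = cs, keep_epochs = TRUE)
  loc <- run_localizer(ler, channel_set = cs, n_perm = 200, seed = 35)
  ter <- compute_ersp(tst_ep, freqs = 6:16, channels = cs, keep_epochs = TRUE)
  X <- extract_suppression_features(ter, loc)
  lab <- attr(X, "labels")
  gap <- colMeans(X[lab == "efficient", , drop = FALSE]) -
         colMeans(X[lab == "inefficient", , drop = FALSE])
  expect_equal(mean(gap), p$eeg_condition_effect, tolerance = 0.15)
})

test_that("localizer JSON summary mirrors the cluster table", {
  loc <- fake_localizer(list(
    list(channel = "C3", cells = 1L, freq_range = c(8, 12),
         time_range = c(0, 1), mass = -4, p = 0.01),
    list(channel = "C3", cells = 2L, freq_range = c(14, 16),
         time_range = c(0, 1), mass = -3, p = 0.02),
    list(channel = "C4", cells = 1L, freq_range = c(9, 11),
         time_range = c(0, 1), mass = -5, p = 0.01)), 8:16, c(0, 0.5, 1))
  s <- localizer_summary(loc)
  expect_equal(s$n_channels, 2)
  expect_equal(s$clusters_per_channel, 1.5)
  expect_equal(s$freq_range, c(8, 16))
  path <- tempfile(fileext = ".json")
  write_localizer_json(loc, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$summary$n_channels, 2)
  expect_equal(nrow(back$clusters), 3)
})
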