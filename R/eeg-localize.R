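# Individualized cluster-based permutation localizer on localizer-video
# epochs, and LS-SVM classification of test-video trials using the
# localizer-selected suppression windows.

# connected components (4-connectivity) among supra-threshold cells of a
# t-map; returns a list of integer cell-index vectors (column-major)
negative_clusters <- function(tmap, thresh) {
  supra <- which(tmap < -thresh)
  if (!length(supra)) return(list())
  nr <- nrow(tmap); nc <- ncol(tmap)
  r <- (supra - 1L) %% nr + 1L
  cc <- (supra - 1L) %/% nr + 1L
  parent <- seq_along(supra)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }
  right <- match(supra + nr, supra)  # (r, c+1)
  down <- match(supra + 1L, supra)   # (r+1, c)
  down[r == nr] <- NA_integer_       # no wrap across rows
  right[cc == nc] <- NA_integer_
  for (i in seq_along(supra)) {
    if (!is.na(right[i])) unite(i, right[i])
    if (!is.na(down[i])) unite(i, down[i])
  }
  roots <- vapply(seq_along(supra), find, integer(1))
  unname(split(supra, roots))
}

# t-maps per channel from a flipped-sign mean; sum of squares is invariant
# under sign flips, so only the mean needs recomputing per permutation
tmap_from_moments <- function(m, ss, n) {
  v <- pmax((ss - n * m^2) / (n - 1), 0)
  se <- sqrt(v / n)
  t <- m / se
  t[se == 0] <- 0
  t
}

#' Individualized cluster-based suppression localizer
#'
#' One-sample t-statistics against zero of per-epoch ERSP log-ratios at
#' every (frequency, time) cell of every channel in the search set;
#' negative (suppression) cells exceeding the two-sided alpha-level t
#' threshold are grouped by 4-connectivity within each channel's grid, and
#' each cluster is scored by its mass (sum of t). The null distribution is
#' built by sign-flipping epoch log-ratios (`n_perm` permutations) and
#' recording the most negative cluster mass across all channels per
#' permutation; observed clusters with permutation
#' `p = (1 + #\{null <= mass\}) / (1 + n_perm) < alpha` are retained.
#' Edge-flagged cells never enter a cluster.
#'
#' @param ersp An `ersp_map` computed with `keep_epochs = TRUE` from the
#'   localizer-video epochs.
#' @param channel_set Channels to search (default: bilateral sensorimotor +
#'   occipital sites of the 32-channel cap). Must be non-empty and present
#'   in the map.
#' @param search_freqs `c(low, high)` Hz search band (default 6-20).
#' @param search_times `c(start, end)` s search window, typically movement
#'   onset to hammering time.
#' @param n_perm Sign-flip permutations (default 1000).
#' @param alpha Cluster-forming and cluster-level significance level
#'   (default 0.05).
#' @param seed Integer seed for the permutations.
#' @return Object of class `localizer_result`: list with `clusters` (each
#'   with `channel`, `cells` (cell indices into the search grid),
#'   `freq_range`, `time_range`, `mass`, `p`), `channels_searched`,
#'   `freqs`, `times` (the search grid), `n_perm`, `alpha`,
#'   `null_min_mass`.
#' @export
run_localizer <- function(ersp, channel_set = SENSORIMOTOR_OCCIPITAL,
                          search_freqs = c(6, 20), search_times = c(0, 1.5),
                          n_perm = 1000, alpha = 0.05, seed = 1) {
  if (is.null(ersp$epochs))
    stopf("run_localizer: compute_ersp must be run with keep_epochs = TRUE")
  if (!length(channel_set)) stopf("run_localizer: empty channel set")
  ci <- match(channel_set, ersp$channels)
  if (anyNA(ci)) stopf("run_localizer: channel '%s' not in the ERSP map",
                       channel_set[which(is.na(ci))[1]])
  n_e <- dim(ersp$epochs)[1]
  if (n_e < 2L) stopf("run_localizer: need >= 2 epochs")
  fi <- which(ersp$freqs >= search_freqs[1] & ersp$freqs <= search_freqs[2])
  ti <- which(ersp$times >= search_times[1] & ersp$times <= search_times[2])
  if (!length(fi) || !length(ti)) stopf("run_localizer: empty search box")
  nf <- length(fi); nt <- length(ti); nch <- length(ci)

  # epochs x (channel, freq, time) matrix over the search box
  E <- matrix(0, n_e, nch * nf * nt)
  for (k in seq_along(ci))
    E[, (k - 1) * nf * nt + seq_len(nf * nt)] <-
      matrix(ersp$epochs[, ci[k], fi, ti], n_e, nf * nt)
  edge_cells <- as.vector(ersp$edge[fi, ti])  # same for every channel

  ss <- colSums(E^2)
  tcrit <- stats::qt(1 - alpha / 2, n_e - 1)

  channel_tmaps <- function(m) {
    t_all <- tmap_from_moments(m, ss, n_e)
    lapply(seq_len(nch), function(k) {
      tm <- matrix(t_all[(k - 1) * nf * nt + seq_len(nf * nt)], nf, nt)
      tm[matrix(edge_cells, nf, nt)] <- 0
      tm
    })
  }

  obs_maps <- channel_tmaps(colMeans(E))
  obs <- list()
  for (k in seq_len(nch)) {
    for (cl in negative_clusters(obs_maps[[k]], tcrit)) {
      obs[[length(obs) + 1L]] <- list(channel = channel_set[k], cells = cl,
                                      mass = sum(obs_maps[[k]][cl]))
    }
  }

  null_min <- with_seed(seed, {
    out <- numeric(n_perm)
    block <- 100L
    done <- 0L
    while (done < n_perm) {
      nb <- min(block, n_perm - done)
      S <- matrix(sample(c(-1, 1), nb * n_e, replace = TRUE), nb, n_e)
      M <- (S %*% E) / n_e
      for (b in seq_len(nb)) {
        maps <- channel_tmaps(M[b, ])
        masses <- unlist(lapply(maps, function(tm) {
          vapply(negative_clusters(tm, tcrit),
                 function(cl) sum(tm[cl]), numeric(1))
        }))
        out[done + b] <- if (length(masses)) min(masses) else 0
      }
      done <- done + nb
    }
    out
  })

  clusters <- list()
  for (cl in obs) {
    p <- (1 + sum(null_min <= cl$mass)) / (1 + n_perm)
    if (p < alpha) {
      rr <- (cl$cells - 1L) %% nf + 1L
      cc <- (cl$cells - 1L) %/% nf + 1L
      clusters[[length(clusters) + 1L]] <-
        list(channel = cl$channel, cells = cl$cells,
             freq_range = range(ersp$freqs[fi][rr]),
             time_range = range(ersp$times[ti][cc]),
             mass = cl$mass, p = p)
    }
  }
  structure(list(clusters = clusters, channels_searched = channel_set,
                 freqs = ersp$freqs[fi], times = ersp$times[ti],
                 search_freqs = search_freqs, search_times = search_times,
                 n_perm = n_perm, alpha = alpha, null_min_mass = null_min),
            class = "localizer_result")
}

#' @export
print.localizer_result <- function(x, ...) {
  s <- localizer_summary(x)
  cat(sprintf("<localizer_result> %d significant cluster(s) on %d channel(s)",
              length(x$clusters), s$n_channels))
  if (length(x$clusters))
    cat(sprintf("; freq range %.2f-%.2f Hz", s$freq_range[1], s$freq_range[2]))
  cat("\n")
  invisible(x)
}

#' Summarize a localizer result
#'
#' Per-participant summary in the shape of the localizer results table:
#' number of channels with at least one significant cluster, average number
#' of clusters per such channel, and the minimal/maximal frequencies across
#' all clusters.
#'
#' @param result A `localizer_result`.
#' @return List with `n_channels`, `clusters_per_channel`, `freq_range`
#'   (NULL when empty).
#' @export
localizer_summary <- function(result) {
  if (!length(result$clusters))
    return(list(n_channels = 0L, clusters_per_channel = 0, freq_range = NULL))
  ch <- vapply(result$clusters, `[[`, character(1), "channel")
  fr <- range(unlist(lapply(result$clusters, `[[`, "freq_range")))
  list(n_channels = length(unique(ch)),
       clusters_per_channel = length(ch) / length(unique(ch)),
       freq_range = fr)
}

#' Write a localizer result as JSON
#'
#' @param result A `localizer_result`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_localizer_json <- function(result, path) {
  s <- localizer_summary(result)
  obj <- list(summary = s,
              clusters = lapply(result$clusters, function(cl)
                cl[c("channel", "freq_range", "time_range", "mass", "p")]),
              search = list(freqs = result$search_freqs,
                            times = result$search_times,
                            channels = result$channels_searched,
                            n_perm = result$n_perm, alpha = result$alpha))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Extract per-trial suppression features from localizer windows
#'
#' For every test epoch and every localizer cluster, the mean single-trial
#' ERSP log-ratio over the cluster's (channel, frequency, time) cells. The
#' test ERSP must share the localizer's grid. Localizer and test epochs are
#' disjoint by construction (localizer videos vs test videos); passing the
#' same object for both is refused.
#'
#' @param test_ersp An `ersp_map` with `keep_epochs = TRUE` computed from
#'   the test-video epochs.
#' @param localizer A `localizer_result`. Empty localizers mark the
#'   participant not-classifiable (error with class
#'   `observa_not_classifiable`).
#' @return Numeric matrix (trials x clusters) with attribute `labels` (the
#'   test epochs' condition labels).
#' @export
extract_suppression_features <- function(test_ersp, localizer) {
  if (!length(localizer$clusters))
    stop(structure(class = c("observa_not_classifiable", "error", "condition"),
                   list(message = "empty localizer: participant not classifiable",
                        call = sys.call(-1))))
  if (is.null(test_ersp$epochs))
    stopf("extract_suppression_features: test ERSP must keep per-epoch log-ratios")
  fi <- match(localizer$freqs, test_ersp$freqs)
  ti <- match(localizer$times, test_ersp$times)
  if (anyNA(fi) || anyNA(ti))
    stopf("extract_suppression_features: test ERSP grid does not match the localizer grid")
  n_e <- dim(test_ersp$epochs)[1]
  nf <- length(fi)
  X <- matrix(0, n_e, length(localizer$clusters))
  for (k in seq_along(localizer$clusters)) {
    cl <- localizer$clusters[[k]]
    ci <- match(cl$channel, test_ersp$channels)
    if (is.na(ci)) stopf("extract_suppression_features: channel %s missing", cl$channel)
    sub <- test_ersp$epochs[, ci, fi, ti, drop = FALSE]
    M <- matrix(sub, n_e, nf * length(ti))  # columns in (freq, time) column-major order
    X[, k] <- rowMeans(M[, cl$cells, drop = FALSE])
  }
  attr(X, "labels") <- test_ersp$labels
  X
}

#' Classify test trials from localizer-selected suppression features
#'
#' Linear least-squares SVM (C = 1) with the shared repeated leave-one-out
#' scheme and label-shuffle null (see [classify_trials()] and
#' [shuffle_null()]).
#'
#' @param features Trials x windows feature matrix from
#'   [extract_suppression_features()] (labels read from its attribute
#'   unless given).
#' @param labels Condition label per trial.
#' @param n_reps,n_shuffles,n_reps_per_shuffle,seed,C See [shuffle_null()].
#' @return A `classification_result`.
#' @export
classify_eeg <- function(features, labels = attr(features, "labels"),
                         n_reps = 500, n_shuffles = 1000,
                         n_reps_per_shuffle = 50, seed = 1, C = 1) {
  shuffle_null(features, labels, n_shuffles = n_shuffles,
               n_reps_per_shuffle = n_reps_per_shuffle,
               n_reps = n_reps, seed = seed, C = C)
}
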