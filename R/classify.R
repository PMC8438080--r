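# Shared per-participant classification machinery: linear least-squares SVM
# (C = 1), repeated leave-one-out-per-condition evaluation, and the
# label-shuffle null. Used by both the looking-video and the EEG pipelines.

# Train a linear LS-SVM in the dual on a precomputed Gram matrix: the KKT
# system [0 1'; 1 K + I/C] [b; alpha] = [0; y], y in {-1, +1}, solved via
# the Cholesky factor of the (positive definite) regularized Gram block:
# b = (1' M^-1 y) / (1' M^-1 1), alpha = M^-1 (y - b), M = K + I/C.
lssvm_fit <- function(K, y, C = 1) {
  n <- length(y)
  R <- chol(K + diag(n) / C)
  Mi_y <- backsolve(R, backsolve(R, y, transpose = TRUE))
  Mi_1 <- backsolve(R, backsolve(R, rep(1, n), transpose = TRUE))
  b <- sum(Mi_y) / sum(Mi_1)
  list(b = b, alpha = Mi_y - b * Mi_1)
}

lssvm_decision <- function(fit, K_test_train) {
  as.numeric(K_test_train %*% fit$alpha + fit$b)
}

# z-score feature columns (zero-variance columns left centered); applied
# once per participant before the Gram matrix is formed
standardize_features <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  s[s == 0 | !is.finite(s)] <- 1
  sweep(sweep(X, 2, mu), 2, s, "/")
}

# Core repeated hold-out evaluation. Per repetition one random trial per
# condition is held out, the LS-SVM is trained on the rest, and the two
# held-out trials are scored; accuracy is the mean percent correct.
# RNG must be seeded by the caller.
loo_accuracy <- function(K, y, idx_pos, idx_neg, n_reps, C = 1) {
  n <- length(y)
  correct <- 0L
  for (r in seq_len(n_reps)) {
    test <- c(idx_pos[sample.int(length(idx_pos), 1)],
              idx_neg[sample.int(length(idx_neg), 1)])
    train <- setdiff(seq_len(n), test)
    fit <- lssvm_fit(K[train, train, drop = FALSE], y[train], C)
    dec <- lssvm_decision(fit, K[test, train, drop = FALSE])
    pred <- ifelse(dec >= 0, 1, -1)
    correct <- correct + sum(pred == y[test])
  }
  100 * correct / (2 * n_reps)
}

#' Classify trials with a linear least-squares SVM
#'
#' Repeated leave-one-out-per-condition classification: on each repetition
#' one random trial of each condition is held out, a linear SVM with
#' least-squares cost (regularization constant `C`, default 1) is trained
#' on the remaining trials, and the two held-out trials are scored.
#' Accuracy is the mean percent correct across repetitions. Features are
#' z-scored across trials before the Gram matrix is formed.
#'
#' @param features Numeric matrix, trials x feature dimensions.
#' @param labels Factor or character vector of two condition labels, one
#'   per trial (>= 2 trials per condition).
#' @param n_reps Number of hold-out repetitions (default 500).
#' @param seed Integer seed.
#' @param C LS-SVM regularization constant (default 1).
#' @return Numeric accuracy in percent, with attribute `train_size` (the
#'   number of training trials per repetition).
#' @export
classify_trials <- function(features, labels, n_reps = 500, seed = 1, C = 1) {
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2L) stopf("classify_trials: need exactly 2 condition labels")
  if (min(table(labels)) < 2L) stopf("classify_trials: need >= 2 trials per condition")
  if (nrow(features) != length(labels)) stopf("classify_trials: features/labels mismatch")
  y <- ifelse(labels == lev[2], 1, -1)
  X <- standardize_features(as.matrix(features))
  K <- tcrossprod(X)
  acc <- with_seed(seed, loo_accuracy(K, y, which(y == 1), which(y == -1), n_reps, C))
  attr(acc, "train_size") <- length(y) - 2L
  acc
}

#' Label-shuffle null distribution and permutation p-value
#'
#' Repeats the full classification procedure of [classify_trials()] with
#' condition labels randomly permuted, `n_shuffles` times. The p-value uses
#' the finite-sample permutation correction
#' `p = (1 + #\{null >= observed\}) / (1 + n_shuffles)`.
#'
#' @inheritParams classify_trials
#' @param n_shuffles Number of label shuffles (>= 1; default 1000).
#' @param n_reps_per_shuffle Hold-out repetitions per shuffle (default 50;
#'   may be smaller than `n_reps` for the observed statistic, recorded in
#'   the result metadata).
#' @param observed Observed accuracy; computed with `n_reps` repetitions if
#'   not supplied.
#' @return Object of class `classification_result`: `accuracy` (%),
#'   `n_reps`, `null_distribution`, `n_shuffles`, `p_value`, `seed`,
#'   `meta` (train size, reps per shuffle, C).
#' @export
shuffle_null <- function(features, labels, n_shuffles = 1000,
                         n_reps_per_shuffle = 50, n_reps = 500,
                         seed = 1, C = 1, observed = NULL) {
  if (n_shuffles < 1) stopf("shuffle_null: n_shuffles must be >= 1")
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2L) stopf("shuffle_null: need exactly 2 condition labels")
  y <- ifelse(labels == lev[2], 1, -1)
  X <- standardize_features(as.matrix(features))
  K <- tcrossprod(X)
  if (is.null(observed)) {
    observed <- with_seed(derive_seed(seed, "observed"),
                          loo_accuracy(K, y, which(y == 1), which(y == -1), n_reps, C))
  }
  null <- with_seed(derive_seed(seed, "shuffles"), {
    vapply(seq_len(n_shuffles), function(s) {
      ys <- sample(y)
      loo_accuracy(K, ys, which(ys == 1), which(ys == -1), n_reps_per_shuffle, C)
    }, numeric(1))
  })
  p <- (1 + sum(null >= as.numeric(observed))) / (1 + n_shuffles)
  structure(list(accuracy = as.numeric(observed), n_reps = n_reps,
                 null_distribution = null, n_shuffles = n_shuffles,
                 p_value = p, seed = seed,
                 meta = list(train_size = length(y) - 2L,
                             n_reps_per_shuffle = n_reps_per_shuffle, C = C)),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> accuracy %.1f%% (%d reps), null: %d shuffles (%.1f-%.1f%%), p = %.4g\n",
              x$accuracy, x$n_reps, x$n_shuffles,
              min(x$null_distribution), max(x$null_distribution), x$p_value))
  invisible(x)
}
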