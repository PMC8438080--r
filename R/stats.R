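#' Welch's unequal-variance t-test
#'
#' Two-sample Welch t-test (or one-sample t-test against `mu` when `b` is
#' `NULL`), returning the statistic, Welch-Satterthwaite degrees of freedom,
#' and two-sided p-value. When both samples have zero variance the test is
#' uninformative and `p = 1` is returned with a flag, a convention shared by
#' the pixel-wise map comparison.
#'
#' @param a,b Numeric vectors (each of length >= 2). `b = NULL` gives the
#'   one-sample test.
#' @param mu Null mean for the one-sample variant.
#' @return A list of class `welch_test` with `statistic`, `df`,
#'   `p_two_sided`, `direction` (sign of the effect), and `degenerate`
#'   (TRUE when variance was zero everywhere).
#' @export
welch_t <- function(a, b = NULL, mu = 0) {
  a <- a[is.finite(a)]
  if (length(a) < 2L) stopf("welch_t: need at least 2 finite values in 'a'")
  if (is.null(b)) {
    va <- stats::var(a)
    if (va == 0) {
      d <- mean(a) - mu
      res <- list(statistic = if (d == 0) 0 else sign(d) * Inf,
                  df = length(a) - 1, p_two_sided = if (d == 0) 1 else 0,
                  direction = sign(d), degenerate = d == 0)
      class(res) <- "welch_test"
      return(res)
    }
    t <- (mean(a) - mu) / sqrt(va / length(a))
    df <- length(a) - 1
  } else {
    b <- b[is.finite(b)]
    if (length(b) < 2L) stopf("welch_t: need at least 2 finite values in 'b'")
    va <- stats::var(a); vb <- stats::var(b)
    na <- length(a); nb <- length(b)
    if (va == 0 && vb == 0) {
      d <- mean(a) - mean(b)
      res <- list(statistic = if (d == 0) 0 else sign(d) * Inf,
                  df = na + nb - 2, p_two_sided = if (d == 0) 1 else 0,
                  direction = sign(d), degenerate = d == 0)
      class(res) <- "welch_test"
      return(res)
    }
    se2a <- va / na; se2b <- vb / nb
    t <- (mean(a) - mean(b)) / sqrt(se2a + se2b)
    df <- (se2a + se2b)^2 /
      (se2a^2 / (na - 1) + se2b^2 / (nb - 1))
  }
  res <- list(statistic = t, df = df,
              p_two_sided = 2 * stats::pt(-abs(t), df),
              direction = sign(t), degenerate = FALSE)
  class(res) <- "welch_test"
  res
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("Welch t = %.4g, df = %.3g, p = %.4g\n",
              x$statistic, x$df, x$p_two_sided))
  invisible(x)
}

# Vectorized Welch test from sufficient statistics; used by the pixel-wise
# map comparison and the time-resolved pupil comparison. Zero-variance-in-
# both cells get p = 1 (no variance, no evidence).
welch_t_stats <- function(ma, va, na, mb, vb, nb) {
  se2a <- va / na
  se2b <- vb / nb
  denom <- sqrt(se2a + se2b)
  t <- (ma - mb) / denom
  df <- (se2a + se2b)^2 / (se2a^2 / (na - 1) + se2b^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  degen <- is.finite(ma) & is.finite(mb) & (va + vb == 0)
  t[degen & ma == mb] <- 0
  p[degen & ma == mb] <- 1
  t[degen & ma != mb] <- sign(ma - mb)[degen & ma != mb] * Inf
  p[degen & ma != mb] <- 0
  df[degen] <- na + nb - 2
  list(t = t, df = df, p = p)
}

#' Benjamini-Hochberg FDR rejection mask
#'
#' Step-up Benjamini-Hochberg procedure at level `q`: reject the `k`
#' smallest p-values where `k` is the largest index with
#' `p_(k) <= k/m * q`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed; never
#'   rejected and not counted in the family).
#' @param q FDR level.
#' @return Logical vector, `TRUE` where rejected.
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (length(p) == 0L) return(logical(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("bh_fdr: p-values outside [0,1]")
  out <- rep(FALSE, length(p))
  ok <- !is.na(p)
  padj <- stats::p.adjust(p[ok], method = "BH")
  out[ok] <- padj <= q
  out
}

#' Sidak multiplicity adjustment
#'
#' Adjusted p-value `1 - (1 - p)^m` for `m` comparisons, used for post-hoc
#' pairwise contrasts after an ANOVA.
#'
#' @param p p-value(s) in `[0, 1]`.
#' @param m Number of comparisons (>= 1).
#' @return Adjusted p-value(s), clipped to 1.
#' @export
sidak_adjust <- function(p, m) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("sidak_adjust: p outside [0,1]")
  if (any(m < 1)) stopf("sidak_adjust: m must be >= 1")
  pmin(1, 1 - (1 - p)^m)
}

#' Between-subjects factorial ANOVA
#'
#' Fixed-effects factorial ANOVA on a long-format table, treating every row
#' (typically a trial-level measurement) as an observation. For balanced
#' designs the classical sequential decomposition coincides with Type II;
#' for unbalanced data Type II sums of squares are used (via
#' \code{car::Anova}) and recorded in the output.
#'
#' @param table data.frame in long format.
#' @param response Name of the numeric response column.
#' @param factors Character vector of factor column names; all main effects
#'   and interactions are fitted.
#' @return data.frame with columns `effect`, `df`, `df_resid`, `F`, `p`,
#'   plus attribute `ss_type = "II"`.
#' @export
factorial_anova <- function(table, response, factors) {
  if (!response %in% names(table)) stopf("factorial_anova: no column '%s'", response)
  missing_f <- setdiff(factors, names(table))
  if (length(missing_f)) stopf("factorial_anova: missing factor column '%s'", missing_f[1])
  dat <- table[, c(response, factors)]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  for (f in factors) dat[[f]] <- factor(dat[[f]])
  # every cell must be observed
  cells <- table(dat[factors])
  if (any(cells == 0)) {
    idx <- which(cells == 0, arr.ind = TRUE)[1, , drop = TRUE]
    lab <- paste(mapply(function(f, i) paste0(f, "=", dimnames(cells)[[f]][i]),
                        factors, idx), collapse = ", ")
    stopf("factorial_anova: empty design cell (%s)", lab)
  }
  fml <- stats::as.formula(paste(response, "~", paste(factors, collapse = " * ")))
  fit <- stats::lm(fml, data = dat)
  an <- car::Anova(fit, type = 2)
  keep <- rownames(an) != "Residuals"
  out <- data.frame(effect = rownames(an)[keep],
                    df = an$Df[keep],
                    df_resid = an$Df[!keep],
                    F = an$`F value`[keep],
                    p = an$`Pr(>F)`[keep],
                    stringsAsFactors = FALSE)
  attr(out, "ss_type") <- "II"
  out
}
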