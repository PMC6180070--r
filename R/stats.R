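#' Friedman test with mid-rank tie correction
#'
#' Non-parametric analysis of variance for k related treatments observed
#' over n blocks.  Values are ranked within each block (ties receive
#' mid-ranks) and the tie-corrected chi-square statistic
#' \deqn{Q = (k-1) \sum_j (R_j - n(k+1)/2)^2 /
#'          (\sum_{ij} r_{ij}^2 - n k (k+1)^2 / 4)}
#' is referred to the chi-square distribution with k-1 degrees of freedom
#' (upper tail).  Without ties this reduces to the classical
#' \eqn{12 \sum_j (R_j - n(k+1)/2)^2 / (n k (k+1))}.
#'
#' @param block_matrix Numeric matrix, blocks x treatments (n >= 2,
#'   k >= 2), no missing blocks.
#' @return List of class `mwm_friedman`: `Q`, `df` (= k-1), `p`, `k`,
#'   `n_blocks`.
#' @export
friedman_test <- function(block_matrix) {
  m <- as.matrix(block_matrix)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need at least 2 blocks and 2 treatments")
  if (any(!is.finite(m))) stop("missing or non-finite values in block matrix")
  n <- nrow(m); k <- ncol(m)
  r <- t(apply(m, 1, rank))
  Rj <- colSums(r)
  num <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2)
  den <- sum(r^2) - n * k * (k + 1)^2 / 4
  Q <- if (den <= 0) 0 else num / den  # all-tied blocks carry no information
  p <- chi2_upper_tail(Q, k - 1)
  structure(list(Q = Q, df = k - 1L, p = p, k = k, n_blocks = n),
            class = "mwm_friedman")
}

#' @export
print.mwm_friedman <- function(x, ...) {
  cat(sprintf("Friedman test: Q = %.3f, df = %d, p = %.4g (n = %d blocks, k = %d)\n",
              x$Q, x$df, x$p, x$n_blocks, x$k))
  invisible(x)
}

#' Upper-tail probability of the chi-square distribution
#'
#' @param Q Non-negative statistic.
#' @param df Degrees of freedom (>= 1).
#' @return P(X >= Q) for X ~ chi-square(df).
#' @export
chi2_upper_tail <- function(Q, df) {
  if (any(Q < 0)) stop("Q must be non-negative")
  stopifnot(df >= 1)
  pchisq(Q, df = df, lower.tail = FALSE)
}

#' Exact binomial confidence interval over classifier significance votes
#'
#' Treats the per-classifier significance outcome (1 = that classifier's
#' classification shows a significant group difference, 0 = not) as a
#' Bernoulli process and returns the Clopper-Pearson 95% interval for the
#' success probability.  The conclusion is CONFIRMED when the whole
#' interval lies clearly above 0.5, i.e. the lower bound exceeds 0.5.
#'
#' @param outcomes Binary (0/1 or logical) vector, one entry per
#'   classifier.
#' @param conf_level Confidence level (default 0.95).
#' @return List of class `mwm_binom_ci`: `successes`, `n`, `mean`, `low`,
#'   `high`, `confirmed`.
#' @export
vote_significance_ci <- function(outcomes, conf_level = 0.95) {
  x <- as.integer(as.logical(outcomes))
  if (length(x) < 1 || any(is.na(x))) stop("outcomes must be binary and non-empty")
  n <- length(x); s <- sum(x)
  alpha <- 1 - conf_level
  low <- if (s == 0) 0 else qbeta(alpha / 2, s, n - s + 1)
  high <- if (s == n) 1 else qbeta(1 - alpha / 2, s + 1, n - s)
  structure(list(successes = s, n = n, mean = s / n, low = low, high = high,
                 confirmed = low > 0.5),
            class = "mwm_binom_ci")
}

#' @export
print.mwm_binom_ci <- function(x, ...) {
  cat(sprintf("Binomial CI: %d/%d = %.2f, 95%% CI [%.3f, %.3f]%s\n",
              x$successes, x$n, x$mean, x$low, x$high,
              if (x$confirmed) " CONFIRMED (> 0.5)" else ""))
  invisible(x)
}

#' Two-group Friedman comparison across trials
#'
#' Builds the block matrix with one block per trial and two columns
#' holding the per-group means of the per-animal measure for that trial
#' (group sizes may differ, so blocks are trial-level group aggregates,
#' not animal pairs), then runs the tie-corrected [friedman_test()].
#'
#' @param values Data frame with columns `group`, `trial`, `animal`,
#'   `value` (one row per animal-trial).
#' @return An `mwm_friedman` result (k = 2, df = 1).
#' @export
group_compare <- function(values) {
  stopifnot(all(c("group", "trial", "animal", "value") %in% names(values)))
  groups <- sort(unique(values$group))
  if (length(groups) != 2) stop("exactly two groups are required")
  trials <- sort(unique(values$trial))
  m <- matrix(NA_real_, length(trials), 2,
              dimnames = list(trials, groups))
  for (ti in seq_along(trials)) {
    for (gi in 1:2) {
      v <- values$value[values$trial == trials[ti] & values$group == groups[gi]]
      if (length(v) == 0) stop(sprintf("group '%s' absent in trial %s",
                                       groups[gi], trials[ti]))
      m[ti, gi] <- mean(v)
    }
  }
  friedman_test(m)
}
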