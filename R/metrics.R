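#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a random positive
#' outranks a random negative, with ties counted one half.
#'
#' @param scores Numeric predictor.
#' @param labels Logical (or 0/1) class labels; both classes must occur.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0) stop("both classes required for AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Obtained by beta-quantile inversion of the binomial tail probabilities.
#'
#' @param successes Number of successes (0..n).
#' @param n Number of trials (>= 1).
#' @param level Confidence level.
#' @return Numeric vector `c(low, high)`.
#' @export
exact_binomial_ci <- function(successes, n, level = 0.95) {
  stopifnot(n >= 1, successes >= 0, successes <= n)
  a <- (1 - level) / 2
  low <- if (successes == 0) 0 else stats::qbeta(a, successes, n - successes + 1)
  high <- if (successes == n) 1 else stats::qbeta(1 - a, successes + 1, n - successes)
  c(low = low, high = high)
}

#' Confidence interval from per-fold statistics
#'
#' Treats the statistics computed on the cross-validation folds as iid and
#' forms `mean +/- t_{k-1} * sd / sqrt(k)`.
#'
#' @param fold_statistics Numeric vector of per-fold values.
#' @param level Confidence level.
#' @return List with `mean`, `low`, `high`, and `flagged` (TRUE when fewer
#'   than 2 folds made an interval impossible).
#' @export
fold_ci <- function(fold_statistics, level = 0.95) {
  x <- fold_statistics[is.finite(fold_statistics)]
  k <- length(x)
  if (k < 2) {
    return(list(mean = if (k) mean(x) else NA_real_,
                low = NA_real_, high = NA_real_, flagged = TRUE))
  }
  m <- mean(x)
  half <- stats::qt(1 - (1 - level) / 2, df = k - 1) * stats::sd(x) / sqrt(k)
  list(mean = m, low = m - half, high = m + half, flagged = FALSE)
}

#' Cohen's kappa and percent agreement for binary ratings
#'
#' Kappa is `(p_o - p_e) / (1 - p_e)` with chance agreement from the marginal
#' products; percent agreement is the observed agreement `p_o`. Callers
#' dichotomize murmur grades (e.g. grade >= 1) before the call.
#'
#' @param rater1,rater2 Logical (or 0/1) vectors of equal length.
#' @return List with `kappa` (NA with `flagged = TRUE` when both raters are
#'   constant and equal, where chance agreement is 1) and
#'   `percent_agreement` in \[0, 100\].
#' @export
kappa_and_agreement <- function(rater1, rater2) {
  r1 <- as.logical(rater1); r2 <- as.logical(rater2)
  stopifnot(length(r1) == length(r2), length(r1) > 0)
  p_o <- mean(r1 == r2)
  p1 <- mean(r1); p2 <- mean(r2)
  p_e <- p1 * p2 + (1 - p1) * (1 - p2)
  if (abs(1 - p_e) < 1e-15) {
    return(list(kappa = NA_real_, percent_agreement = 100 * p_o, flagged = TRUE))
  }
  list(kappa = (p_o - p_e) / (1 - p_e), percent_agreement = 100 * p_o,
       flagged = FALSE)
}
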