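# Diagnostic-performance and repeatability statistics: ROC/AUC with
# DeLong comparison of correlated curves, confusion-matrix metrics,
# McNemar, ICC(2,1) with Fisher-Z comparison.

.check_labels <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  labels <- as.integer(as.logical(labels))
  if (!any(labels == 1) || !any(labels == 0))
    stop("ROC needs both classes present", call. = FALSE)
  labels
}

# midrank-based placements: V10_i = P(X_i > Y) + 0.5 P(X_i = Y), etc.
.delong_placements <- function(scores, labels) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  m <- length(x); n <- length(y)
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = colMeans(cmp), auc = mean(cmp),
       m = m, n = n)
}

#' ROC curve and AUC
#'
#' Empirical ROC with the Mann-Whitney AUC estimator (ties count one
#' half).  The 95% CI uses the DeLong structural-components variance.
#' The reported optimal threshold maximizes Youden's J; ties are broken
#' toward the higher threshold (higher specificity), the natural
#' direction for deficit-style scores where prediction is positive at or
#' above the threshold.
#'
#' @param scores Numeric scores (higher = more diseased, e.g. TPD).
#' @param labels Binary ground truth (1/TRUE = positive).
#' @return Object of class `roc_result`: `auc`, `ci95`, `thresholds`,
#'   `sens`, `spec`, `optimal_threshold`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- .check_labels(scores, labels)
  pl <- .delong_placements(scores, labels)
  v <- if (pl$m > 1 && pl$n > 1)
    stats::var(pl$v10) / pl$m + stats::var(pl$v01) / pl$n else NA_real_
  ci <- if (is.na(v)) c(NA_real_, NA_real_) else
    pmin(pmax(pl$auc + c(-1, 1) * 1.959964 * sqrt(v), 0), 1)
  thr <- c(sort(unique(scores)), Inf)
  sens <- vapply(thr, function(t) mean(scores[labels == 1] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[labels == 0] < t), numeric(1))
  j <- sens + spec - 1
  best <- max(which(j == max(j)))   # highest threshold among ties
  structure(list(auc = pl$auc, ci95 = ci, thresholds = thr, sens = sens,
                 spec = spec, youden = j,
                 optimal_threshold = thr[best]),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (95%% CI %.3f-%.3f), optimal threshold %.4g\n",
              x$auc, x$ci95[1], x$ci95[2], x$optimal_threshold))
  invisible(x)
}

#' DeLong test for two correlated AUCs
#'
#' Paired comparison of the AUCs of two score sets over the same cases,
#' using the structural-components estimate of the variance of the AUC
#' difference and a two-sided normal p-value.  If the estimated variance
#' of the difference is zero, p = 1 when the AUCs are equal (identical
#' curves), else the z statistic is infinite.
#'
#' @param scores_a,scores_b Paired scores.
#' @param labels Shared binary labels.
#' @return List: `auc_a`, `auc_b`, `z`, `p`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- .check_labels(scores_a, labels)
  if (length(scores_b) != length(scores_a))
    stop("paired scores differ in length", call. = FALSE)
  pa <- .delong_placements(scores_a, labels)
  pb <- .delong_placements(scores_b, labels)
  m <- pa$m; n <- pa$n
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  vd <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- pa$auc - pb$auc
  if (vd <= 0) {
    z <- if (d == 0) 0 else sign(d) * Inf
  } else z <- d / sqrt(vd)
  list(auc_a = pa$auc, auc_b = pb$auc, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Confusion-matrix metrics at a threshold
#'
#' Prediction is positive when `score >= threshold` (deficit-style
#' scores).
#'
#' @param scores Numeric scores.
#' @param labels Binary ground truth.
#' @param threshold Decision threshold.
#' @return List: `sens`, `spec`, `ppv`, `npv` (percent, NA when
#'   undefined) and `table` (2x2 matrix: rows predicted, cols truth).
#' @export
confusion_at_threshold <- function(scores, labels, threshold) {
  labels <- as.integer(as.logical(labels))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  pct <- function(a, b) if (a + b == 0) NA_real_ else 100 * a / (a + b)
  list(sens = pct(tp, fn), spec = pct(tn, fp),
       ppv = pct(tp, fp), npv = pct(tn, fn),
       table = matrix(c(tp, fn, fp, tn), 2, 2,
                      dimnames = list(predicted = c("pos", "neg"),
                                      truth = c("pos", "neg"))))
}

#' McNemar test on discordant pairs
#'
#' Exact two-sided binomial test on the discordant counts when
#' `b + c < 25`, otherwise the continuity-corrected chi-square.
#' `b = c = 0` returns p = 1 by convention.
#'
#' @param b,c Discordant-pair counts.
#' @return Two-sided p-value.
#' @export
mcnemar_test <- function(b, c) {
  stopifnot(b >= 0, c >= 0)
  n <- b + c
  if (n == 0) return(1)
  if (n < 25) {
    p <- 2 * stats::pbinom(min(b, c), n, 0.5)
    if (b == c) p <- p - stats::dbinom(b, n, 0.5)  # don't double-count center
    return(min(p, 1))
  }
  x <- (abs(b - c) - 1)^2 / n
  stats::pchisq(x, df = 1, lower.tail = FALSE)
}

#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC
#' from the ANOVA mean squares of a subjects x raters (test/retest)
#' table, with the 95% CI of McGraw and Wong.  Zero or negative
#' between-subject variance yields a nonpositive ICC and is flagged.
#'
#' @param test,retest Paired measurements (n >= 3).
#' @return Object of class `icc_result`: `icc`, `ci95`, `n`, `ms`
#'   (mean squares), `degenerate`.
#' @export
icc_agreement <- function(test, retest) {
  if (length(test) != length(retest))
    stop("test and retest differ in length", call. = FALSE)
  n <- length(test)
  if (n < 3) stop("need at least 3 paired measurements", call. = FALSE)
  x <- cbind(test, retest)
  k <- 2
  row_m <- rowMeans(x); col_m <- colMeans(x); g <- mean(x)
  msr <- k * sum((row_m - g)^2) / (n - 1)
  msc <- n * sum((col_m - g)^2) / (k - 1)
  sse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + g)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  # McGraw & Wong F-based CI for ICC(A,1)
  alpha <- 0.05
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  vnum <- (a * msc + b * mse)^2
  vden <- (a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1))
  v <- vnum / vden
  ci <- c(NA_real_, NA_real_)
  degenerate <- !is.finite(icc) || msr <= mse
  if (!degenerate && is.finite(v) && v > 0) {
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
    ci <- c(lo, hi)
  }
  structure(list(icc = icc, ci95 = ci, n = n,
                 ms = c(msr = msr, msc = msc, mse = mse),
                 degenerate = degenerate),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC(2,1) = %.3f (95%% CI %.3f-%.3f), n = %d%s\n",
              x$icc, x$ci95[1], x$ci95[2], x$n,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Fisher-Z comparison of two ICCs
#'
#' `z = (atanh(icc_a) - atanh(icc_b)) / sqrt(1/(n_a-3) + 1/(n_b-3))`
#' with a two-sided normal p-value; the transform normalizes the
#' sampling distribution of correlation-type estimates.
#'
#' @param icc_a,icc_b ICC estimates (|icc| < 1).
#' @param n_a,n_b Numbers of subjects (> 3).
#' @return List: `z`, `p`.
#' @export
fisher_z_compare <- function(icc_a, n_a, icc_b, n_b) {
  stopifnot(abs(icc_a) < 1, abs(icc_b) < 1, n_a > 3, n_b > 3)
  z <- (atanh(icc_a) - atanh(icc_b)) /
    sqrt(1 / (n_a - 3) + 1 / (n_b - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}
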