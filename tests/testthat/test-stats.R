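# ROC/AUC, DeLong, confusion metrics, McNemar, ICC, Fisher-Z.

# brute-force AUC by pair enumeration (independent oracle)
auc_brute <- function(scores, labels) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  tot <- 0
  for (a in x) for (b in y)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(x) * length(y))
}

test_that("AUC equals brute-force pair counting, including edge cases", {
  expect_equal(roc_auc(1:4, c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(roc_auc(rep(2, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  expect_equal(roc_auc(c(1, 3, 2, 4), c(0, 0, 1, 1))$auc,
               auc_brute(c(1, 3, 2, 4), c(0, 0, 1, 1)))
  set.seed(61)
  for (r in 1:20) {
    n <- sample(6:50, 1)
    sc <- sample(0:10, n, replace = TRUE)   # plenty of ties
    lb <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(roc_auc(sc, lb)$auc, auc_brute(sc, lb))
  }
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("Youden-optimal threshold breaks ties toward specificity", {
  r <- roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(r$auc, 1.0)
  # any threshold in (3, 10] is perfect; tie-break picks the largest
  expect_equal(r$optimal_threshold, 10)
  cm <- confusion_at_threshold(c(1, 2, 3, 10, 11, 12),
                               c(0, 0, 0, 1, 1, 1), r$optimal_threshold)
  expect_equal(c(cm$sens, cm$spec, cm$ppv, cm$npv), c(100, 100, 100, 100))
})

test_that("DeLong test: identical curves, structural-components oracle, symmetry", {
  set.seed(62)
  lab <- rep(c(0, 1), each = 10)
  a <- rnorm(20) + lab
  expect_equal(delong_test(a, a, lab)$p, 1)
  b <- 0.5 * a + rnorm(20, sd = 0.8)
  dt <- delong_test(a, b, lab)
  # independent double-sum oracle of the paired variance
  x_a <- a[lab == 1]; y_a <- a[lab == 0]
  x_b <- b[lab == 1]; y_b <- b[lab == 0]
  m <- 10; n <- 10
  psi <- function(u, v) (u > v) + 0.5 * (u == v)
  v10a <- sapply(seq_len(m), function(i) mean(psi(x_a[i], y_a)))
  v01a <- sapply(seq_len(n), function(j) mean(psi(x_a, y_a[j])))
  v10b <- sapply(seq_len(m), function(i) mean(psi(x_b[i], y_b)))
  v01b <- sapply(seq_len(n), function(j) mean(psi(x_b, y_b[j])))
  vd <- (var(v10a) + var(v10b) - 2 * cov(v10a, v10b)) / m +
    (var(v01a) + var(v01b) - 2 * cov(v01a, v01b)) / n
  z_oracle <- (mean(v10a) - mean(v10b)) / sqrt(vd)
  expect_equal(dt$z, z_oracle, tolerance = 1e-10)
  # symmetric under swapping the two score sets
  dt_sw <- delong_test(b, a, lab)
  expect_equal(dt_sw$p, dt$p, tolerance = 1e-12)
  expect_equal(dt_sw$z, -dt$z, tolerance = 1e-12)
})

test_that("confusion matrix metrics match the worked 2x2 table", {
  # TP=9, FN=1, FP=2, TN=8
  scores <- c(rep(1, 9), 0, 1, 1, rep(0, 8))
  labels <- c(rep(1, 10), rep(0, 10))
  cm <- confusion_at_threshold(scores, labels, 1)
  expect_equal(cm$table["pos", "pos"], 9)
  expect_equal(cm$sens, 90)
  expect_equal(cm$spec, 80)
  expect_equal(cm$ppv, 100 * 9 / 11, tolerance = 1e-9)
  expect_equal(cm$npv, 100 * 8 / 9, tolerance = 1e-9)
  # threshold above every score: sens 0, spec 100
  cm2 <- confusion_at_threshold(scores, labels, 2)
  expect_equal(c(cm2$sens, cm2$spec), c(0, 100))
})

test_that("McNemar: exact two-sided values and conventions", {
  expect_equal(mcnemar_test(8, 2), 0.109375)
  expect_equal(mcnemar_test(2, 8), 0.109375)
  expect_equal(mcnemar_test(5, 5), 1)
  expect_equal(mcnemar_test(0, 0), 1)
  # large-sample branch agrees with the continuity-corrected chi-square
  expect_equal(mcnemar_test(20, 10),
               stats::pchisq((abs(20 - 10) - 1)^2 / 30, 1, lower.tail = FALSE))
})

test_that("ICC(2,1) matches the aov mean-square oracle and its contracts", {
  set.seed(63)
  t1 <- rnorm(6); t2 <- t1 + rnorm(6, 0, 0.5) + 0.2
  r <- icc_agreement(t1, t2)
  d <- data.frame(y = c(t1, t2), subj = factor(rep(1:6, 2)),
                  rater = factor(rep(1:2, each = 6)))
  ms <- stats::anova(stats::aov(y ~ subj + rater, d))[["Mean Sq"]]
  icc_o <- (ms[1] - ms[3]) / (ms[1] + ms[3] + 2 * (ms[2] - ms[3]) / 6)
  expect_equal(r$icc, icc_o, tolerance = 1e-12)
  expect_lte(r$icc, 1)
  # perfect agreement
  expect_equal(icc_agreement(t1, t1)$icc, 1)
  # invariant under a shared shift (absolute agreement)
  r2 <- icc_agreement(t1 + 5, t2 + 5)
  expect_equal(r2$icc, r$icc, tolerance = 1e-12)
  expect_error(icc_agreement(t1, t2[-1]), "length")
  expect_error(icc_agreement(1:2, 1:2), "at least 3")
  # degenerate: no between-subject variance
  rd <- icc_agreement(rep(1, 5), rep(1.5, 5))
  expect_true(rd$degenerate)
  expect_lte(rd$icc, 0)
})

test_that("ICC recovers a known intraclass correlation at n = 2000", {
  set.seed(64)
  s <- rnorm(2000, 0, sqrt(0.4))
  x <- s + rnorm(2000, 0, sqrt(0.6))
  y <- s + rnorm(2000, 0, sqrt(0.6))
  expect_lt(abs(icc_agreement(x, y)$icc - 0.4), 0.05)
})

test_that("Fisher-Z comparison follows its closed form", {
  expect_equal(fisher_z_compare(0.5, 25, 0.5, 25)$p, 1)
  fz <- fisher_z_compare(0.8, 50, 0.2, 50)
  z_hand <- (atanh(0.8) - atanh(0.2)) / sqrt(1 / 47 + 1 / 47)
  expect_equal(fz$z, z_hand, tolerance = 1e-12)
  expect_equal(fz$p, 2 * pnorm(-abs(z_hand)), tolerance = 1e-12)
  expect_error(fisher_z_compare(1, 10, 0.5, 10), "icc_a")
})
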