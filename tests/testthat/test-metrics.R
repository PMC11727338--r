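# Metric suite against brute-force oracles, plus the analytic identities
# (F1/DSC equality, AUC rank invariance, HD95 symmetry).

test_that("confusion counts match trivial and brute-force cases", {
  m <- matrix(0L, 10, 10); m[1:2, 1:5] <- 1L
  cc <- confusion_counts(m, m)
  expect_identical(unlist(cc), c(tp = 10L, fp = 0L, tn = 90L, fn = 0L))
  ones <- matrix(1L, 4, 4); zeros <- matrix(0L, 4, 4)
  cc2 <- confusion_counts(ones, zeros)
  expect_identical(unlist(cc2), c(tp = 0L, fp = 16L, tn = 0L, fn = 0L))
  set.seed(1)
  p <- random_mask(8); t <- random_mask(8)
  expect_identical(as.list(confusion_counts(p, t)), oracle_confusion(p, t))
})

test_that("dsc covers trivial, degenerate and hand-counted cases", {
  m <- random_mask(6, 0.4)
  if (sum(m) == 0) m[1, 1] <- 1L
  expect_equal(dsc(m, m), 1.0)
  a <- matrix(0L, 4, 4); a[1, 1] <- 1L
  b <- matrix(0L, 4, 4); b[4, 4] <- 1L
  expect_equal(dsc(a, b), 0.0)
  # |A| = 4, |B| = 2, |A.B| = 2 -> 2*2/6
  A <- matrix(0L, 4, 4); A[1, 1:4] <- 1L
  B <- matrix(0L, 4, 4); B[1, 1:2] <- 1L
  expect_equal(dsc(A, B), 2 * 2 / 6)
  z <- matrix(0L, 4, 4)
  expect_equal(dsc(z, z), 1.0)   # both empty: agreement on "no lesion"
  expect_equal(dsc(A, z), 0.0)
})

test_that("precision/recall/accuracy follow their confusion-count formulas", {
  pr <- prf_metrics(list(tp = 2, fp = 2, tn = 0, fn = 0))
  expect_equal(pr$precision, 0.5)
  pr2 <- prf_metrics(list(tp = 3, fp = 0, tn = 5, fn = 0))
  expect_equal(pr2$recall, 1.0)
  pr3 <- prf_metrics(list(tp = 3, fp = 1, tn = 10, fn = 2))
  expect_equal(pr3$accuracy, 13 / 16)
  expect_true(is.na(prf_metrics(list(tp = 0, fp = 0, tn = 4, fn = 1))$precision))
})

test_that("ROC-AUC: perfect separation, constant scores, rank oracle, monotone invariance", {
  truth <- c(1, 1, 0, 1, 0, 0)
  perfect <- c(0.9, 0.8, 0.3, 0.7, 0.2, 0.1)
  expect_equal(roc_auc(perfect, truth), 1.0)
  expect_equal(roc_auc(rep(0.4, 6), truth), 0.5)   # single interior trapezoid
  probs <- c(0.9, 0.8, 0.7, 0.4, 0.3, 0.1)
  expect_equal(roc_auc(probs, truth), oracle_auc(probs, truth))
  # invariant under strictly monotone transforms of the scores
  expect_equal(roc_auc(qlogis(probs * 0.98 + 0.01), truth), roc_auc(probs, truth))
  expect_equal(roc_auc(probs^3, truth), roc_auc(probs, truth))
  expect_error(roc_auc(probs, rep(1, 6)), "single class")
})

test_that("ROC curve endpoints and monotonicity hold on random maps", {
  set.seed(2)
  for (i in 1:5) {
    probs <- matrix(runif(64), 8, 8)
    truth <- random_mask(8)
    if (length(unique(as.vector(truth))) < 2) next
    rc <- roc_curve(probs, truth)
    expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[1], 0)
    expect_equal(rc$fpr[nrow(rc)], 1); expect_equal(rc$tpr[nrow(rc)], 1)
    expect_true(all(diff(rc$fpr) >= 0))
    expect_equal(roc_auc(probs, truth), oracle_auc(probs, truth), tolerance = 1e-12)
  }
})

test_that("hd95: zero on identity, two-point case, shifted-square oracle", {
  m <- matrix(0L, 8, 8); m[3:5, 3:5] <- 1L
  expect_equal(hd95(m, m), 0.0)
  a <- matrix(0L, 9, 9); a[2, 2] <- 1L
  b <- matrix(0L, 9, 9); b[2, 7] <- 1L
  expect_equal(hd95(a, b), 5.0)
  sq <- matrix(0L, 16, 16); sq[3:8, 3:8] <- 1L
  sh <- matrix(0L, 16, 16); sh[6:11, 3:8] <- 1L   # shifted 3 px, in bounds
  expect_equal(hd95(sq, sh), oracle_hd95(sq, sh), tolerance = 1e-12)
  expect_error(hd95(matrix(0L, 4, 4), m[1:4, 1:4]), "empty")
})

test_that("hd95 is symmetric and translation invariant", {
  set.seed(3)
  base <- matrix(0L, 20, 20); base[5:9, 6:11] <- 1L; base[8:10, 14:15] <- 1L
  other <- matrix(0L, 20, 20); other[6:12, 5:9] <- 1L
  expect_equal(hd95(base, other), hd95(other, base))
  shift <- function(m, d) {
    out <- matrix(0L, nrow(m), ncol(m))
    out[(1 + d):nrow(m), (1 + d):ncol(m)] <- m[1:(nrow(m) - d), 1:(ncol(m) - d)]
    out
  }
  expect_equal(hd95(shift(base, 3), shift(other, 3)), hd95(base, other))
})

test_that("all metrics agree with brute force on 100 seeded random pairs", {
  set.seed(99)
  n_checked_hd <- 0
  for (i in 1:100) {
    pred <- random_mask(16, runif(1, 0.2, 0.6))
    truth <- random_mask(16, runif(1, 0.2, 0.6))
    probs <- matrix(runif(256), 16, 16)
    cc <- confusion_counts(pred, truth)
    oc <- oracle_confusion(pred, truth)
    expect_identical(as.list(cc), oc)                      # exact counts
    expect_equal(dsc(pred, truth), oracle_dsc(pred, truth), tolerance = 1e-9)
    pr <- prf_metrics(cc)
    expect_equal(pr$precision, oc$tp / (oc$tp + oc$fp), tolerance = 1e-9)
    expect_equal(pr$recall, oc$tp / (oc$tp + oc$fn), tolerance = 1e-9)
    expect_equal(pr$accuracy, (oc$tp + oc$tn) / 256, tolerance = 1e-9)
    expect_equal(roc_auc(probs, truth), oracle_auc(probs, truth), tolerance = 1e-9)
    if (sum(pred) > 0 && sum(truth) > 0 && i <= 25) {      # oracle is O(n^2)
      expect_equal(hd95(pred, truth), oracle_hd95(pred, truth), tolerance = 1e-9)
      n_checked_hd <- n_checked_hd + 1
    }
    lab <- label_components(truth, 8)
    olab <- oracle_label(truth, 8)
    expect_identical(max(lab$labels), max(olab))           # same component count
  }
  expect_gt(n_checked_hd, 10)
})

test_that("DSC equals the harmonic mean of precision and recall on every pair", {
  set.seed(7)
  for (i in 1:40) {
    pred <- random_mask(12, runif(1, 0.1, 0.7))
    truth <- random_mask(12, runif(1, 0.1, 0.7))
    cc <- confusion_counts(pred, truth)
    if (cc$tp + cc$fp == 0 || cc$tp + cc$fn == 0) next
    pr <- prf_metrics(cc)
    f1 <- if (pr$precision + pr$recall == 0) 0 else
      2 * pr$precision * pr$recall / (pr$precision + pr$recall)
    expect_equal(dsc(pred, truth), f1, tolerance = 1e-12)
  }
})

test_that("roc_auc cross-checks against an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  probs <- runif(200)
  truth <- rbinom(200, 1, 0.4)
  expect_equal(roc_auc(probs, truth),
               as.numeric(pROC::auc(pROC::roc(truth, probs, quiet = TRUE))),
               tolerance = 1e-9)
})

test_that("aggregate_runs reproduces hand-computed mean, SD, and t-based CI", {
  runs <- tibble::tibble(dsc = c(0.90, 0.92))
  agg <- aggregate_runs(runs)
  expect_equal(agg$mean, 0.91)
  expect_equal(agg$sd, sd(c(0.90, 0.92)), tolerance = 1e-9)  # ~0.01414
  ident <- tibble::tibble(dsc = rep(0.8, 4), hd = rep(2.5, 4))
  agg2 <- aggregate_runs(ident)
  expect_true(all(agg2$sd == 0) && all(agg2$ci95 == 0))
  set.seed(13)
  ten <- tibble::tibble(metric_a = runif(10))
  agg3 <- aggregate_runs(ten)
  expect_equal(agg3$ci95, 2.262157 * agg3$sd / sqrt(10), tolerance = 1e-5)  # t(0.975, 9)
  expect_error(aggregate_runs(ten[1, ]), ">= 2")
})
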