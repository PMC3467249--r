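test_that("confusion metrics: perfect prediction and error paths", {
  cm <- confusion_metrics(rep(c("NR", "CCR"), 5), rep(c("NR", "CCR"), 5))
  for (m in c("sensitivity", "specificity", "ppv", "npv", "accuracy")) {
    expect_equal(cm[[m]], 100)
  }
  for (m in c("fpr", "fnr", "fdr")) expect_equal(cm[[m]], 0)
  expect_error(confusion_metrics(character(), character()),
               class = "chemosig_domain_error")
  expect_error(confusion_metrics(c("NR"), c("NR", "CCR")),
               class = "chemosig_domain_error")
})

test_that("zero-denominator rates are NA, never 0", {
  cm <- confusion_metrics(truth = c("CCR", "CCR"), predicted = c("CCR", "CCR"))
  expect_true(is.na(cm$sensitivity))
  expect_true(is.na(cm$ppv))
  expect_true(is.na(cm$fdr))
  expect_equal(cm$specificity, 100)
})

test_that("the three complementary-rate identities hold for random counts", {
  set.seed(15)
  for (i in 1:50) {
    k <- rmultinom(1, sample(4:200, 1), rep(0.25, 4))
    cm <- confusion_metrics(tp = k[1], fn = k[2], tn = k[3], fp = k[4])
    if (!is.na(cm$sensitivity)) expect_equal(cm$sensitivity + cm$fnr, 100)
    if (!is.na(cm$specificity)) expect_equal(cm$specificity + cm$fpr, 100)
    if (!is.na(cm$ppv)) expect_equal(cm$ppv + cm$fdr, 100)
    expect_equal(cm$accuracy,
                 100 * (cm$tp + cm$tn) / (cm$tp + cm$tn + cm$fp + cm$fn))
  }
})

test_that("AUC equals the normalized concordant-pair count", {
  r <- roc_auc(c(1, 2, 3, 4), c("CCR", "CCR", "NR", "NR"))
  expect_equal(r$auc, 1)
  expect_equal(roc_auc(c(1, 2, 3, 4), c("CCR", "NR", "CCR", "NR"))$auc, 0.75)
  expect_warning(rc <- roc_auc(rep(1, 6), rep(c("NR", "CCR"), 3)), "constant")
  expect_equal(rc$auc, 0.5)

  brute_auc <- function(s, y) {
    pos <- s[y == "NR"]; neg <- s[y != "NR"]
    pairs <- expand.grid(p = pos, n = neg)
    mean(ifelse(pairs$p > pairs$n, 1, ifelse(pairs$p == pairs$n, 0.5, 0)))
  }
  set.seed(16)
  for (i in 1:20) {
    n <- sample(6:50, 1)
    y <- sample(c("NR", "CCR"), n, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(y)) < 2) next
    s <- sample(round(rnorm(n), 1))   # ties likely
    expect_equal(roc_auc(s, y)$auc, brute_auc(s, y), tolerance = 1e-12)
  }
})

test_that("class-independent scores give AUC near 0.5", {
  set.seed(17)
  n <- 2000
  y <- rep(c("NR", "CCR"), n / 2)
  auc <- roc_auc(rnorm(n), y)$auc
  se <- sqrt((n / 2 + 1) / (12 * (n / 2) ^ 2))  # Mann-Whitney null SE approx
  expect_lt(abs(auc - 0.5), 3 * se)
})

test_that("ROC curve starts at (0,0) and ends at (1,1), monotone", {
  set.seed(18)
  r <- roc_auc(rnorm(30), sample(c("NR", "CCR"), 30, TRUE))$roc
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[nrow(r)], 1); expect_equal(r$tpr[nrow(r)], 1)
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
})

test_that("SMACOF embeds exactly embeddable configurations to ~zero stress", {
  set.seed(19)
  Z <- matrix(rnorm(30), 10, 3)                  # points already in 3-D
  res <- mds_smacof(Z, dims = 3)
  expect_lte(res$stress, 1e-6)
  expect_equal(res$variance_fraction, 1, tolerance = 1e-9)

  square <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2, byrow = TRUE)
  expect_lte(mds_smacof(square, dims = 2)$stress, 1e-6)
})

test_that("SMACOF stress is non-increasing and beats the classical start", {
  set.seed(20)
  for (i in 1:5) {
    X <- matrix(rnorm(12 * 8), 12, 8)
    res <- mds_smacof(X, dims = 2, tol = 1e-9)
    expect_true(all(diff(res$trace) <= 1e-12))
    expect_lte(res$trace[length(res$trace)], res$trace[1])
  }
  expect_error(mds_smacof(matrix(rnorm(6), 3, 2), dims = 3),
               class = "chemosig_dimension_error")
})

test_that("Fisher exact (probability-mass rule) matches enumeration", {
  expect_equal(fisher_exact(matrix(c(3, 10, 7, 2), 2)), 17732 / 646646,
               tolerance = 1e-12)
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_warning(p0 <- fisher_exact(matrix(c(0, 0, 3, 4), 2)), "zero margin")
  expect_equal(p0, 1)

  set.seed(21)
  for (i in 1:25) {
    tb <- matrix(sample(0:12, 4, TRUE), 2)
    if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) next
    # independent oracle: stats::fisher.test two-sided uses the same
    # probability-mass convention for 2x2 tables
    expect_equal(fisher_exact(tb), stats::fisher.test(tb)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("r x 2 exact test matches the reference implementation", {
  smoking <- matrix(c(0, 6, 3, 1, 0, 1, 1, 6, 4, 1), ncol = 2)  # NR | CCR
  p <- fisher_rx2(smoking)
  expect_equal(p, stats::fisher.test(smoking)$p.value, tolerance = 1e-9)
  expect_lt(p, 0.1)  # a borderline association, as reported for the cohort
  set.seed(22)
  for (i in 1:5) {
    tb <- matrix(sample(0:6, 8, TRUE), ncol = 2)
    if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) next
    expect_equal(fisher_rx2(tb), stats::fisher.test(tb)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("two-group comparisons match base-R oracles and edge rules", {
  set.seed(23)
  x <- rnorm(8); y <- rnorm(10, 0.5)
  expect_equal(group_compare(x, y, "welch_t"),
               t.test(x, y)$p.value, tolerance = 1e-12)
  expect_equal(group_compare(x, y, "pooled_t"),
               t.test(x, y, var.equal = TRUE)$p.value, tolerance = 1e-12)
  expect_equal(as.numeric(group_compare(x, y, "mann_whitney")),
               wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value,
               tolerance = 1e-12)
  expect_equal(attr(group_compare(x, y, "mann_whitney"), "U"),
               unname(wilcox.test(x, y, exact = FALSE)$statistic))
  expect_equal(group_compare(c(1, 1, 2), c(1, 1, 2), "pooled_t"), 1)
  expect_warning(p <- group_compare(c(1, 1), c(2, 2), "welch_t"), "zero variance")
  expect_equal(p, 0)
  expect_error(group_compare(1, c(1, 2)), class = "chemosig_domain_error")
})
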