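test_that("Mann-Whitney exact enumeration matches hand counts and wilcox", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 0.1)  # 2/20 arrangements as extreme
  # identical samples: U = nm/2, p = 1 by convention, flagged
  eq <- mann_whitney(rep(2, 5), rep(2, 4))
  expect_equal(eq$U, 10)
  expect_equal(eq$p_value, 1)
  expect_true(eq$degenerate)
  # independent oracle: wilcox.test exact p on tie-free small samples
  set.seed(41)
  for (i in 1:10) {
    x <- sample(100, sample(3:8, 1))
    y <- sample(200:300, sample(3:8, 1))
    mw <- mann_whitney(x, y)
    wt <- wilcox.test(x, y, exact = TRUE)
    expect_equal(mw$U, unname(wt$statistic))
    expect_equal(mw$p_value, wt$p.value, tolerance = 1e-12)
  }
  expect_error(mann_whitney(numeric(0), 1:3), "nonempty")
})

test_that("Mann-Whitney approximation matches wilcox.test with ties", {
  set.seed(42)
  for (i in 1:10) {
    x <- round(rnorm(30, 0, 2), 1)
    y <- round(rnorm(25, 0.8, 2), 1)
    mw <- mann_whitney(x, y)
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(mw$U, unname(wt$statistic))
    expect_equal(mw$p_value, wt$p.value, tolerance = 1e-10)
  }
})

test_that("Bonferroni threshold arithmetic", {
  expect_equal(bonferroni_threshold(0.05, 8), 0.00625)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 5), 0.002)
  # monotone decreasing in the number of comparisons
  ms <- vapply(1:10, bonferroni_threshold, alpha = 0.05, numeric(1))
  expect_true(all(diff(ms) < 0))
  expect_error(bonferroni_threshold(1.2, 4))
  expect_error(bonferroni_threshold(0.05, 0))
})

test_that("Spearman correlation: monotone invariance and oracle", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  expect_equal(spearman_rho(x, exp(x))$rho, 1)
  expect_equal(spearman_rho(x, -x)$rho, -1)
  set.seed(43)
  a <- rnorm(40); b <- a + rnorm(40)
  sr <- spearman_rho(a, b)
  ct <- cor.test(a, b, method = "spearman", exact = FALSE)
  expect_equal(sr$rho, unname(ct$estimate))
  expect_equal(sr$p_value, ct$p.value, tolerance = 1e-10)
  expect_true(spearman_rho(rep(1, 5), 1:5)$degenerate)
  expect_error(spearman_rho(1:2, 1:2), "size >= 3")
})

test_that("logistic model recovers the 2x2 contingency odds ratio", {
  # exposed: 40 cases / 10 controls; unexposed: 20 cases / 30 controls
  dat <- data.frame(
    exposed = rep(c(1, 1, 0, 0), c(40, 10, 20, 30)),
    group = rep(c("PAD", "nonPAD", "PAD", "nonPAD"), c(40, 10, 20, 30)))
  fit <- fit_mlr(dat, "exposed", covariates = character(0))
  or <- fit$terms$odds_ratio[fit$terms$term == "exposed"]
  expect_equal(or, (40 * 30) / (10 * 20), tolerance = 1e-6)
  expect_false(fit$separation)
  expect_true(fit$terms$ci_low[2] < or & or < fit$terms$ci_high[2])
})

test_that("null predictors give OR near 1; separation is flagged", {
  set.seed(44)
  dat <- data.frame(x = rnorm(200),
                    group = sample(c("PAD", "nonPAD"), 200, TRUE))
  fit <- fit_mlr(dat, "x", covariates = character(0))
  expect_gt(fit$terms$p_value[2], 0.05)
  expect_lt(abs(log(fit$terms$odds_ratio[2])), 0.5)
  sep <- data.frame(x = c(rnorm(50, -5), rnorm(50, 5)),
                    group = rep(c("nonPAD", "PAD"), each = 50))
  fs <- fit_mlr(sep, "x", covariates = character(0))
  expect_true(fs$separation)
  expect_true(all(is.na(fs$terms$odds_ratio)))
  expect_error(fit_mlr(dat[dat$group == "PAD", ], "x", character(0)),
               "per class")
})

test_that("stratified folds balance classes to within one subject", {
  labs <- rep(c("PAD", "nonPAD"), each = 118)
  f <- stratified_kfold(labs, k = 5, seed = 9)
  expect_equal(sort(as.numeric(table(f))), c(47, 47, 47, 47, 48))
  per <- table(labs, f)
  expect_true(all(per %in% c(23, 24)))
  expect_identical(f, stratified_kfold(labs, k = 5, seed = 9))
  expect_false(identical(f, stratified_kfold(labs, k = 5, seed = 10)))
  expect_error(stratified_kfold(c("a", "a", "b"), k = 2), "at least k")
})

test_that("trapezoidal AUC equals the rank-statistic identity", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)),
               1)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(TRUE, TRUE, FALSE, FALSE)),
               0)
  set.seed(45)
  for (i in 1:20) {
    n1 <- sample(5:40, 1); n0 <- sample(5:40, 1)
    p <- c(round(runif(n1), 1), round(runif(n0), 1))  # forced ties
    y <- rep(c(TRUE, FALSE), c(n1, n0))
    u <- mann_whitney(p[y], p[!y])$U
    expect_equal(roc_auc(p, y), u / (n1 * n0), tolerance = 1e-12)
  }
  expect_error(roc_auc(runif(4), rep(TRUE, 4)), "both classes")
})

test_that("pooled confusion arithmetic: 108/118 and 110/118 correct", {
  prob <- c(rep(0.2, 108), rep(0.8, 10),   # non-PAD: 10 false positives
            rep(0.9, 110), rep(0.1, 8))    # PAD: 8 false negatives
  y <- rep(c(FALSE, TRUE), each = 118)
  m <- dvos:::threshold_metrics(prob, y, 0.5)
  expect_equal(unname(m["accuracy"]), 218 / 236)
  expect_equal(unname(m["sensitivity"]), 110 / 118)
  expect_equal(unname(m["specificity"]), 108 / 118)
  expect_equal(unname(m[c("tp", "fp", "tn", "fn")]), c(110, 10, 108, 8))
  # probability exactly at threshold classifies as PAD
  expect_equal(unname(dvos:::threshold_metrics(0.5, TRUE, 0.5)["tp"]), 1)
})

test_that("cross-validation separates what is separable and not the null", {
  set.seed(46)
  n <- 60
  dat <- data.frame(
    x = c(rnorm(n, 0), rnorm(n, 8)),
    age = rnorm(2 * n, 55, 10),
    group = rep(c("nonPAD", "PAD"), each = n))
  cvp <- cross_validated_classification(dat, "x", covariates = "age",
                                        seed = 1)
  expect_equal(cvp$pooled$auc, 1)
  expect_equal(unname(cvp$pooled$metrics["accuracy"]), 1)
  expect_equal(sum(cvp$pooled$confusion), 2 * n)
  # pooled accuracy re-derived from the confusion matrix
  expect_equal(unname(cvp$pooled$metrics["accuracy"]),
               sum(diag(cvp$pooled$confusion)) / sum(cvp$pooled$confusion))
  set.seed(47)
  dat$y <- sample(dat$group)
  cvn <- cross_validated_classification(dat, "x", covariates = "age",
                                        label = "y", seed = 1)
  expect_lt(abs(cvn$pooled$auc - 0.5), 0.15)
})

test_that("medication sensitivity keeps folds and reports deltas", {
  set.seed(48)
  n <- 40
  dat <- data.frame(
    x = c(rnorm(n, 0), rnorm(n, 2)),
    age = rnorm(2 * n, 55, 10),
    statin = runif(2 * n) < 0.6,
    antiplatelet = runif(2 * n) < 0.8,
    antihypertensive = runif(2 * n) < 0.6,
    group = rep(c("nonPAD", "PAD"), each = n))
  base <- cross_validated_classification(dat, "x", covariates = "age",
                                         seed = 3)
  ms <- medication_sensitivity(dat, "x", covariates = "age", seed = 3)
  expect_identical(ms$oof$fold, base$oof$fold)  # stratification unchanged
  expect_equal(nrow(ms$comparison), 2)
  expect_equal(ms$comparison$auc[1], base$pooled$auc)
  # irrelevant medication covariates barely move the AUC
  expect_lt(abs(diff(ms$comparison$auc)), 0.1)
  expect_true(all(c("auc", "accuracy", "sensitivity", "specificity",
                    "precision", "f1") %in% ms$summary$metric))
})
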