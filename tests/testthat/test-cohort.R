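test_that("sampled covariates match the calibration moments", {
  set.seed(1)
  cv <- sample_covariates(1e4, "nonPAD")
  expect_lt(abs(mean(cv$age) - 54.8) / 54.8, 0.02)
  expect_lt(abs(sd(cv$age) - 13.7) / 13.7, 0.02)
  expect_lt(abs(mean(cv$bmi) - 30.3) / 30.3, 0.02)
  # zero-inflated hypertension duration still matches the overall moments
  expect_lt(abs(mean(cv$htn_duration) - 5.4) / 5.4, 0.04)
  expect_lt(abs(sd(cv$htn_duration) - 6.9) / 6.9, 0.04)
  expect_equal(mean(cv$htn_duration == 0), 0.45, tolerance = 0.02)
  set.seed(1)
  pad <- sample_covariates(1e4, "PAD")
  expect_lt(abs(mean(pad$smoking) - 0.19), 0.015)
  expect_lt(abs(mean(pad$sex == "M") - 0.42), 0.015)
  expect_lt(abs(mean(pad$abi_left) - 0.88), 0.01)
})

test_that("degenerate variance collapses covariates to group means", {
  set.seed(2)
  cv <- sample_covariates(50, "nonPAD", sd_scale = 0)
  expect_true(all(cv$age == 54.8))
  expect_true(all(cv$bmi == 30.3))
  expect_true(all(cv$htn_duration %in% c(0, 5.4 / 0.55)))
})

test_that("ABI screening rule follows the clinical thresholds", {
  expect_equal(classify_abi(0.85), "PAD")
  expect_equal(classify_abi(0.9), "PAD")
  expect_equal(classify_abi(1.10), "nonPAD")
  expect_equal(classify_abi(1.35), "needs_imaging")
  expect_equal(classify_abi(1.30), "needs_imaging")
  expect_equal(classify_abi(0.95), "needs_imaging")  # 0.9 < abi < 1 zone
  expect_equal(classify_abi(1.10, symptoms = TRUE), "needs_imaging")
  expect_equal(classify_abi(1.10, high_risk = TRUE), "needs_imaging")
  expect_error(classify_abi(0), "positive")
  expect_error(classify_abi(-1), "positive")
})

test_that("feature targets reproduce printed moments and severity coupling", {
  set.seed(7)
  tg <- sample_feature_targets(1e4, "nonPAD")
  se3 <- function(s) 3 * s / sqrt(1e4)
  expect_lt(abs(mean(tg$hf_60) - 2.48), se3(0.85))
  expect_lt(abs(mean(tg$delta_hbo_60) - 6.81), se3(4.11))
  expect_lt(abs(mean(tg$vo2_100) - 0.079), se3(0.050))
  expect_lt(abs(sd(tg$hf_60) - 0.85), 0.03)
  # default loading induces positive cross-parameter correlation
  expect_gt(cor(tg$hf_60, tg$delta_hbo_60, method = "spearman"), 0.2)
  # high loading drives it above 0.7
  set.seed(8)
  hi <- sample_feature_targets(1e4, "nonPAD", loading = 0.9)
  expect_gt(cor(hi$hf_60, hi$delta_hbo_60, method = "spearman"), 0.7)
  # degenerate SDs give every subject the group means
  set.seed(9)
  dg <- sample_feature_targets(5, "PAD", sd_scale = 0)
  expect_true(all(dg$hf_60 == 0.86))
  expect_true(all(dg$tp_100 == 17.12))
})

test_that("PAD hemoglobin flow is stochastically lower than non-PAD", {
  set.seed(11)
  a <- sample_feature_targets(2000, "PAD")$hf_60
  b <- sample_feature_targets(2000, "nonPAD")$hf_60
  expect_gt(mean(b > a), 0.5)
})

test_that("printed group-mean targets round-trip through construction", {
  for (g in names(table1_targets)) {
    tr <- construct_trace(table1_targets[[g]], default_protocol)
    fx <- extract_features(tr, default_protocol)
    for (i in 1:2) for (p in c("delta_hbo", "hf", "vo2", "tp")) {
      expect_lt(abs(fx[[p]][i] - table1_targets[[g]][[p]][i]) /
                  table1_targets[[g]][[p]][i], 0.05)
    }
    expect_equal(tr$hbt, tr$hbo + tr$hbd)  # additive identity, every sample
  }
})

test_that("construction round-trips across random draws from both groups", {
  set.seed(13)
  for (g in c("nonPAD", "PAD")) {
    tg <- sample_feature_targets(40, g)
    for (i in seq_len(40)) {
      tr <- construct_trace(tg[i, ], default_protocol)
      fx <- extract_features(tr, default_protocol)
      tgt <- dvos:::targets_long(tg[i, ])
      for (j in 1:2) {
        for (p in c("delta_hbo", "hf", "vo2"))
          expect_lt(abs(fx[[p]][j] - tgt[[p]][j]) / tgt[[p]][j], 0.05)
        # Tp within 2 samples of its target
        expect_lt(abs(fx$tp[j] - tgt$tp[j]), 2 / 2.56)
      }
    }
  }
})

test_that("the steepest constructed interval reproduces the HF rate exactly", {
  tg <- table1_targets$nonPAD
  tr <- construct_trace(tg, default_protocol)
  grid <- interval_slopes(tr$hbt, tr$time_s, 60)
  expect_equal(max(grid), tg$hf[1] / 5, tolerance = 0.02)
})

test_that("degenerate target combinations are rejected as infeasible", {
  flat <- data.frame(pressure = c(60, 100), delta_hbo = 0, hf = 0, vo2 = 0,
                     tp = c(20, 20))
  expect_error(construct_trace(flat, default_protocol), "infeasible")
  neg <- data.frame(pressure = c(60, 100), delta_hbo = c(5, 5),
                    hf = c(-1, 1), vo2 = c(0.05, 0.05), tp = c(20, 20))
  expect_error(construct_trace(neg, default_protocol), "infeasible")
})

test_that("cohort generation is deterministic and calibrated", {
  a <- generate_cohort(n_pad = 4, n_nonpad = 4, seed = 42)
  b <- generate_cohort(n_pad = 4, n_nonpad = 4, seed = 42)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$targets, b$targets)
  expect_identical(a$recordings[[3]]$channels[[5]]$intensity,
                   b$recordings[[3]]$channels[[5]]$intensity)
  # zero-noise cohort: extracted features equal latent targets within 5%
  zc <- generate_cohort(n_pad = 2, n_nonpad = 2, noise = zero_noise,
                        seed = 1)
  for (i in seq_along(zc$traces)) {
    tr <- invert_hemoglobin(zc$recordings[[i]])
    fx <- extract_features(tr, default_protocol)
    tgt <- dvos:::targets_long(zc$targets[i, ])
    for (j in 1:2) for (p in c("delta_hbo", "hf", "vo2"))
      expect_lt(abs(fx[[p]][j] - tgt[[p]][j]) / tgt[[p]][j], 0.05)
  }
})
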