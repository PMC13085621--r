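test_that("delta_hbo subtracts the 5-s pre-occlusion mean from the peak", {
  # pre-occlusion level 10, occlusion maximum 16.81 (held on a plateau so
  # the sampling grid attains it exactly)
  tr <- knot_trace(kn(0, 10, 60, 10, 86, 16.81, 92, 16.81, 119, 10, 300, 10))
  expect_equal(delta_hbo(tr, default_protocol, 60), 6.81, tolerance = 1e-6)
  # flat trace
  flat <- knot_trace(kn(0, 4, 300, 4))
  expect_equal(delta_hbo(flat, default_protocol, 60), 0)
  # monotone linear rise 0 -> A attains its max at occlusion end
  a <- 5.5
  rise <- knot_trace(kn(0, 0, 60, 0, 120, a, 300, a))
  got <- delta_hbo(rise, default_protocol, 60)
  expect_equal(got, a * (119.921875 - 60) / 60, tolerance = 1e-9)
  expect_gt(got, 0.98 * a)
})

test_that("interval slopes are least squares over six half-open windows", {
  times <- protocol_times(default_protocol)
  # exact line of slope b
  g <- interval_slopes(2.2 * times, times, 60)
  expect_equal(as.numeric(g), rep(2.2, 6), tolerance = 1e-9)
  expect_length(g, 6)
  # piecewise: slope 3 for the first 5 s, flat after
  pw <- knot_trace(kn(0, 0, 60, 0, 65, 15, 300, 15))
  g2 <- interval_slopes(pw$hbt, times, 60)
  expect_equal(as.numeric(g2), c(3, 0, 0, 0, 0, 0), tolerance = 1e-9)
  # explicit normal-equations oracle on noisy data
  set.seed(31)
  x <- 1.5 * times + rnorm(length(times))
  g3 <- interval_slopes(x, times, 60)
  for (k in 0:5) {
    idx <- times >= 60 + 5 * k & times < 65 + 5 * k
    expect_equal(g3[k + 1], unname(coef(lm(x[idx] ~ times[idx]))[2]),
                 tolerance = 1e-9)
  }
  # unbiasedness: mean of each interval's estimated slope equals the truth
  est <- vapply(1:100, function(s) {
    set.seed(s)
    as.numeric(interval_slopes(0.4 * times + rnorm(length(times), sd = 0.05),
                               times, 60))
  }, numeric(6))
  expect_equal(rowMeans(est), rep(0.4, 6), tolerance = 0.01)
  expect_error(interval_slopes(1:10, (0:9) / 2.56, 0), "30 s")
})

test_that("hemoglobin flow is the maximum interval slope", {
  # trace whose six interval slopes are the fixture grid
  slopes <- c(0.5, 2.48, 1.0, 0.3, 0.1, 0.0)
  lev <- cumsum(c(0, slopes * 5))
  tr <- knot_trace(kn(0, 0, 60, 0,
                      65, lev[2], 70, lev[3], 75, lev[4], 80, lev[5],
                      85, lev[6], 90, lev[7], 300, lev[7]))
  expect_equal(hemoglobin_flow(tr, default_protocol, 60), 2.48,
               tolerance = 1e-9)
  flat <- knot_trace(kn(0, 1, 300, 1))
  expect_equal(hemoglobin_flow(flat, default_protocol, 60), 0)
  # strictly decreasing HbT: negative flow, not clipped
  dec <- knot_trace(kn(0, 50, 300, 20))
  expect_lt(hemoglobin_flow(dec, default_protocol, 60), 0)
})

test_that("the VO2 conversion factor survives dimensional analysis", {
  # independent derivation: umol/L/s -> mL O2 / 100 mL tissue / min
  o2_umol_per_hb_umol <- 4
  ml_per_mol_o2 <- 22400
  factor <- 1e-6 * o2_umol_per_hb_umol * ml_per_mol_o2 * 60 * (100 / 1000)
  expect_equal(vo2_conversion_factor(), factor)
  expect_equal(factor, 0.5376)
})

test_that("oxygen consumption converts the maximal HbD rise rate", {
  tr0 <- knot_trace(kn(0, 0, 300, 0),
                    kn(0, 0, 60, 0, 72, 1.2, 300, 1.2))  # 0.1 umol/L/s
  expect_equal(oxygen_consumption(tr0, default_protocol, 60), 0.05376,
               tolerance = 1e-9)
  # the Table-1 non-PAD scale: slope 0.1228 -> ~0.066
  tr1 <- knot_trace(kn(0, 0, 300, 0),
                    kn(0, 0, 60, 0, 72, 12 * 0.1228, 300, 1))
  expect_equal(oxygen_consumption(tr1, default_protocol, 60), 0.066,
               tolerance = 0.001)
  flat <- knot_trace(kn(0, 0, 300, 0), kn(0, 0.7, 300, 0.7))
  expect_equal(oxygen_consumption(flat, default_protocol, 60), 0)
})

test_that("plateau time follows the 90%-of-maximum crossings", {
  # rise 0->10 over the occlusion's first 50 s, hold, fall at 0.5 umol/L/s:
  # t1 = 45 s into occlusion, t2 = 2 s after deflation, Tp = 17 s
  tr <- knot_trace(kn(0, 0, 60, 0, 110, 10, 120, 10, 140, 0, 300, 0))
  expect_equal(as.numeric(plateau_time(tr, default_protocol, 60)), 17,
               tolerance = 0.01)
  # instant rise at onset, instant drop at deflation: Tp = occlusion duration
  box <- knot_trace(kn(0, 0, 59.9, 0, 60, 10, 119.9, 10, 120, 0, 300, 0))
  expect_equal(as.numeric(plateau_time(box, default_protocol, 60)), 60,
               tolerance = 1)
  # symmetric triangle peaking at deflation: crossings equidistant from peak
  tri <- knot_trace(kn(0, 0, 60, 0, 120, 10, 180, 0, 300, 0))
  tp <- as.numeric(plateau_time(tri, default_protocol, 60))
  expect_equal(tp, 2 * 0.1 * 60, tolerance = 0.02)
  # never falling below 90% in recovery: truncated and flagged
  stuck <- knot_trace(kn(0, 0, 60, 0, 90, 10, 300, 10))
  tps <- plateau_time(stuck, default_protocol, 60)
  expect_true(attr(tps, "truncated"))
  expect_equal(as.numeric(tps), 180 - 87, tolerance = 0.5)
})

test_that("extract_features handles degenerate traces gracefully", {
  zero <- knot_trace(kn(0, 0, 300, 0))
  fx <- extract_features(zero, default_protocol)
  expect_equal(fx$delta_hbo, c(0, 0))
  expect_equal(fx$hf, c(0, 0))
  expect_equal(fx$vo2, c(0, 0))
  expect_true(attr(plateau_time(zero, default_protocol, 60), "degenerate"))
})

test_that("features are shift invariant (amplitudes) and scale equivariant", {
  tr <- construct_trace(table1_targets$nonPAD, default_protocol)
  fx <- extract_features(tr, default_protocol)
  shifted <- hemo_trace(tr$time_s, hbo = tr$hbo + 3, hbd = tr$hbd + 2)
  fs <- extract_features(shifted, default_protocol)
  for (p in c("delta_hbo", "hf", "vo2"))
    expect_equal(fs[[p]], fx[[p]], tolerance = 1e-9)
  scaled <- hemo_trace(tr$time_s, hbo = 2.5 * tr$hbo, hbd = 2.5 * tr$hbd)
  fc <- extract_features(scaled, default_protocol)
  for (p in c("delta_hbo", "delta_hbt", "hf", "vo2"))
    expect_equal(fc[[p]], 2.5 * fx[[p]], tolerance = 1e-9)
  expect_equal(fc$tp, fx$tp, tolerance = 1e-9)
})

test_that("flow dominates every interval slope; filtering distorts < 2%", {
  tr <- construct_trace(table1_targets$PAD, default_protocol)
  grid <- interval_slopes(tr$hbt, tr$time_s, 60)
  expect_true(all(hemoglobin_flow(tr, default_protocol, 60) >= grid))
  filt <- hemo_trace(tr$time_s,
                     hbo = lowpass_filter(tr$hbo, 2.56),
                     hbd = lowpass_filter(tr$hbd, 2.56))
  f0 <- extract_features(tr, default_protocol)
  f1 <- extract_features(filt, default_protocol)
  for (p in c("delta_hbo", "hf", "vo2", "tp"))
    expect_lt(max(abs(f1[[p]] - f0[[p]]) / f0[[p]]), 0.02)
})
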