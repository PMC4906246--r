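test_that("noise-free Q-V fit gives the 250 mV/e capacitor calibration", {
  d <- make_delta_profile("dor_wt")
  qv <- make_qv_ensemble(compel_spec(d, vm_noise_sd = 0), 0)[[1]]
  fit <- fit_qv(qv)
  expect_equal(fit$slope, 250)          # 1 e <-> 250 mV at C_m = 4 e/V
  expect_equal(fit$slope_min, fit$slope_max)
  expect_equal(fit$capacitance, 4)
})

test_that("perturbing one point grows the secant spread linearly", {
  base <- qv_series(0, -2:2, 250 * (-2:2), rep(0, 5))
  spreads <- vapply(c(1, 2, 4), function(eps) {
    v <- base$vm_mV; v[3] <- v[3] + eps
    f <- fit_qv(qv_series(0, -2:2, v, rep(0, 5)))
    f$slope_max - f$slope_min
  }, numeric(1))
  expect_equal(spreads / spreads[1], c(1, 2, 4))
  # degenerate imbalance ladders are rejected at construction
  expect_error(qv_series(0, c(1, 1, 1), c(1, 2, 3), rep(0, 3)), "distinct")
})

test_that("gating charge: null pair, published plateaus, full translocation", {
  wt <- make_delta_profile("dor_wt")
  qv <- make_qv_ensemble(compel_spec(wt, vm_noise_sd = 0), c(0, 0, 12.5, 15))
  expect_equal(gating_charge(qv[[1]], qv[[2]])$q_g, 0)
  expect_equal(gating_charge(qv[[1]], qv[[3]])$q_g, 0.42)
  expect_equal(gating_charge(qv[[1]], qv[[4]])$q_g, 0.42)

  # synthetic carrier crossing the full field: delta jump 0 -> 1
  full <- delta_profile(c(-1, 0, 10, 12), c(0, 0, 1, 1))
  qvf <- make_qv_ensemble(compel_spec(full, vm_noise_sd = 0), c(0, 12))
  expect_equal(gating_charge(qvf[[1]], qvf[[2]])$q_g, 1.0)
})

test_that("scan -> electrical-distance profile: plateau, additivity, errors", {
  m2 <- make_delta_profile("m2r")
  scan0 <- make_qv_ensemble(compel_spec(m2, vm_noise_sd = 0),
                            seq(0, 15, by = 2.5))
  prof0 <- electrical_distance_profile(scan0, reference_z = 0)
  expect_equal(prof0$delta[length(prof0$delta)], 0.53)
  expect_equal(max(abs(attr(prof0, "additivity_residuals"))), 0)

  # noisy scan recovers the generator plateau within 3x the reported err
  scan <- make_qv_ensemble(
    compel_spec(m2, vm_noise_sd = 10, n_replicates = 50, seed = 7),
    seq(0, 15, by = 2.5))
  prof <- electrical_distance_profile(scan, reference_z = 0)
  last <- length(prof$delta)
  expect_lt(abs(prof$delta[last] - 0.53), 3 * max(prof$err[last], 1e-3))

  expect_error(electrical_distance_profile(rev(scan0)), "sorted")
  expect_error(electrical_distance_profile(scan0, reference_z = 1.23),
               "reference")
})

test_that("carrier equivalence: proton ~ sodium, sign and interval linearity", {
  m2 <- make_delta_profile("m2r")
  q_na <- carrier_equivalence(m2, 1, 0, 15)
  expect_equal(q_na, 0.53)
  expect_equal(round(q_na, 1), 0.5)            # the printed proton value
  expect_equal(carrier_equivalence(m2, 1, 5, 5), 0)
  expect_equal(carrier_equivalence(m2, -1, 0, 15), -0.53)
  expect_error(carrier_equivalence(m2, 1, 0, 99), "domain")
})

test_that("additivity and boundedness hold on noisy ensembles", {
  wt <- make_delta_profile("dor_wt")
  qv <- make_qv_ensemble(
    compel_spec(wt, vm_noise_sd = 10, n_replicates = 50, seed = 3),
    c(0, 5, 15))
  gAC <- gating_charge(qv[[1]], qv[[3]])
  gAB <- gating_charge(qv[[1]], qv[[2]])
  gBC <- gating_charge(qv[[2]], qv[[3]])
  err <- sqrt(gAB$err^2 + gBC$err^2 + gAC$err^2) + 1e-3
  expect_lt(abs(gAC$q_g - gAB$q_g - gBC$q_g), 6 * err)
  for (g in list(gAC, gAB, gBC)) expect_lte(abs(g$q_g), 1)
})

test_that("estimator calibration: 200 seeded ensembles, mean within 1 SE", {
  wt <- make_delta_profile("dor_wt")
  ests <- vapply(seq_len(200), function(s) {
    qv <- make_qv_ensemble(
      compel_spec(wt, vm_noise_sd = 10, n_replicates = 50, seed = 1000 + s),
      c(0, 15))
    e <- gating_charge(qv[[1]], qv[[2]])
    c(e$q_g, e$err)
  }, numeric(2))
  q <- ests[1, ]; errs <- ests[2, ]
  expect_lt(abs(mean(q) - 0.42), stats::sd(q) / sqrt(200))
  # reported max/min-slope err tracks the empirical SD within factor 2
  expect_lt(stats::median(errs) / stats::sd(q), 4)
  expect_gt(stats::median(errs) / stats::sd(q), 1 / 4)
  expect_true(all(abs(q) <= 1))
})

test_that("inconsistent capacitance between series raises a warning", {
  a <- qv_series(0, -2:2, 250 * (-2:2), rep(0, 5))
  b <- qv_series(10, -2:2, 320 * (-2:2) - 50, rep(0, 5))
  expect_warning(gating_charge(a, b), "capacitance")
})
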