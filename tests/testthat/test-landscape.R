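wt_pmf <- make_reference_pmf("dor_wt")
wt_delta <- make_delta_profile("dor_wt")

test_that("zero voltage reproduces the base PMF; tilting is linear", {
  t0 <- tilt_pmf(wt_pmf, wt_delta, 0)
  expect_equal(t0$G, wt_pmf$G, tolerance = 1e-12)

  t250 <- tilt_pmf(wt_pmf, wt_delta, 250)
  t500 <- tilt_pmf(wt_pmf, wt_delta, 500)
  t750 <- tilt_pmf(wt_pmf, wt_delta, 750)
  expect_equal(t250$G + t500$G - wt_pmf$G, t750$G, tolerance = 1e-9)
})

test_that("1000 mV depolarization makes the transient site the global minimum", {
  t1000 <- tilt_pmf(wt_pmf, wt_delta, 1000)
  g_transient <- min(t1000$G[t1000$z > 5 & t1000$z < 11])
  g_allosteric <- t1000$G[which.min(abs(t1000$z))]
  expect_lt(g_transient, g_allosteric)
  # and the equilibrium profile has it the other way round
  expect_gt(pmf_eval(wt_pmf, 7), pmf_eval(wt_pmf, 0))
})

test_that("hyperpolarization lowers the inward (delta < 0) region", {
  thyp <- tilt_pmf(wt_pmf, wt_delta, -500)
  sel <- thyp$z > -3 & thyp$z < -1    # delta dips to -0.03 around z = -2
  expect_lt(min(thyp$G[sel] - thyp$base_G[sel]), 0)
})

test_that("equalization voltage matches the closed form and a brute-force scan", {
  # dG = 11, delta = 0.30 at the transient well => 11/(F*0.30) = 380 mV
  expect_equal(equalization_voltage(wt_pmf, wt_delta, 0, 7),
               1000 * 11 / (vs_constants$faraday * 0.30), tolerance = 1e-3)

  m2_pmf <- make_reference_pmf("m2r"); m2_delta <- make_delta_profile("m2r")
  v_star <- suppressWarnings(equalization_voltage(m2_pmf, m2_delta, 0, 7.5))
  # brute-force oracle: scan tilt_pmf for the voltage levelling the two
  # fixed state positions (the minima themselves wander under tilt, so
  # the comparison is at the states the closed form uses)
  i_a <- which.min(abs(m2_pmf$z)); i_b <- which.min(abs(m2_pmf$z - 7.5))
  scan <- seq(100, 2000, by = 1)
  gap <- vapply(scan, function(v) {
    tl <- tilt_pmf(m2_pmf, m2_delta, v)
    tl$G[i_b] - tl$G[i_a]
  }, numeric(1))
  v_scan <- scan[which.min(abs(gap))]
  expect_equal(v_star, v_scan, tolerance = 0.01)

  out <- equalization_voltage(wt_pmf, wt_delta, 3, 3)
  expect_true(is.na(out))
  expect_match(attr(out, "reason"), "degenerate")
  # equal electrical distance -> undefined
  flatd <- delta_profile(c(-6, 0, 15), c(0.2, 0.2, 0.2))
  expect_true(is.na(suppressWarnings(
    equalization_voltage(wt_pmf, flatd, -1.6, 0))))
})

test_that("kinetic traps: monotone in threshold, WT > mutant at 500 mV", {
  mono <- pmf_curve(seq(0, 10, 0.1), seq(20, 0, length.out = 101))
  expect_identical(kinetic_traps(mono, 2)$count, 0L)

  mut_t <- tilt_pmf(make_reference_pmf("dor_n131v"),
                    make_delta_profile("dor_n131v"), 500)
  wt_t <- tilt_pmf(wt_pmf, wt_delta, 500)
  path <- c(-3, 12.5)
  n_wt <- kinetic_traps(wt_t, 2, path)$count
  n_mut <- kinetic_traps(mut_t, 2, path)$count
  expect_gt(n_wt, n_mut)

  expect_identical(kinetic_traps(wt_t, 1e6, path)$count, 0L)
  counts <- vapply(c(0.5, 2, 5, 20), function(th)
    kinetic_traps(wt_t, th, path)$count, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("MFPT: flat-landscape closed form and voltage monotonicity", {
  flat <- pmf_curve(c(-20, 20), c(0, 0), fun = function(z) rep(0, length(z)))
  D <- 0.05
  L <- 6; ell <- 2   # travel and reflecting offset
  expect_equal(mean_first_passage_time(flat, D, z_start = 0, z_absorb = L,
                                       z_reflect = -ell),
               (L^2 / 2 + L * ell) / D, tolerance = 1e-4)

  times <- vapply(c(0, 250, 500, 750, 1000), function(v)
    mean_first_passage_time(tilt_pmf(wt_pmf, wt_delta, v), D,
                            z_start = 0, z_absorb = 12.5, z_reflect = -4),
    numeric(1))
  expect_true(all(diff(times) < 0))   # depolarization accelerates escape

  # mutant transits faster than WT at 500 mV (fewer/shallower traps)
  mut_t <- tilt_pmf(make_reference_pmf("dor_n131v"),
                    make_delta_profile("dor_n131v"), 500)
  wt_t <- tilt_pmf(wt_pmf, wt_delta, 500)
  expect_lt(mean_first_passage_time(mut_t, D, 0, 12.5, -4),
            mean_first_passage_time(wt_t, D, 0, 12.5, -4))
})

test_that("MFPT quadrature matches simulated Langevin escape within 20%", {
  # moderate barrier (~8 kJ/mol) so 200 escapes stay fast
  well <- pmf_curve(seq(-3, 5, 0.05),
                    8 * exp(-((seq(-3, 5, 0.05) - 1.5)^2) / 0.8) +
                      2 * (seq(-3, 5, 0.05))^2 * (seq(-3, 5, 0.05) < 0))
  th <- mean_first_passage_time(well, D = 0.05, z_start = 0,
                                z_absorb = 4, z_reflect = -2)
  set.seed(17)
  sims <- vapply(seq_len(200), function(i)
    langevin_first_passage(well, z_start = 0, z_absorb = 4, z_reflect = -2,
                           dt = 0.01, D = 0.05, max_steps = 5e6),
    numeric(1))
  expect_true(all(is.finite(sims)))
  expect_equal(mean(sims), th, tolerance = 0.2)
})
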