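test_that("state assignment: constant, square wave, spike debouncing", {
  st <- assign_states(trajectory1d(rep(0, 500), dt = 1), min_dwell = 10)
  expect_true(all(st$states == "allosteric"))

  sq <- rep(rep(c(0, 9), each = 250), 4)
  st2 <- assign_states(trajectory1d(sq, dt = 1), min_dwell = 50)
  r <- rle(as.character(st2$states))
  expect_equal(unique(r$values), c("allosteric", "transient"))
  expect_equal(length(r$lengths), 8)

  spike <- rep(0, 400); spike[200] <- 9
  st3 <- assign_states(trajectory1d(spike, dt = 1), min_dwell = 5)
  expect_true(all(st3$states == "allosteric"))

  expect_error(assign_states(trajectory1d(rep(0, 10), dt = 1),
                             boundaries = numeric(0)), "boundaries")
})

test_that("debouncing is idempotent and events shrink with min_dwell", {
  set.seed(8)
  z <- cumsum(rnorm(4000, sd = 0.6)) / 3 + 2   # wandering trace
  for (md in c(1, 20, 100)) {
    st <- assign_states(trajectory1d(z, dt = 1), min_dwell = md)
    # re-labelling the already-debounced labels changes nothing
    idx <- as.integer(st$states)
    expect_identical(voltsense:::.debounce(idx, md), idx)
  }
  ev_counts <- vapply(c(1, 10, 50, 200), function(md)
    nrow(detect_transitions(assign_states(trajectory1d(z, dt = 1),
                                          min_dwell = md))), integer(1))
  expect_true(all(diff(ev_counts) <= 0))
})

test_that("transition detection: fixtures and voltage annotation", {
  st <- assign_states(trajectory1d(rep(0, 300), dt = 1), min_dwell = 10)
  expect_identical(nrow(detect_transitions(st)), 0L)

  z <- c(rep(0, 500), rep(9, 500))
  st2 <- assign_states(trajectory1d(z, dt = 0.5), min_dwell = 50)
  ev <- detect_transitions(st2, vm_series = rep(750, 1000))
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$time_frame, 501L)
  expect_equal(ev$from_state, "allosteric")
  expect_equal(ev$to_state, "transient")
  expect_equal(ev$vm_mV, 750)

  expect_error(detect_transitions(st2, vm_series = rep(0, 10)), "mismatch")
})

test_that("voltage-driven expulsion: events at 1000 mV, none at 0 mV", {
  pmf <- make_reference_pmf("dor_wt")
  d <- make_delta_profile("dor_wt")
  run <- function(vm) {
    tr <- langevin_trajectory(pmf, n_steps = 2e5, dt = 0.02, seed = 3,
                              z_init = 0, stride = 5, metropolis = FALSE,
                              voltage = if (vm > 0) list(vm_mV = vm, delta = d))
    detect_transitions(assign_states(tr, min_dwell = 100))
  }
  ev_hot <- run(1000)
  expect_gte(sum(ev_hot$to_state == "transient"), 1)
  ev_cold <- run(0)
  expect_identical(sum(ev_cold$to_state %in% c("transient", "bulk")), 0L)
})

test_that("transition statistics aggregate replicates and track MFPT", {
  ev1 <- data.frame(time = 1, from_state = "allosteric",
                    to_state = "transient")
  stats_all <- transition_statistics(list(ev1, ev1, ev1))
  expect_equal(stats_all$fraction_transitioned, 1)
  expect_equal(stats_all$median_time, 1)
  expect_equal(stats_all$iqr_time, 0)

  # empirical median of simulated escapes vs MFPT on a small barrier
  zg <- seq(-2, 4, 0.05)
  well <- pmf_curve(zg, 6 * exp(-(zg - 1.5)^2 / 0.8) + 2 * zg^2 * (zg < 0))
  th <- mean_first_passage_time(well, D = 0.05, 0, 3.5, -1.5)
  set.seed(21)
  sims <- vapply(seq_len(150), function(i)
    langevin_first_passage(well, 0, 3.5, -1.5, dt = 0.01, D = 0.05,
                           max_steps = 2e6), numeric(1))
  # median of an exponential-ish passage-time distribution ~ log(2)*mean
  expect_equal(stats::median(sims) / log(2), th, tolerance = 0.3)
})

test_that("transition fraction is monotone in voltage for both receptor forms", {
  horizon_steps <- 3e5
  frac <- function(profile, vm, n = 25) {
    pmf <- make_reference_pmf(profile); d <- make_delta_profile(profile)
    mean(vapply(seq_len(n), function(i) {
      set.seed(1e4 + 37 * i + vm)
      t <- langevin_first_passage(pmf, z_start = 0, z_absorb = 11,
                                  z_reflect = -4, dt = 0.02, D = 0.05,
                                  voltage = if (vm > 0)
                                    list(vm_mV = vm, delta = d),
                                  max_steps = horizon_steps)
      is.finite(t)
    }, logical(1)))
  }
  for (profile in c("dor_wt", "dor_n131v")) {
    fr <- vapply(c(0, 250, 500, 750, 1000), function(v) frac(profile, v),
                 numeric(1))
    # non-decreasing within binomial error at n = 25 per level
    expect_true(all(diff(fr) >= -2 * sqrt(0.25 / 25)),
                label = paste(profile, paste(round(fr, 2), collapse = " ")))
  }
  # the mutant transits at lower voltage than WT
  expect_gte(frac("dor_n131v", 500), frac("dor_wt", 500))
})
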