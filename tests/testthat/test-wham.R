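# Small dor_wt umbrella experiment reused by several tests (reduced
# scale relative to the acceptance run to keep the suite fast).
small_dorwt_windows <- local({
  pmf <- make_reference_pmf("dor_wt")
  suppressWarnings(make_umbrella_windows(
    pmf, seq(-3.5, 10, by = 0.5), kappa = 400,
    steps_per_window = 1e5, stride = 2,
    equilibration_steps = 2000, seed = 101))
})

test_that("windows sampled exactly from Gaussians recover a quadratic PMF", {
  a <- 2.5   # curvature, kJ/mol/A^2
  win <- gaussian_windows_quadratic(a, centers = seq(-2, 2, 0.25),
                                    kappa = 120, n = 4e4, seed = 21)
  curve <- wham(win, bin_width = 0.1)
  sel <- abs(curve$z) <= 1.8
  truth <- 0.5 * a * curve$z[sel]^2
  expect_lt(max(abs(curve$G[sel] - (truth - min(truth)))), 0.5)
})

test_that("a single unbiased window on a flat potential yields a flat PMF", {
  set.seed(9)
  win <- list(list(center = 0, kappa = 0, temperature = 310,
                   samples = stats::runif(2e5, -2, 2)))
  expect_warning(wham(list(list(center = 0, kappa = 0, temperature = 310,
                                samples = stats::runif(500, -1, 1))),
                      bin_width = 0.5), "bin_width")
  curve <- suppressWarnings(wham(win, bin_width = 0.5))
  inner <- curve$G[curve$z > -1.9 & curve$z < 1.9]
  expect_gte(length(inner), 6)
  # multinomial SD of -kT log p at these counts is ~0.012 kJ/mol
  expect_lt(max(inner) - min(inner), 3 * 0.012 * 3)
})

test_that("package WHAM agrees with an independent MLE oracle (< 0.2 kJ/mol)", {
  # identical binned likelihood (refine = 0), two independent solution
  # routes: Anderson-accelerated self-consistency vs BFGS on the
  # convex MLE objective, with separately coded bias weights
  cases <- list(
    quad = gaussian_windows_quadratic(2.5, seq(-2, 2, 0.25), 120, 5e3, seed = 3),
    dorwt = small_dorwt_windows$windows,
    m2r = suppressWarnings(make_umbrella_windows(
      make_reference_pmf("m2r"), seq(-2, 10, by = 0.4), kappa = 600,
      steps_per_window = 1e4, equilibration_steps = 1000, seed = 33))$windows)
  for (nm in names(cases)) {
    curve <- wham(cases[[nm]], bin_width = 0.25, refine = 0)
    orc <- oracle_wham_mle(cases[[nm]], bin_width = 0.25)
    shared <- match(round(curve$z, 6), round(orc$z, 6))
    diffs <- abs(curve$G - orc$G[shared])
    expect_lt(max(diffs, na.rm = TRUE), 0.2, label = nm)
  }
})

test_that("WHAM output is invariant under window reordering", {
  win <- small_dorwt_windows$windows
  a <- wham(win, bin_width = 0.25)
  set.seed(4)
  b <- wham(win[sample(length(win))], bin_width = 0.25)
  expect_equal(a$z, b$z)
  # invariance holds to the amplified solver tolerance (the adaptive
  # refinement replays an order-independent but tolerance-limited path)
  expect_lt(max(abs(a$G - b$G)), 0.01)
})

test_that("reduced-scale dor_wt recovery reproduces the printed barriers", {
  curve <- wham(small_dorwt_windows, bin_width = 0.25)
  ba <- barrier_analysis(curve)
  st <- ba$states
  expect_setequal(c("deep", "allosteric", "transient"),
                  intersect(st$label, c("deep", "allosteric", "transient")))
  main <- ba$barriers$barrier[ba$barriers$from == "allosteric" &
                              ba$barriers$to == "transient"]
  expect_lt(abs(main - 13.0), 2.5)
  inter <- ba$barriers$barrier[ba$barriers$from == "allosteric" &
                               ba$barriers$to == "deep"]
  expect_lt(abs(inter - 5.3), 2.5)
  expect_lt(abs(st$G[st$label == "transient"] -
                st$G[st$label == "allosteric"] - 11.0), 2.5)
})

test_that("non-overlapping window sets fail naming the gap", {
  pmf <- make_reference_pmf("dor_wt")
  win <- suppressWarnings(make_umbrella_windows(
    pmf, c(-2, -1.5, -1, 4, 4.5, 5), kappa = 400,
    steps_per_window = 2000, equilibration_steps = 200, seed = 5))
  expect_error(wham(win), "non-overlapping")
})

test_that("bootstrap: deterministic duplicated samples give ~zero SD", {
  base <- seq(-1, 1, length.out = 2e4)
  win <- lapply(c(-0.5, 0, 0.5), function(c0)
    list(center = c0, kappa = 10, temperature = 310,
         samples = base))
  curve <- bootstrap_pmf(win, bin_width = 0.25, n_boot = 30, seed = 2)
  # no sampling variability: SD is pure Dirichlet-weight noise,
  # ~ kT/sqrt(samples per bin) plus anchoring correlation ~ 0.08
  expect_lt(stats::median(curve$sd, na.rm = TRUE), 0.12)
})

test_that("bootstrap SD shrinks with sample size and is < 2.5 kJ/mol at scale", {
  pmf <- make_reference_pmf("dor_wt")
  mk <- function(n, seed) suppressWarnings(make_umbrella_windows(
    pmf, seq(-2, 4, by = 0.5), kappa = 400, steps_per_window = n,
    equilibration_steps = 500, seed = seed))
  small <- bootstrap_pmf(mk(4000, 7), bin_width = 0.25, n_boot = 40, seed = 1)
  large <- bootstrap_pmf(mk(16000, 7), bin_width = 0.25, n_boot = 40, seed = 1)
  expect_lt(stats::median(large$sd), stats::median(small$sd))
  expect_lt(mean(small$sd[small$n_eff > 100]), 2.5)
  expect_error(bootstrap_pmf(mk(2000, 1), n_boot = 1), "n_boot")
})

test_that("barrier analysis handles analytic, monotone, and m2r curves", {
  wt <- barrier_analysis(make_reference_pmf("dor_wt", dz = 0.1),
                         smooth = FALSE)
  expect_equal(wt$states$z[wt$states$label == "allosteric"], 0, tolerance = 0.1)
  expect_equal(
    wt$barriers$barrier[wt$barriers$from == "allosteric" &
                        wt$barriers$to == "transient"], 13.0)

  mono <- pmf_curve(seq(0, 5, 0.1), seq(0, 10, length.out = 51))
  bm <- barrier_analysis(mono, smooth = FALSE)
  expect_identical(sum(bm$extrema$type == "min" &
                       bm$extrema$z > 0), 0L)   # no internal minima

  m2 <- barrier_analysis(make_reference_pmf("m2r", dz = 0.1), smooth = FALSE)
  expect_equal(
    m2$barriers$barrier[m2$barriers$from == "allosteric" &
                        m2$barriers$to == "transient"], 26.0)

  expect_error(barrier_analysis(pmf_curve(1:4, c(1, 0, 1, 2))), "fewer")
})
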