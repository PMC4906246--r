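# Independent oracles used to cross-check the pipeline.

# Binned maximum-likelihood solution of the umbrella-unbiasing problem,
# solved by BFGS minimization of the convex MBAR-style objective
#   kappa(g) = sum_b n_b log sum_k N_k exp(g_k - w_kb/kT) - sum_k N_k g_k
# rather than by the package's fixed-point WHAM iteration. Returns G on
# the same bin grid as wham() for direct comparison.
oracle_wham_mle <- function(windows, bin_width = 0.25,
                            temperature = voltsense::vs_constants$temperature) {
  win <- if (inherits(windows, "umbrella_set")) windows$windows else windows
  kT <- voltsense::thermal_energy(temperature)
  allz <- unlist(lapply(win, `[[`, "samples"))
  edges <- seq(floor(min(allz) / bin_width) * bin_width,
               max(allz) + bin_width, by = bin_width)
  centers <- edges[-length(edges)] + bin_width / 2
  B <- length(centers); K <- length(win)
  counts <- vapply(win, function(w)
    tabulate(findInterval(w$samples, edges, rightmost.closed = TRUE),
             nbins = B), numeric(B))
  nb <- rowSums(counts); Nk <- colSums(counts)
  # reduced bias from the bin-averaged harmonic Boltzmann factor
  # (analytic normal-CDF integral), matching the binned likelihood
  u <- vapply(seq_len(K), function(k) {
    kap <- win[[k]]$kappa; c0 <- win[[k]]$center
    if (kap <= 0) return(numeric(B))
    s <- sqrt(kT / kap)
    w <- sqrt(2 * pi) * s *
      (stats::pnorm((centers + bin_width / 2 - c0) / s) -
       stats::pnorm((centers - bin_width / 2 - c0) / s)) / bin_width
    -log(w)
  }, numeric(B))
  obj <- function(g) {
    lse <- log(as.numeric(exp(sweep(-u, 2, g + log(Nk), "+")) %*%
                            rep(1, K)))
    sum(nb * lse) - sum(Nk * g)
  }
  grad <- function(g) {
    M <- exp(sweep(-u, 2, g + log(Nk), "+"))   # B x K
    D <- rowSums(M)
    colSums(nb * M / D) - Nk
  }
  g <- numeric(K)
  fit <- stats::optim(g, obj, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  M <- exp(sweep(-u, 2, fit$par + log(Nk), "+"))
  p <- nb / rowSums(M)
  p[nb == 0] <- NA
  G <- -kT * log(p / sum(p, na.rm = TRUE))
  list(z = centers, G = G - min(G, na.rm = TRUE))
}

# Kolmogorov-Smirnov distance between sampled positions and the
# Boltzmann density exp(-G/kT) restricted to [lo, hi].
oracle_boltzmann_ks <- function(samples, potential, lo, hi,
                                temperature = voltsense::vs_constants$temperature) {
  kT <- voltsense::thermal_energy(temperature)
  zg <- seq(lo, hi, length.out = 4000)
  dens <- exp(-voltsense::pmf_eval(potential, zg) / kT)
  cdf <- cumsum(dens); cdf <- (cdf - cdf[1]) / (cdf[length(cdf)] - cdf[1])
  theo <- stats::approx(zg, cdf, xout = sort(samples), rule = 2)$y
  emp <- seq_along(theo) / length(theo)
  max(abs(emp - theo), abs(emp - 1 / length(theo) - theo))
}

# Exactly-distributed umbrella windows on a quadratic potential
# G(z) = 0.5 * a * z^2: the biased density of window (c, kappa) is
# normal with precision (a + kappa)/kT and mean kappa*c/(a + kappa).
gaussian_windows_quadratic <- function(a, centers, kappa, n,
                                       temperature = voltsense::vs_constants$temperature,
                                       seed = 42) {
  kT <- voltsense::thermal_energy(temperature)
  set.seed(seed)
  lapply(centers, function(c0)
    list(center = c0, kappa = kappa, temperature = temperature,
         samples = stats::rnorm(n, mean = kappa * c0 / (a + kappa),
                                sd = sqrt(kT / (a + kappa)))))
}
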