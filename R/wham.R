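#' Weighted-histogram analysis of umbrella-sampling windows
#'
#' Reconstructs the unbiased free-energy profile G(z) from harmonic
#' umbrella windows by the standard WHAM self-consistency equations:
#' \deqn{p_b = \frac{\sum_k n_{kb}}{\sum_k N_k\,e^{(f_k - w_k(z_b))/kT}},
#'       \qquad
#'       f_k = -kT \ln \sum_b p_b\, e^{-w_k(z_b)/kT},}
#' iterated from f = 0 until the largest change in any f_k is below
#' `tol`, then \eqn{G = -kT \ln p} anchored so the populated minimum
#' is 0. Bins never visited by any window are returned as NA and
#' flagged, not interpolated.
#'
#' @param windows an `umbrella_set` from [make_umbrella_windows], or a
#'   plain list of list(center, kappa, temperature, samples).
#' @param bin_width histogram bin width, Angstrom. The protocol
#'   constraint is < 0.5 A; larger values are allowed with a warning.
#' @param tol convergence tolerance on the window free energies,
#'   kJ/mol (default 1e-8).
#' @param max_iter iteration cap; non-convergence is an error
#'   reporting the residual.
#' @param f_init optional warm-start window free energies (used by the
#'   bootstrap).
#' @param refine number of adaptive within-bin density refinements of
#'   the bias weights after the first converged solve (default 3; 0
#'   reproduces plain binned WHAM with bin-averaged bias factors).
#'   Needed for accuracy when kappa * bin_width^2 is several kT.
#' @return a [pmf_curve] on the bin centers with `n_eff` = total
#'   samples per bin; attribute `"f"` carries the converged window
#'   free energies, attribute `"iterations"` the count.
#' @export
wham <- function(windows, bin_width = 0.25, tol = 1e-8, max_iter = 1e5,
                 f_init = NULL, refine = 3L) {
  win <- if (inherits(windows, "umbrella_set")) windows$windows else windows
  stopifnot(length(win) >= 1)
  if (bin_width >= 0.5)
    warning("bin_width >= 0.5 A exceeds the protocol constraint", call. = FALSE)
  temperature <- win[[1]]$temperature %||% vs_constants$temperature
  kT <- thermal_energy(temperature)

  allz <- unlist(lapply(win, `[[`, "samples"))
  edges <- seq(floor(min(allz) / bin_width) * bin_width,
               max(allz) + bin_width, by = bin_width)
  centers <- edges[-length(edges)] + bin_width / 2
  B <- length(centers); K <- length(win)

  counts <- vapply(win, function(w) {
    idx <- findInterval(w$samples, edges, rightmost.closed = TRUE)
    tabulate(idx, nbins = B)
  }, numeric(B))                       # B x K
  nb <- rowSums(counts)
  Nk <- colSums(counts)

  # detect sampling gaps: interior bins between populated ones with no
  # samples at all make the profile disconnected
  pop <- which(nb > 0)
  if (length(pop) >= 2) {
    gap <- setdiff(seq(min(pop), max(pop)), pop)
    if (length(gap) > 2 / bin_width)  # more than ~2 A of dead space
      stop(sprintf(
        "non-overlapping windows: no samples in [%.2f, %.2f] A",
        centers[min(gap)], centers[max(gap)]))
  }

  g0 <- if (is.null(f_init)) numeric(K) else as.numeric(f_init) / kT
  fit <- .wham_engine(nb, Nk, centers, bin_width, win, kT,
                      tol / kT, max_iter, g0, refine = refine)
  if (!fit$converged)
    stop(sprintf("WHAM did not converge in %d iterations (residual %.3g kJ/mol)",
                 as.integer(max_iter), fit$residual * kT))
  g <- fit$g; iter <- fit$iter
  p <- fit$p
  p[nb == 0] <- NA_real_
  p <- p / sum(p, na.rm = TRUE)
  G <- -kT * log(p)
  G <- G - min(G, na.rm = TRUE)
  keep <- !is.na(G)
  curve <- pmf_curve(centers[keep], G[keep],
                     n_eff = nb[keep], temperature = temperature,
                     anchor = TRUE)
  attr(curve, "f") <- g * kT
  attr(curve, "iterations") <- iter
  attr(curve, "flagged_empty_bins") <- centers[!keep]
  curve
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Bin-averaged Boltzmann factors of the harmonic biases,
#   c_kb = (1/dz) int_bin rho_hat(z)/rho_hat(z_b) exp(-w_k(z)/kT) dz.
# With stiff springs (kappa*dz^2 >> kT) the bias varies by many kT
# across one bin, so the common bin-center approximation
# exp(-w(z_b)/kT) breaks the estimator. The first pass uses the
# analytic normal-CDF average of exp(-w/kT) (rho_hat constant); later
# passes refine with the current PMF estimate interpolated within the
# bin (rho_hat = exp(-G_hat/kT)), evaluated on a sub-grid. Two or
# three such refinements reach near-binless accuracy.
.bias_weights <- function(centers, bin_width, win, kT, G_hat = NULL,
                          n_sub = 10) {
  B <- length(centers)
  if (is.null(G_hat)) {
    return(vapply(seq_along(win), function(k) {
      kap <- win[[k]]$kappa; c0 <- win[[k]]$center
      if (kap <= 0) return(rep(1, B))
      s <- sqrt(kT / kap)
      lo <- centers - bin_width / 2; hi <- centers + bin_width / 2
      sqrt(2 * pi) * s *
        (stats::pnorm((hi - c0) / s) - stats::pnorm((lo - c0) / s)) / bin_width
    }, numeric(B)))
  }
  # sub-grid points within each bin (B x S)
  off <- (seq_len(n_sub) - 0.5) / n_sub - 0.5
  Zs <- outer(centers, off * bin_width, "+")
  ok <- is.finite(G_hat)
  Gs <- matrix(stats::approx(centers[ok], G_hat[ok], xout = as.numeric(Zs),
                             rule = 2)$y, nrow = B)
  rhofac <- exp(-(Gs - ifelse(ok, G_hat, 0)) / kT)   # rho_hat(z)/rho_hat(z_b)
  vapply(seq_along(win), function(k) {
    kap <- win[[k]]$kappa; c0 <- win[[k]]$center
    w <- if (kap > 0) exp(-0.5 * kap * (Zs - c0)^2 / kT) else matrix(1, B, n_sub)
    rowMeans(rhofac * w)
  }, numeric(B))
}

# Full WHAM fit: self-consistent solve, then adaptive refinement of
# the within-bin density model (see .bias_weights), re-solving after
# each weight update with a warm start.
.wham_engine <- function(nb, Nk, centers, bin_width, win, kT,
                         tol, max_iter, g_init, refine = 3L) {
  expw <- .bias_weights(centers, bin_width, win, kT)
  sol <- .wham_solve(nb, Nk, expw, g_init, tol, max_iter)
  for (r in seq_len(refine)) {
    if (!sol$converged) break
    denom <- as.numeric(expw %*% (Nk * exp(sol$g)))
    p <- ifelse(denom > 0, nb / denom, 0)
    G_hat <- -kT * log(p)
    G_hat[nb == 0] <- NA_real_
    expw <- .bias_weights(centers, bin_width, win, kT, G_hat = G_hat)
    sol <- .wham_solve(nb, Nk, expw, sol$g, tol, max_iter)
  }
  denom <- as.numeric(expw %*% (Nk * exp(sol$g)))
  sol$p <- ifelse(denom > 0, nb / denom, 0)
  sol
}

# Self-consistent WHAM iteration in reduced units (g = f/kT), with
# Anderson acceleration (depth 5): the plain fixed-point map converges
# geometrically with a ratio approaching 1 when adjacent windows
# overlap only through histogram tails, so the iteration is
# extrapolated against its recent residual history. Convergence is
# always certified on the plain fixed-point residual max|F(g) - g|.
.wham_solve <- function(nb, Nk, expw, g, tol, max_iter, depth = 5L) {
  Fmap <- function(g) {
    denom <- as.numeric(expw %*% (Nk * exp(g)))
    p <- ifelse(denom > 0, nb / denom, 0)
    gn <- -log(as.numeric(crossprod(expw, p)))
    gn - gn[1]
  }
  K <- length(g)
  Gh <- Rh <- matrix(0, K, 0)          # g and residual history
  iter <- 0L; delta <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    fg <- Fmap(g)
    r <- fg - g
    delta <- max(abs(r))
    if (delta < tol)
      return(list(g = fg, iter = iter, converged = TRUE, residual = delta))
    Gh <- cbind(Gh, fg); Rh <- cbind(Rh, r)
    if (ncol(Gh) > depth + 1L) { Gh <- Gh[, -1, drop = FALSE]
                                 Rh <- Rh[, -1, drop = FALSE] }
    m <- ncol(Rh)
    if (m >= 2) {
      dR <- Rh[, -1, drop = FALSE] - Rh[, -m, drop = FALSE]
      dG <- Gh[, -1, drop = FALSE] - Gh[, -m, drop = FALSE]
      gamma <- tryCatch(qr.solve(dR, r, tol = 1e-12),
                        error = function(e) NULL)
      cand <- if (!is.null(gamma)) fg - dG %*% gamma else NULL
      if (!is.null(cand) && all(is.finite(cand))) {
        g <- as.numeric(cand) ; g <- g - g[1]
        next
      }
    }
    g <- fg
  }
  list(g = g, iter = iter, converged = FALSE, residual = delta)
}

#' Bayesian-bootstrap SD of a WHAM profile
#'
#' Each bootstrap replicate reweights every window's samples with
#' normalized Dirichlet(1,...,1) weights (continuous Bayesian
#' bootstrap rather than integer resampling), reruns WHAM on the
#' weighted histograms (warm-started from the full-data solution),
#' anchors each replicate at the full-data reference bin, and reports
#' the per-bin SD across replicates. The published protocol used 200
#' runs.
#'
#' @inheritParams wham
#' @param n_boot number of bootstrap replicates (>= 2; default 200).
#' @param seed RNG seed for the Dirichlet draws.
#' @return the full-data [pmf_curve] with its `sd` field filled in.
#' @export
bootstrap_pmf <- function(windows, bin_width = 0.25, n_boot = 200,
                          seed = 1, tol = 1e-8, max_iter = 1e5) {
  if (n_boot < 2) stop("n_boot must be >= 2")
  win <- if (inherits(windows, "umbrella_set")) windows$windows else windows
  full <- wham(win, bin_width = bin_width, tol = tol, max_iter = max_iter)
  f0 <- attr(full, "f")
  ref_bin <- which.min(full$G)
  edges <- c(full$z - bin_width / 2, full$z[length(full$z)] + bin_width / 2)
  # precompute each sample's bin once
  idx <- lapply(win, function(w)
    findInterval(w$samples, edges, rightmost.closed = TRUE))
  set.seed(as.integer(seed))
  B <- length(full$z)
  boot <- matrix(NA_real_, nrow = B, ncol = n_boot)
  for (r in seq_len(n_boot)) {
    wboot <- lapply(seq_along(win), function(k) {
      w <- win[[k]]
      n <- length(w$samples)
      wt <- stats::rexp(n)
      wt <- wt / sum(wt) * n          # Dirichlet(1,..,1) scaled to N_k
      cnt <- numeric(B)
      ok <- idx[[k]] >= 1 & idx[[k]] <= B
      agg <- rowsum(wt[ok], idx[[k]][ok])
      cnt[as.integer(rownames(agg))] <- agg[, 1]
      list(center = w$center, kappa = w$kappa,
           temperature = w$temperature, counts = cnt)
    })
    cv <- .wham_weighted(wboot, full$z, bin_width, tol, max_iter, f0)
    boot[, r] <- cv - cv[ref_bin]
  }
  full$sd <- apply(boot, 1, stats::sd, na.rm = TRUE)
  full
}

# WHAM on precomputed (possibly weighted) histogram counts over a fixed
# bin grid; returns G on that grid (NA where unpopulated), un-anchored
# except G[1st populated] finite.
.wham_weighted <- function(wins, centers, bin_width, tol, max_iter, f_init) {
  temperature <- wins[[1]]$temperature %||% vs_constants$temperature
  kT <- thermal_energy(temperature)
  B <- length(centers); K <- length(wins)
  counts <- vapply(wins, `[[`, numeric(B), "counts")
  nb <- rowSums(counts); Nk <- colSums(counts)
  sol <- .wham_engine(nb, Nk, centers, bin_width, wins, kT,
                      tol / kT, max_iter, as.numeric(f_init) / kT,
                      refine = 2L)
  if (!sol$converged) stop("bootstrap WHAM replicate did not converge")
  p <- sol$p
  p[nb == 0] <- NA_real_
  -kT * log(p / sum(p, na.rm = TRUE))
}

#' Extrema and barrier table of a free-energy profile
#'
#' Locates local minima and maxima of the profile (after optional
#' 3-bin smoothing and persistence pruning of wiggles smaller than
#' `prune` kJ/mol), labels minima by the nearest reference binding
#' site, and tabulates forward barriers between every ordered pair of
#' labeled states: barrier(A -> B) = max G on the path between them
#' minus G(A).
#'
#' @param curve a [pmf_curve] with >= 5 points.
#' @param smooth logical, apply a 3-bin moving average before
#'   locating extrema (default TRUE; appropriate for bootstrap-noisy
#'   reconstructions, harmless for analytic curves on fine grids).
#'   Reported free energies and barriers always come from the raw
#'   curve - smoothing only steers where extrema are looked up, so
#'   sharp barrier tops are not flattened.
#' @param prune persistence threshold (kJ/mol): adjacent
#'   minimum/maximum pairs whose amplitude is below this are treated
#'   as noise and removed. Default 1.0.
#' @param reference_sites named numeric of site positions used to
#'   label minima; defaults to the pocket landmarks (deep -1.6,
#'   allosteric 0, transient 7 A).
#' @return list with `extrema` (data.frame z, G, type), `states`
#'   (data.frame label, z, G: one minimum per label, nearest wins),
#'   and `barriers` (data.frame from, to, barrier).
#' @export
barrier_analysis <- function(curve, smooth = TRUE, prune = 1.0,
                             reference_sites = c(deep = -1.6,
                                                 allosteric = 0,
                                                 transient = 7)) {
  stopifnot(inherits(curve, "pmf_curve"))
  z <- curve$z; G <- curve$G
  if (length(z) < 5) stop("curve has fewer than 5 bins")
  if (smooth && length(G) >= 3) {
    Gs <- as.numeric(stats::filter(G, rep(1 / 3, 3), sides = 2))
    Gs[1] <- G[1]; Gs[length(G)] <- G[length(G)]
  } else Gs <- G

  ext <- .find_extrema(z, Gs, prune)
  # report raw free energies at the located extrema
  ext$G <- G[match(ext$z, z)]
  minima <- ext[ext$type == "min", , drop = FALSE]

  # label minima by nearest reference site; nearest minimum wins a label
  states <- do.call(rbind, lapply(names(reference_sites), function(lab) {
    if (!nrow(minima)) return(NULL)
    d <- abs(minima$z - reference_sites[[lab]])
    i <- which.min(d)
    # only claim if this minimum is closer to this site than to others
    if (which.min(abs(minima$z[i] - reference_sites)) !=
        which(names(reference_sites) == lab)) return(NULL)
    data.frame(label = lab, z = minima$z[i], G = minima$G[i])
  }))
  barriers <- NULL
  if (!is.null(states) && nrow(states) >= 2) {
    pairs <- expand.grid(a = seq_len(nrow(states)), b = seq_len(nrow(states)))
    pairs <- pairs[pairs$a != pairs$b, ]
    barriers <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      a <- pairs$a[i]; b <- pairs$b[i]
      sel <- z >= min(states$z[a], states$z[b]) &
             z <= max(states$z[a], states$z[b])
      data.frame(from = states$label[a], to = states$label[b],
                 barrier = max(G[sel]) - states$G[a])
    }))
  }
  list(extrema = ext, states = states, barriers = barriers)
}

# Local extrema by slope sign change, endpoints included as boundary
# extrema, followed by persistence pruning: interior adjacent
# minimum/maximum pairs whose amplitude is below `prune` are removed
# (smallest first). The alternating min/max structure is preserved.
.find_extrema <- function(z, G, prune) {
  n <- length(G)
  s <- sign(diff(G))
  for (i in seq_along(s)) if (s[i] == 0) s[i] <- if (i > 1) s[i - 1] else 1
  turn <- which(diff(s) != 0) + 1L
  typ <- ifelse(s[turn - 1L] < 0, "min", "max")
  first_typ <- if (length(typ)) {
    if (typ[1] == "min") "max" else "min"
  } else if (G[1] <= G[n]) "min" else "max"
  last_typ <- if (length(typ)) {
    if (typ[length(typ)] == "min") "max" else "min"
  } else if (first_typ == "min") "max" else "min"
  idx <- c(1L, turn, n)
  typ <- c(first_typ, typ, last_typ)
  repeat {
    m <- length(idx)
    if (m < 4) break
    amps <- abs(diff(G[idx]))
    # only prune pairs consisting of two interior extrema
    cand <- which(seq_len(m - 1) >= 2 & seq_len(m - 1) <= m - 2)
    if (!length(cand)) break
    j <- cand[which.min(amps[cand])]
    if (amps[j] >= prune) break
    idx <- idx[-c(j, j + 1L)]
    typ <- typ[-c(j, j + 1L)]
  }
  data.frame(z = z[idx], G = G[idx], type = typ,
             stringsAsFactors = FALSE)
}
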