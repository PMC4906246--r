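#' Voltage-tilted free-energy landscape
#'
#' Adds the work done by the membrane field on a +1 carrier to the
#' equilibrium PMF:
#' \deqn{G_V(z) = G(z) - F\,(V_m/1000)\,\delta(z),}
#' with F = 96.485 kJ/mol/V. The sign makes depolarization (positive
#' V_m, inside positive) lower outward positions (larger delta) for a
#' cation: under sufficient depolarization the orthosteric/transient
#' site becomes the global minimum. Each tilted curve is re-anchored
#' at the allosteric minimum (z nearest 0), so curves at different
#' voltages share a reference rather than an arbitrary offset.
#'
#' @param pmf a [pmf_curve] (equilibrium profile).
#' @param delta a [delta_profile]; must cover the PMF grid (values are
#'   interpolated onto it).
#' @param vm_mV membrane voltage, mV.
#' @param carrier_charge carrier charge, e (default +1).
#' @return object of class `tilted_landscape` (also a [pmf_curve])
#'   with fields `vm_mV`, `base_G` on the same grid.
#' @export
tilt_pmf <- function(pmf, delta, vm_mV, carrier_charge = 1) {
  stopifnot(inherits(pmf, "pmf_curve"), inherits(delta, "delta_profile"))
  if (min(pmf$z) < min(delta$z) - 1e-6 || max(pmf$z) > max(delta$z) + 1e-6)
    stop("delta profile does not cover the PMF grid ([",
         min(delta$z), ", ", max(delta$z), "] vs [",
         min(pmf$z), ", ", max(pmf$z), "])")
  d <- delta_eval(delta, pmf$z)
  G_V <- pmf$G - carrier_charge * vs_constants$faraday * (vm_mV / 1000) * d
  # anchor at the allosteric (base global-minimum) position so that
  # V_m = 0 reproduces the base PMF exactly
  i0 <- which.min(pmf$G)
  obj <- pmf_curve(pmf$z, G_V - G_V[i0], temperature = pmf$temperature,
                   anchor = FALSE)
  obj$vm_mV <- vm_mV
  obj$base_G <- pmf$G - pmf$G[i0]
  obj$delta <- d
  class(obj) <- c("tilted_landscape", class(obj))
  obj
}

#' @export
print.tilted_landscape <- function(x, ...) {
  cat(sprintf("<tilted_landscape> V_m = %g mV, %d points, z in [%.1f, %.1f] A\n",
              x$vm_mV, length(x$z), min(x$z), max(x$z)))
  invisible(x)
}

#' Voltage at which two binding sites become isoenergetic
#'
#' Solves \eqn{G(b) - G(a) = F\,V\,(\delta(b) - \delta(a))} for V: the
#' membrane voltage at which the tilted landscape makes states a and b
#' equally deep. Returns a signed value in mV; when the two states
#' see the same electrical distance the voltage is undefined and NA is
#' returned with a message attribute.
#'
#' @param pmf a [pmf_curve].
#' @param delta a [delta_profile].
#' @param state_a,state_b z positions of the two states (Angstrom).
#'   They are expected to be minima of the base PMF; if not, a warning
#'   is issued and the value computed anyway.
#' @return V* in mV (NA if undefined).
#' @examples
#' pmf <- make_reference_pmf("dor_wt"); d <- make_delta_profile("dor_wt")
#' equalization_voltage(pmf, d, 0, 7)   # ~380 mV
#' @export
equalization_voltage <- function(pmf, delta, state_a, state_b) {
  stopifnot(inherits(pmf, "pmf_curve"), inherits(delta, "delta_profile"))
  if (isTRUE(all.equal(state_a, state_b))) {
    out <- NA_real_
    attr(out, "reason") <- "degenerate states (same position)"
    return(out)
  }
  for (s in c(state_a, state_b)) {
    g0 <- pmf_eval(pmf, s)
    nb <- pmf_eval(pmf, s + c(-0.3, 0.3))
    if (any(nb < g0 - 1e-6))
      warning(sprintf("state z = %.2f is not a local minimum of the PMF", s),
              call. = FALSE)
  }
  dd <- delta_eval(delta, state_b) - delta_eval(delta, state_a)
  dG <- pmf_eval(pmf, state_b) - pmf_eval(pmf, state_a)
  if (abs(dd) < 1e-12) {
    out <- NA_real_
    attr(out, "reason") <- "states at equal electrical distance; no finite equalization voltage"
    return(out)
  }
  1000 * dG / (vs_constants$faraday * dd)
}

#' Kinetic traps on a tilted landscape
#'
#' Counts the local minima along the outward path whose confining
#' barrier - the lower of the two flanking maxima minus the minimum -
#' exceeds `depth_threshold`. Landscape ruggedness under depolarization
#' creates such traps; the smoother Asn131Val mutant surface has fewer,
#' which is why it transits faster despite a similar equilibrium
#' barrier.
#'
#' @param landscape a `tilted_landscape` (or any [pmf_curve]).
#' @param depth_threshold minimum confining depth to count, kJ/mol
#'   (default 2; below ~kT would count noise, above ~5 would hide the
#'   published ruggedness).
#' @param path length-2 numeric z interval to scan (default: whole
#'   grid).
#' @return list(count, positions, depths).
#' @export
kinetic_traps <- function(landscape, depth_threshold = 2,
                          path = range(landscape$z)) {
  stopifnot(inherits(landscape, "pmf_curve"), length(path) == 2)
  sel <- landscape$z >= min(path) & landscape$z <= max(path)
  if (!any(sel)) stop("path outside the landscape grid")
  z <- landscape$z[sel]; G <- landscape$G[sel]
  ext <- .find_extrema(z, G, prune = 0)
  pos <- depths <- numeric(0)
  mins <- which(ext$type == "min")
  for (i in mins) {
    if (i == 1 || i == nrow(ext)) next     # boundary minima are not traps
    depth <- min(ext$G[i - 1], ext$G[i + 1]) - ext$G[i]
    if (depth > depth_threshold) {
      pos <- c(pos, ext$z[i]); depths <- c(depths, depth)
    }
  }
  list(count = length(pos), positions = pos, depths = depths)
}

#' Mean first-passage time over a landscape
#'
#' Overdamped escape time from `z_start` to the absorbing boundary
#' `z_absorb` with a reflecting wall at `z_reflect`, by the standard
#' double quadrature
#' \deqn{T = \frac{1}{D}\int_{start}^{absorb} e^{G(z)/kT}
#'       \int_{reflect}^{z} e^{-G(z')/kT}\,dz'\,dz,}
#' evaluated by trapezoid rule on a refined grid. Links the tilted
#' landscapes quantitatively to the voltage-dependent expulsion times
#' seen in trajectories.
#'
#' @param landscape a [pmf_curve] or `tilted_landscape`.
#' @param D diffusion coefficient, A^2/ps.
#' @param z_start starting position.
#' @param z_absorb absorbing boundary (> z_start).
#' @param z_reflect reflecting wall (< z_start).
#' @param n_grid quadrature resolution (default 2000).
#' @return MFPT in ps.
#' @export
mean_first_passage_time <- function(landscape, D, z_start, z_absorb,
                                    z_reflect, n_grid = 2000) {
  stopifnot(inherits(landscape, "pmf_curve"), D > 0,
            z_reflect < z_start, z_start < z_absorb)
  kT <- thermal_energy(landscape$temperature %||% vs_constants$temperature)
  zg <- seq(z_reflect, z_absorb, length.out = n_grid)
  G <- pmf_eval(landscape, zg)
  if (!all(is.finite(G))) stop("non-finite landscape values in range")
  h <- zg[2] - zg[1]
  em <- exp(-(G - min(G)) / kT)
  ep <- exp((G - min(G)) / kT)
  inner <- c(0, cumsum((em[-1] + em[-n_grid]) / 2 * h))  # int e^{-G/kT}
  integrand <- ep * inner
  i0 <- which.min(abs(zg - z_start))
  idx <- i0:n_grid
  sum((integrand[idx][-1] + integrand[idx][-length(idx)]) / 2 * h) / D
}
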