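#' Charge-density profile across the simulation box
#'
#' Laterally averaged charge density rho(z) on a uniform grid, the raw
#' material for the slab Poisson integration that the membrane-voltage
#' determination rests on.
#'
#' @param z uniform grid, nm.
#' @param rho charge density, e/nm^3.
#' @param cross_section_area lateral box area, nm^2 (bookkeeping for
#'   total charge; the 1D potential does not depend on it).
#' @return object of class `charge_density`.
#' @export
charge_density <- function(z, rho, cross_section_area = 1) {
  z <- as.numeric(z); rho <- as.numeric(rho)
  stopifnot(length(z) == length(rho), length(z) >= 3)
  dz <- diff(z)
  if (any(abs(dz - dz[1]) > 1e-8 * abs(dz[1])))
    stop("charge_density: grid must be uniform")
  if (dz[1] <= 0) stop("charge_density: grid must be increasing")
  total <- sum((rho[-1] + rho[-length(rho)]) / 2 * dz) * cross_section_area
  structure(list(z = z, rho = rho, box_length = z[length(z)] - z[1],
                 cross_section_area = cross_section_area,
                 total_charge = total),
            class = "charge_density")
}

#' Electrostatic potential from a 1D charge density (slab Poisson)
#'
#' Double integration of Poisson's equation for a laterally averaged
#' density:
#' \deqn{\phi(z) = -\frac{1}{\epsilon_0}\int_0^z (z - z')\,\rho(z')\,dz',}
#' with rho converted from e/nm^3 to C/m^3, evaluated by trapezoid
#' quadrature on the uniform grid and referenced so that
#' phi(reference) = 0. With `periodic = TRUE` a linear term is
#' subtracted so that phi is equal at both box ends (zero net field
#' across the periodic box), the standard slab-potential convention.
#'
#' @param density a [charge_density].
#' @param periodic subtract the linear term enforcing phi(L) = phi(0).
#' @param reference_z grid position where phi = 0 (default: first grid
#'   point).
#' @return object of class `potential_profile`: list(z (nm), phi (V),
#'   reference_z).
#' @examples
#' # parallel-plate capacitor: +/- surface charges 4 nm apart
#' z <- seq(0, 8, by = 0.01)
#' rho <- numeric(length(z)); rho[z == 2] <- 0.1; rho[z == 6] <- -0.1
#' # (delta-like slabs of 0.001 e/nm^2 given the 0.01 nm spacing)
#' @export
potential_from_density <- function(density, periodic = FALSE,
                                   reference_z = NULL) {
  stopifnot(inherits(density, "charge_density"))
  z <- density$z; rho <- density$rho
  n <- length(z)
  dz <- (z[n] - z[1]) / (n - 1)
  # e/nm^3 -> C/m^3 is *e*1e27; z in nm -> m is 1e-9 per length unit;
  # the double integral carries (nm)^2, so the net factor is e*1e9/eps0.
  conv <- vs_constants$e_coulomb * 1e9 / vs_constants$eps0
  # cumulative trapezoids of rho and z'*rho
  ctrap <- function(y) c(0, cumsum((y[-1] + y[-n]) / 2 * dz))
  I0 <- ctrap(rho)        # int rho dz'
  I1 <- ctrap(rho * z)    # int z' rho dz'
  phi <- -conv * (z * I0 - I1)
  if (periodic) phi <- phi - (phi[n] - phi[1]) * (z - z[1]) / (z[n] - z[1])
  if (is.null(reference_z)) reference_z <- z[1]
  ref <- stats::approx(z, phi, xout = reference_z)$y
  if (is.na(ref)) stop("reference_z outside the grid")
  structure(list(z = z, phi = phi - ref, reference_z = reference_z),
            class = "potential_profile")
}

#' @export
print.potential_profile <- function(x, ...) {
  cat(sprintf("<potential_profile> %d points, z in [%.2f, %.2f] nm, phi span %.4g V\n",
              length(x$z), min(x$z), max(x$z), diff(range(x$phi))))
  invisible(x)
}

#' Transmembrane voltage from bulk plateau regions
#'
#' V_m = mean(phi) over the intracellular plateau minus mean(phi) over
#' the extracellular plateau (sign convention: V_m = phi_in - phi_out,
#' depolarized means positive). A warning is attached when either
#' range is not flat (internal spread > 10% of the plateau
#' difference), since the compartments must be bulk solution.
#'
#' @param potential a `potential_profile`.
#' @param side_a_range length-2 numeric, intracellular plateau (nm).
#' @param side_b_range length-2 numeric, extracellular plateau (nm).
#' @return V_m in mV, with attribute `"warning"` if a plateau is not
#'   flat.
#' @export
transmembrane_voltage <- function(potential, side_a_range, side_b_range) {
  stopifnot(inherits(potential, "potential_profile"),
            length(side_a_range) == 2, length(side_b_range) == 2)
  z <- potential$z
  pick <- function(rng) {
    i <- which(z >= min(rng) & z <= max(rng))
    if (!length(i)) stop("plateau range [", min(rng), ", ", max(rng),
                         "] outside the grid")
    potential$phi[i]
  }
  a <- pick(side_a_range); b <- pick(side_b_range)
  vm <- (mean(a) - mean(b)) * 1000
  warn <- NULL
  spread <- max(diff(range(a)), diff(range(b))) * 1000
  if (abs(vm) > 0 && spread > 0.1 * abs(vm)) {
    warn <- sprintf("plateau not flat: internal spread %.3g mV vs |V_m| %.3g mV",
                    spread, abs(vm))
    warning(warn, call. = FALSE)
  }
  structure(vm, warning = warn)
}

#' Overlapping-window average with running mean
#'
#' The voltage time-averaging scheme used throughout: means over
#' overlapping windows (stride = half the window length), followed by
#' a boxcar running mean. Output time stamps are the window centers.
#'
#' @param x numeric series, uniform in time.
#' @param dt sampling interval (same unit as `window`).
#' @param window window duration.
#' @param running_mean boxcar duration applied to the window means
#'   (must be <= window).
#' @return data.frame(time, value); `time` is relative to the first
#'   sample.
#' @export
windowed_average <- function(x, dt, window, running_mean = window / 2) {
  stopifnot(is.numeric(x), dt > 0, window > 0, running_mean <= window)
  n <- length(x)
  w <- max(1L, as.integer(round(window / dt)))
  if (w > n) stop("window longer than series")
  stride <- max(1L, w %/% 2L)
  starts <- seq(1L, n - w + 1L, by = stride)
  means <- vapply(starts, function(s) mean(x[s:(s + w - 1L)]), numeric(1))
  times <- (starts - 1 + (w - 1) / 2) * dt
  k <- max(1L, as.integer(round(running_mean / (stride * dt))))
  if (k > 1 && length(means) >= k) {
    sm <- stats::filter(means, rep(1 / k, k), sides = 2)
    keep <- !is.na(sm)
    means <- as.numeric(sm[keep]); times <- times[keep]
  }
  data.frame(time = times, value = means)
}
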