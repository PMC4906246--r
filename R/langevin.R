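#' One-dimensional ion trajectory
#'
#' Time series of the ion's transmembrane coordinate z (Angstrom,
#' relative to the Asp2.50 C-alpha reference), optionally with an
#' aligned membrane-voltage series, produced by the overdamped Langevin
#' sampler or read from disk.
#'
#' @param z numeric coordinate series (Angstrom).
#' @param dt time step between frames (ps).
#' @param vm optional aligned membrane-voltage series (mV).
#' @param seed the RNG seed that produced the series, if any.
#' @param meta optional named list of provenance (bias, voltage, ...).
#' @return an object of class `trajectory1d`.
#' @export
trajectory1d <- function(z, dt, vm = NULL, seed = NULL, meta = list()) {
  z <- as.numeric(z)
  stopifnot(length(z) >= 1, is.numeric(dt), dt > 0)
  if (!all(is.finite(z))) stop("trajectory1d: non-finite coordinates")
  if (!is.null(vm) && length(vm) != length(z))
    stop("trajectory1d: vm series length must match z")
  structure(list(z = z, dt = dt, vm = vm, seed = seed, meta = meta),
            class = "trajectory1d")
}

#' @export
print.trajectory1d <- function(x, ...) {
  cat(sprintf("<trajectory1d> %d frames, dt = %g ps, z in [%.2f, %.2f] A%s\n",
              length(x$z), x$dt, min(x$z), max(x$z),
              if (!is.null(x$vm)) ", with V_m series" else ""))
  invisible(x)
}

# Tabulate the deterministic force -dG_eff/dz on a fine grid.
# G_eff = G(z) - F * (V_m/1000) * delta(z); the harmonic bias is
# handled analytically inside the C++ stepper.
.vs_force_table <- function(potential, voltage = NULL, bounds,
                            dz = 0.02) {
  z <- seq(bounds[1], bounds[2], by = dz)
  G <- pmf_eval(potential, z)
  if (!is.null(voltage)) {
    G <- G - vs_constants$faraday * (voltage$vm_mV / 1000) *
      delta_eval(voltage$delta, z)
  }
  # central differences; one-sided at the walls
  n <- length(z)
  f <- numeric(n)
  f[2:(n - 1)] <- -(G[3:n] - G[1:(n - 2)]) / (2 * dz)
  f[1] <- -(G[2] - G[1]) / dz
  f[n] <- -(G[n] - G[n - 1]) / dz
  list(z = z, force = f, pot = G)
}

#' Overdamped Langevin trajectory on a 1D potential
#'
#' Brownian-dynamics sampler standing in for the MD engine: the ion
#' coordinate evolves by the Euler-Maruyama update
#' \deqn{z \leftarrow z + D\,dt\,F_{eff}(z)/kT + \sqrt{2 D\,dt}\,\eta,}
#' with \eqn{\eta} standard normal and \eqn{F_{eff} = -dG_{eff}/dz}
#' where \eqn{G_{eff}} is the potential plus an optional harmonic
#' umbrella bias \eqn{\kappa/2 (z-z_0)^2} and optional voltage tilt
#' \eqn{-F (V_m/1000)\,\delta(z)}. Boundaries at the potential grid
#' edges (or `bounds`) are reflecting, representing the receptor
#' walls. Deterministic for a fixed seed.
#'
#' @param potential a [pmf_curve].
#' @param n_steps number of integration steps recorded (after burn-in).
#' @param dt time step, ps.
#' @param D diffusion coefficient, A^2/ps.
#' @param seed integer RNG seed; if NULL the current RNG state is used.
#' @param z_init starting coordinate; default the potential's minimum
#'   (or the bias center when biased).
#' @param bias optional list(z0=, kappa=) harmonic umbrella restraint
#'   (kJ/mol/A^2).
#' @param voltage optional list(vm_mV=, delta=) membrane voltage and
#'   [delta_profile] adding the tilt \eqn{-F V_m \delta(z)}.
#' @param bounds length-2 numeric, reflecting walls; default the
#'   potential grid range.
#' @param burnin steps discarded before recording (default 0).
#' @param stride record every `stride`-th step (default 1).
#' @param metropolis accept/reject each Euler move with the
#'   Metropolis-Hastings ratio (MALA), making the sampled distribution
#'   exactly Boltzmann at any stable step size (default TRUE; set
#'   FALSE for plain Euler-Maruyama dynamics, e.g. when time scales
#'   matter more than equilibrium accuracy).
#' @param temperature K.
#' @return a [trajectory1d]; `dt` of the result is `dt * stride`.
#' @export
langevin_trajectory <- function(potential, n_steps, dt = 0.01, D = 0.05,
                                seed = NULL, z_init = NULL, bias = NULL,
                                voltage = NULL, bounds = NULL,
                                burnin = 0, stride = 1, metropolis = TRUE,
                                temperature = vs_constants$temperature) {
  stopifnot(inherits(potential, "pmf_curve"), n_steps >= 1, dt > 0, D > 0)
  kT <- thermal_energy(temperature)
  if (is.null(bounds)) bounds <- range(potential$z)
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2])
  kappa <- 0; center <- 0
  if (!is.null(bias)) {
    kappa <- bias$kappa; center <- bias$z0
    stopifnot(is.numeric(kappa), kappa >= 0, is.numeric(center))
    stab <- kappa * dt * D / kT
    if (stab >= 0.5)
      stop(sprintf("unstable step: kappa*dt*D/kT = %.3f (dt = %g too large)",
                   stab, dt))
    if (stab >= 0.1)
      warning(sprintf(
        "kappa*dt*D/kT = %.3f >= 0.1; biased sampling may carry discretization bias",
        stab))
  }
  tab <- .vs_force_table(potential, voltage, bounds)
  if (is.null(z_init))
    z_init <- if (!is.null(bias)) center else potential$z[which.min(potential$G)]
  z_init <- min(max(z_init, bounds[1]), bounds[2])
  if (!is.null(seed)) set.seed(as.integer(seed))
  z <- cpp_langevin(tab$z, tab$force, tab$pot, z_init, D, dt, kT,
                    as.integer(n_steps), as.integer(burnin),
                    as.integer(stride), kappa, center,
                    bounds[1], bounds[2], isTRUE(metropolis))
  trajectory1d(z, dt = dt * stride, seed = seed,
               meta = list(D = D, bias = bias, voltage = voltage,
                           bounds = bounds, temperature = temperature))
}

#' First-passage time of a Langevin particle
#'
#' Runs the same Brownian dynamics as [langevin_trajectory] until the
#' coordinate first reaches `z_absorb` (absorbing boundary), with a
#' reflecting wall at `z_reflect`. Used to validate the
#' mean-first-passage-time quadrature and to emulate voltage-driven
#' expulsion experiments.
#'
#' @inheritParams langevin_trajectory
#' @param z_start starting position.
#' @param z_absorb absorbing boundary (> z_start).
#' @param z_reflect reflecting wall (< z_start).
#' @param max_steps horizon; NA is returned if not absorbed in time.
#' @return passage time in ps, or NA.
#' @export
langevin_first_passage <- function(potential, z_start, z_absorb, z_reflect,
                                   dt = 0.01, D = 0.05, seed = NULL,
                                   voltage = NULL, max_steps = 1e7,
                                   temperature = vs_constants$temperature) {
  stopifnot(inherits(potential, "pmf_curve"),
            z_reflect < z_start, z_start < z_absorb, D > 0)
  kT <- thermal_energy(temperature)
  tab <- .vs_force_table(potential, voltage, c(z_reflect, z_absorb))
  if (!is.null(seed)) set.seed(as.integer(seed))
  cpp_first_passage(tab$z, tab$force, z_start, D, dt, kT,
                    z_reflect, z_absorb, max_steps)
}

#' Umbrella-sampling window set
#'
#' Generates one biased Langevin trajectory per restraint center, with
#' the harmonic bias parameters attached, after discarding an
#' equilibration segment. Emulates the umbrella-sampling stage of the
#' PMF calculation (the published protocol used windows finer than
#' 0.5 A and >150 ns per window; the synthetic protocol controls
#' per-window sample counts instead).
#'
#' Adjacent windows whose centers are farther apart than
#' 3 * sqrt(kT/kappa) have weak histogram overlap; this is recorded as
#' a warning in the returned metadata (and signalled once), not an
#' error, since WHAM can still bridge the gap with enough samples.
#'
#' @param potential a [pmf_curve].
#' @param centers sorted restraint centers (Angstrom).
#' @param kappa harmonic force constant (kJ/mol/A^2).
#' @param steps_per_window recorded samples per window.
#' @param equilibration_steps discarded steps per window.
#' @param seed integer; per-window seeds are derived deterministically.
#' @param stride record every `stride`-th integration step: the window
#'   then integrates `steps_per_window * stride` steps but stores
#'   `steps_per_window` samples. Successive samples decorrelate over
#'   ~kT/(kappa*D) ps, so thinning loses little information while
#'   keeping memory flat (default 1).
#' @param dt,D,temperature integrator parameters, see
#'   [langevin_trajectory].
#' @return an object of class `umbrella_set`: list of windows, each
#'   a list(center, kappa, temperature, samples), plus metadata.
#' @export
make_umbrella_windows <- function(potential, centers, kappa,
                                  steps_per_window,
                                  equilibration_steps = 2000,
                                  seed = 1, dt = 0.01, D = 0.05,
                                  stride = 1,
                                  temperature = vs_constants$temperature) {
  stopifnot(inherits(potential, "pmf_curve"), length(centers) >= 1,
            kappa > 0, steps_per_window >= 1)
  if (is.unsorted(centers)) stop("centers must be sorted")
  if (steps_per_window <= 0) stop("zero steps after equilibration")
  kT <- thermal_energy(temperature)
  spacing_limit <- 3 * sqrt(kT / kappa)
  gaps <- diff(centers)
  weak <- which(gaps > spacing_limit)
  warnings <- character(0)
  if (length(weak)) {
    warnings <- sprintf(
      "weak overlap between windows %d and %d (gap %.2f A > %.2f A)",
      weak, weak + 1, gaps[weak], spacing_limit)
    warning(sprintf(
      "%d window pair(s) with center gap > 3*sqrt(kT/kappa) = %.2f A; %s",
      length(weak), spacing_limit,
      "overlap relies on histogram tails"), call. = FALSE)
  }
  stab <- kappa * dt * D / kT
  if (stab >= 0.1 && stab < 0.5)
    warning(sprintf(
      "kappa*dt*D/kT = %.3f >= 0.1; biased sampling may carry discretization bias",
      stab), call. = FALSE)
  windows <- vector("list", length(centers))
  for (i in seq_along(centers)) {
    tr <- suppressWarnings(langevin_trajectory(
      potential, n_steps = steps_per_window, dt = dt, D = D,
      seed = as.integer(seed) + 7919L * i, stride = stride,
      bias = list(z0 = centers[i], kappa = kappa),
      burnin = equilibration_steps, temperature = temperature))
    windows[[i]] <- list(center = centers[i], kappa = kappa,
                         temperature = temperature, samples = tr$z)
  }
  structure(list(windows = windows,
                 meta = list(kappa = kappa, dt = dt, D = D, seed = seed,
                             equilibration_steps = equilibration_steps,
                             overlap_warnings = warnings)),
            class = "umbrella_set")
}

#' @export
print.umbrella_set <- function(x, ...) {
  n <- length(x$windows)
  cat(sprintf("<umbrella_set> %d windows, kappa = %g kJ/mol/A^2, %d samples each\n",
              n, x$meta$kappa, length(x$windows[[1]]$samples)))
  if (length(x$meta$overlap_warnings))
    cat("  ", length(x$meta$overlap_warnings), "overlap warning(s)\n")
  invisible(x)
}
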