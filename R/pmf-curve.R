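#' Free-energy profile along the transmembrane axis
#'
#' Container for a potential of mean force G(z): a grid of positions
#' (Angstrom, relative to the Asp2.50 C-alpha reference plane at z = 0),
#' free energies (kJ/mol, anchored so that the populated minimum is 0),
#' and optionally per-bin bootstrap SDs and effective sample counts.
#' Analytic reference curves additionally carry a continuous evaluator.
#'
#' @param z numeric vector of positions (Angstrom), strictly increasing.
#' @param G numeric vector of free energies (kJ/mol), same length as `z`.
#' @param sd optional per-bin SD (kJ/mol).
#' @param n_eff optional per-bin effective sample count.
#' @param fun optional vectorized function of z returning G (analytic
#'   curves); must agree with `G` on the grid.
#' @param temperature temperature in K.
#' @param anchor logical; shift G so min(G) = 0 (default TRUE).
#' @return an object of class `pmf_curve`.
#' @export
pmf_curve <- function(z, G, sd = NULL, n_eff = NULL, fun = NULL,
                      temperature = vs_constants$temperature,
                      anchor = TRUE) {
  z <- as.numeric(z); G <- as.numeric(G)
  stopifnot(length(z) == length(G), length(z) >= 2)
  if (is.unsorted(z, strictly = TRUE))
    stop("pmf_curve: z grid must be strictly increasing")
  if (!all(is.finite(G))) stop("pmf_curve: non-finite free energies")
  if (!is.null(sd)) {
    stopifnot(length(sd) == length(G))
    if (any(sd < 0, na.rm = TRUE)) stop("pmf_curve: negative SD")
  }
  offset <- if (anchor) min(G) else 0
  G <- G - offset
  if (!is.null(fun)) {
    f0 <- fun
    fun <- function(x) f0(x) - offset
  }
  structure(
    list(z = z, G = G, sd = sd, n_eff = n_eff, fun = fun,
         temperature = temperature),
    class = "pmf_curve")
}

#' Evaluate a PMF at arbitrary positions
#'
#' Uses the analytic evaluator when present, otherwise monotone-safe
#' linear interpolation on the grid (no extrapolation: values outside
#' the grid are clamped to the edge values, representing the
#' receptor/bulk walls).
#'
#' @param curve a [pmf_curve].
#' @param z positions (Angstrom).
#' @return free energies (kJ/mol).
#' @export
pmf_eval <- function(curve, z) {
  stopifnot(inherits(curve, "pmf_curve"))
  if (!is.null(curve$fun)) return(curve$fun(z))
  stats::approx(curve$z, curve$G, xout = pmin(pmax(z, min(curve$z)),
                                              max(curve$z)))$y
}

#' @export
print.pmf_curve <- function(x, ...) {
  cat(sprintf(
    "<pmf_curve> %d points, z in [%.2f, %.2f] A, G in [%.2f, %.2f] kJ/mol%s\n",
    length(x$z), min(x$z), max(x$z), min(x$G), max(x$G),
    if (!is.null(x$sd)) sprintf(", median SD %.2f", stats::median(x$sd, na.rm = TRUE)) else ""))
  invisible(x)
}

#' Electrical-distance profile delta(z)
#'
#' The fraction of the transmembrane voltage drop traversed by a charge
#' at position z, anchored at the reference position (delta = 0 at the
#' allosteric site, z = 0) and reaching a plateau beyond the pocket
#' exit. Built either analytically from the variant tables
#' ([make_delta_profile]) or empirically from a Q-V position scan
#' ([electrical_distance_profile]).
#'
#' @param z numeric positions (Angstrom), strictly increasing.
#' @param delta numeric electrical distances (dimensionless).
#' @param err optional per-point error.
#' @param fun optional continuous evaluator.
#' @return an object of class `delta_profile`.
#' @export
delta_profile <- function(z, delta, err = NULL, fun = NULL) {
  z <- as.numeric(z); delta <- as.numeric(delta)
  stopifnot(length(z) == length(delta), length(z) >= 2)
  if (is.unsorted(z, strictly = TRUE))
    stop("delta_profile: z must be strictly increasing")
  if (!all(is.finite(delta))) stop("delta_profile: non-finite delta")
  structure(list(z = z, delta = delta, err = err, fun = fun),
            class = "delta_profile")
}

#' Evaluate an electrical-distance profile at arbitrary positions
#'
#' Linear interpolation on the stored grid unless an analytic evaluator
#' is attached; outside the grid the edge (plateau) values are held.
#'
#' @param profile a [delta_profile].
#' @param z positions (Angstrom).
#' @return delta values.
#' @export
delta_eval <- function(profile, z) {
  stopifnot(inherits(profile, "delta_profile"))
  if (!is.null(profile$fun)) return(profile$fun(z))
  stats::approx(profile$z, profile$delta,
                xout = pmin(pmax(z, min(profile$z)), max(profile$z)))$y
}

#' @export
print.delta_profile <- function(x, ...) {
  cat(sprintf("<delta_profile> %d points, z in [%.2f, %.2f] A, plateau %.3f\n",
              length(x$z), min(x$z), max(x$z), x$delta[length(x$delta)]))
  invisible(x)
}
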