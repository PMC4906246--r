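#' Knot tables defining the reference free-energy profiles
#'
#' Each receptor variant is defined by an ordered knot table (z in
#' Angstrom relative to the Asp2.50 C-alpha plane, G in kJ/mol) through
#' which a shape-preserving monotone cubic (Fritsch-Carlson) is drawn,
#' so that the curve has no extrema other than those implied by the
#' knots. The tables encode the published landscape features: for the
#' wild-type delta-opioid receptor a global minimum at the
#' crystallographic allosteric site (z = 0), a second intracellular
#' minimum near z = -1.6 A behind a 5.3 kJ/mol barrier, a 9.0 kJ/mol
#' local barrier confining the ion in the extracellular direction, a
#' 13.0 kJ/mol total barrier toward the transient (orthosteric-pocket)
#' site whose minima near z ~ 7 and 10 A sit ~11 kJ/mol above the
#' allosteric site; for the Asn131(3.35)Val mutant a broadened ~4 A
#' basin with its preferred position at z = -2.2 A, the same 13.0
#' kJ/mol main barrier but smoother, and a transient site ~10 kJ/mol
#' up; for the M2 muscarinic receptor a single sharp 26 kJ/mol barrier
#' ~4.5 A above Asp69(2.50), a minor well at z ~ 3 A, and a transient
#' site ~15 kJ/mol above the allosteric one. Knot values not pinned by
#' a published number (wall heights, bulk plateaus, minor-well depths)
#' are package constants documented in the methods vignette.
#'
#' @keywords internal
.vs_pmf_knots <- list(
  dor_wt = list(
    z = c(-6, -1.6, -0.8, 0, 2.0, 3.0, 4.5, 7.0, 8.5, 10.0, 12.5, 15),
    G = c(20, 1.5, 5.3, 0, 9.0, 7.0, 13.0, 11.0, 14.0, 12.0, 15.0, 15.0)),
  dor_n131v = list(
    z = c(-6, -4.0, -2.2, 0.5, 4.5, 7.5, 9.5, 12.5, 15),
    G = c(20, 1.5, 0, 1.5, 13.0, 10.0, 13.0, 14.0, 14.0)),
  m2r = list(
    z = c(-5, 0, 2.0, 3.0, 4.5, 7.5, 9.5, 12.5, 15),
    G = c(20, 0, 9.0, 7.0, 26.0, 15.0, 17.0, 18.0, 18.0))
)

#' Knot tables for the electrical-distance profiles
#'
#' delta = 0 at the allosteric reference position; a small negative
#' excursion at z = -2 models the hyperpolarized attraction deeper into
#' the pocket; plateau values beyond the pocket exit (z >= 12.5 A) are
#' the published maximal gating charges for a +1 carrier: 0.42 (WT
#' delta-OR), 0.63 (Asn131Val), 0.53 (M2R). Intermediate values near
#' the base of the orthosteric pocket (~0.3 at z ~ 7 A for WT
#' delta-OR and M2R) follow the published position scan; elsewhere the
#' profile is monotone-interpolated.
#'
#' @keywords internal
.vs_delta_knots <- list(
  dor_wt    = list(z = c(-6, -2, 0, 7.0, 12.5, 15),
                   delta = c(0, -0.03, 0, 0.30, 0.42, 0.42)),
  dor_n131v = list(z = c(-6, -2, 0, 12.5, 15),
                   delta = c(0, -0.03, 0, 0.63, 0.63)),
  m2r       = list(z = c(-5, -2, 0, 7.5, 12.5, 15),
                   delta = c(0, -0.03, 0, 0.30, 0.53, 0.53))
)

# Shape-preserving monotone cubic through (x, y): Hermite spline with
# Fritsch-Carlson derivatives. Unlike stats::splinefun(method =
# "monoH.FC"), the derivative is forced to exactly zero at knots where
# the secant slope changes sign, so knot extrema are never overshot and
# the curve has no extrema other than those implied by the knots.
.monotone_cubic <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 3, !is.unsorted(x, strictly = TRUE))
  d <- diff(y) / diff(x)                 # secants
  m <- numeric(n)
  m[1] <- d[1]; m[n] <- d[n - 1]
  for (i in 2:(n - 1)) {
    m[i] <- if (d[i - 1] * d[i] <= 0) 0 else {
      # harmonic mean respects the FC monotonicity region
      2 / (1 / d[i - 1] + 1 / d[i])
    }
  }
  # FC limiter: |m| <= 3 |secant| on both sides
  for (i in seq_len(n - 1)) {
    if (d[i] == 0) { m[i] <- m[i + 1] <- 0; next }
    m[i]     <- sign(d[i]) * min(abs(m[i]),     3 * abs(d[i]))
    m[i + 1] <- sign(d[i]) * min(abs(m[i + 1]), 3 * abs(d[i]))
  }
  stats::splinefunH(x, y, m)
}

#' Receptor variants with bundled reference profiles
#'
#' @return character vector of recognized profile ids.
#' @export
profile_ids <- function() names(.vs_pmf_knots)

.vs_check_profile <- function(profile_id) {
  if (!is.character(profile_id) || length(profile_id) != 1 ||
      !profile_id %in% names(.vs_pmf_knots))
    stop("unknown profile_id '", paste(profile_id, collapse = ","),
         "'; expected one of: ", paste(names(.vs_pmf_knots), collapse = ", "))
  profile_id
}

#' Analytic reference PMF for a receptor variant
#'
#' Builds the ground-truth free-energy profile G(z) for one of the
#' three receptor variants by monotone cubic (Fritsch-Carlson)
#' interpolation of the variant's knot table. The interpolant passes
#' through every knot exactly, is shape-preserving (no spurious
#' extrema between knots), and is anchored so that the global minimum
#' is 0 kJ/mol.
#'
#' @param profile_id one of `"dor_wt"` (wild-type delta-opioid
#'   receptor), `"dor_n131v"` (Asn131(3.35)Val mutant), `"m2r"` (M2
#'   muscarinic receptor).
#' @param dz grid spacing for the stored curve, Angstrom.
#' @param temperature temperature in K.
#' @return a [pmf_curve] with a continuous evaluator; evaluation
#'   outside the knot range clamps to the wall values.
#' @examples
#' pmf <- make_reference_pmf("dor_wt")
#' pmf_eval(pmf, 0)                  # allosteric site, 0 by anchoring
#' max(pmf_eval(pmf, seq(0, 7, 0.01)))  # 13.0 kJ/mol main barrier
#' @export
make_reference_pmf <- function(profile_id, dz = 0.05,
                               temperature = vs_constants$temperature) {
  .vs_check_profile(profile_id)
  kn <- .vs_pmf_knots[[profile_id]]
  sf <- .monotone_cubic(kn$z, kn$G)
  lo <- min(kn$z); hi <- max(kn$z)
  fun <- function(z) sf(pmin(pmax(z, lo), hi))
  z <- seq(lo, hi, by = dz)
  pmf_curve(z = z, G = fun(z), fun = fun, temperature = temperature)
}

#' Analytic electrical-distance profile for a receptor variant
#'
#' delta(z) is the fraction of the transmembrane voltage drop a charge
#' has traversed at position z. It is 0 at the allosteric reference
#' position, non-decreasing for z >= 0, and constant beyond the pocket
#' exit at the variant's maximal gating charge per unit carrier charge
#' (0.42, 0.63, 0.53 for dor_wt, dor_n131v, m2r).
#'
#' @inheritParams make_reference_pmf
#' @param dz grid spacing, Angstrom.
#' @return a [delta_profile] with continuous evaluator.
#' @examples
#' d <- make_delta_profile("dor_wt")
#' delta_eval(d, c(0, 7, 15))   # 0, 0.30, 0.42
#' @export
make_delta_profile <- function(profile_id, dz = 0.05) {
  .vs_check_profile(profile_id)
  kn <- .vs_delta_knots[[profile_id]]
  sf <- .monotone_cubic(kn$z, kn$delta)
  lo <- min(kn$z); hi <- max(kn$z)
  fun <- function(z) sf(pmin(pmax(z, lo), hi))
  z <- seq(lo, hi, by = dz)
  delta_profile(z = z, delta = fun(z), fun = fun)
}
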