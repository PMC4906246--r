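#' Least-squares fit of a charge-imbalance/voltage series
#'
#' Fits V_m = slope * dq + intercept. The inverse slope is the
#' system's capacitance in e/V; its near-constancy across ion
#' positions is the premise of the pairing estimator. `slope_min` and
#' `slope_max` are the extreme secant slopes among consecutive
#' imbalance points, the max/min-slope device used to propagate errors
#' into the gating charge.
#'
#' @param series a [qv_series].
#' @return list(slope, intercept, slope_min, slope_max, capacitance)
#'   with slope in mV/e and capacitance in e/V.
#' @export
fit_qv <- function(series) {
  stopifnot(inherits(series, "qv_series"))
  if (length(unique(series$imbalance_e)) < 2)
    stop("fit_qv: all imbalance values identical")
  o <- order(series$imbalance_e)
  q <- series$imbalance_e[o]; v <- series$vm_mV[o]
  fit <- stats::lm.fit(cbind(1, q), v)
  slope <- unname(fit$coefficients[2])
  secants <- diff(v) / diff(q)
  list(slope = slope, intercept = unname(fit$coefficients[1]),
       slope_min = min(secants), slope_max = max(secants),
       capacitance = 1000 / slope)
}

#' Gating-charge estimate for one pair of ion positions
#'
#' @param q_g gating charge, e.
#' @param err half-spread from the max/min-slope evaluation, e.
#' @param z_a,z_b the position pair (Angstrom).
#' @param capacitance pooled capacitance used, e/V.
#' @param warning optional inconsistency note.
#' @return object of class `gating_charge_estimate`.
#' @export
gating_charge_estimate <- function(q_g, err, z_a, z_b, capacitance,
                                   warning = NULL) {
  stopifnot(err >= 0)
  structure(list(q_g = q_g, err = err, z_a = z_a, z_b = z_b,
                 capacitance = capacitance, warning = warning),
            class = "gating_charge_estimate")
}

#' @export
print.gating_charge_estimate <- function(x, ...) {
  cat(sprintf("<gating charge> %.3f +/- %.3f e (z %.1f -> %.1f A, C = %.2f e/V)\n",
              x$q_g, x$err, x$z_a, x$z_b, x$capacitance))
  invisible(x)
}

#' Gating charge from a pair of Q-V series
#'
#' At each common charge imbalance dq, the voltage difference
#' dV(dq) = V_a(dq) - V_b(dq) between the two restrained ion
#' positions reflects the charge the ion displaces across the field;
#' the gating charge is the mean of dV over imbalances divided by the
#' pooled fitted slope of the Q-V relationships. The error is the
#' half-spread obtained by re-evaluating with the extreme secant
#' slopes of the two series. Sign convention: with `series_a` the
#' inner (reference) position and `series_b` the outer one, outward
#' movement of a cation gives a positive gating charge.
#'
#' @param series_a [qv_series] at the reference (inner) position.
#' @param series_b [qv_series] at the displaced (outer) position.
#' @return a [gating_charge_estimate]. A warning is attached (and
#'   signalled) when the two series' slopes differ by more than 10%
#'   of their mean, i.e. when the constant-capacitance premise fails.
#' @examples
#' d <- make_delta_profile("dor_wt")
#' qv <- make_qv_ensemble(compel_spec(d, vm_noise_sd = 0), c(0, 15))
#' gating_charge(qv[[1]], qv[[2]])$q_g   # 0.42 e
#' @export
gating_charge <- function(series_a, series_b) {
  stopifnot(inherits(series_a, "qv_series"), inherits(series_b, "qv_series"))
  common <- intersect(series_a$imbalance_e, series_b$imbalance_e)
  if (length(common) < 3)
    stop("gating_charge: fewer than 3 common imbalance values")
  va <- series_a$vm_mV[match(common, series_a$imbalance_e)]
  vb <- series_b$vm_mV[match(common, series_b$imbalance_e)]
  dv <- mean(va - vb)                               # mV
  fa <- fit_qv(series_a); fb <- fit_qv(series_b)
  slope <- (fa$slope + fb$slope) / 2                # mV/e
  warn <- NULL
  if (abs(fa$slope - fb$slope) > 0.1 * abs(slope)) {
    warn <- sprintf("capacitance inconsistent between positions (%.1f vs %.1f mV/e)",
                    fa$slope, fb$slope)
    warning(warn, call. = FALSE)
  }
  s_min <- min(fa$slope_min, fb$slope_min)
  s_max <- max(fa$slope_max, fb$slope_max)
  q_g <- dv / slope
  err <- abs(dv / s_min - dv / s_max) / 2
  gating_charge_estimate(q_g, err,
                         z_a = series_a$position_z[1],
                         z_b = series_b$position_z[1],
                         capacitance = 1000 / slope, warning = warn)
}

#' Electrical-distance profile from a Q-V position scan
#'
#' Converts a scan of Q-V series measured with the probe ion
#' restrained at successive positions (the published protocol stepped
#' by 2.5 A from the pocket to the bulk) into delta(z): for each scan
#' position, delta(z_i) = q_g(reference -> z_i) / q_ion, with the
#' max/min-slope error per point. An additivity diagnostic is
#' attached: the residual q_g(a->c) - q_g(a->b) - q_g(b->c) over
#' consecutive position triples, which telescopes to 0 on noise-free
#' data.
#'
#' @param scan list of [qv_series] at distinct, sorted positions.
#' @param reference_z the scan position taken as delta = 0 (the
#'   allosteric site); must be present in the scan.
#' @param q_ion carrier charge, e (default +1).
#' @return a [delta_profile] with `err`, plus attributes
#'   `"additivity_residuals"` and `"gating_charges"`.
#' @export
electrical_distance_profile <- function(scan, reference_z = 0, q_ion = 1) {
  stopifnot(is.list(scan), length(scan) >= 2)
  pos <- vapply(scan, function(s) s$position_z[1], numeric(1))
  if (anyDuplicated(pos)) stop("duplicate scan positions")
  if (is.unsorted(pos)) stop("scan positions must be sorted")
  iref <- which(abs(pos - reference_z) < 1e-9)
  if (!length(iref)) stop("reference position not present in scan")
  ref <- scan[[iref]]
  est <- lapply(seq_along(scan), function(i) {
    if (i == iref)
      return(gating_charge_estimate(0, 0, reference_z, reference_z, NA))
    suppressWarnings(gating_charge(ref, scan[[i]]))
  })
  delta <- vapply(est, `[[`, numeric(1), "q_g") / q_ion
  err <- vapply(est, `[[`, numeric(1), "err") / abs(q_ion)
  # additivity over consecutive triples (a = reference pairing route)
  resid <- if (length(scan) >= 3) {
    vapply(seq_len(length(scan) - 2), function(i) {
      a <- scan[[i]]; b <- scan[[i + 1]]; c <- scan[[i + 2]]
      suppressWarnings(
        gating_charge(a, c)$q_g - gating_charge(a, b)$q_g -
          gating_charge(b, c)$q_g)
    }, numeric(1))
  } else numeric(0)
  prof <- delta_profile(pos, delta, err = err)
  attr(prof, "additivity_residuals") <- resid
  attr(prof, "gating_charges") <- est
  prof
}

#' Gating charge of an arbitrary carrier over an interval
#'
#' The gating charge depends only on the carrier charge and the
#' electrical distance traversed, q_g = q (delta(z_to) -
#' delta(z_from)): a proton crossing the pocket registers the same
#' gating charge as a sodium ion over the same span.
#'
#' @param profile a [delta_profile].
#' @param carrier_charge carrier charge in e (e.g. +1 for Na+ or H+).
#' @param z_from,z_to interval endpoints (Angstrom), within the
#'   profile domain.
#' @return gating charge, e.
#' @examples
#' d <- make_delta_profile("m2r")
#' carrier_equivalence(d, 1, 0, 15)   # 0.53, ~0.5 e
#' @export
carrier_equivalence <- function(profile, carrier_charge, z_from, z_to) {
  stopifnot(inherits(profile, "delta_profile"))
  rng <- range(profile$z)
  if (any(c(z_from, z_to) < rng[1] - 1e-9 | c(z_from, z_to) > rng[2] + 1e-9))
    stop("endpoints outside the profile domain")
  carrier_charge * (delta_eval(profile, z_to) - delta_eval(profile, z_from))
}
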