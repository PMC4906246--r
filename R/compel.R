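#' Double-bilayer (computational electrophysiology) generator spec
#'
#' Parameters of the synthetic charge-imbalance experiment: a membrane
#' capacitor of capacitance `C_m` (e per volt; the default 4.0
#' reproduces the published calibration that a single Na+ imbalance
#' sustains ~250 mV, scaling to ~1,000 mV at 4 ions), a probe ion of
#' charge `q_ion` restrained at a position z, Gaussian measurement
#' noise on the window-averaged voltage, and an integer imbalance
#' ladder (default -4..+4, the published range).
#'
#' @param delta a [delta_profile] giving the electrical distance of the
#'   probe ion position.
#' @param C_m membrane capacitance, e/V.
#' @param q_ion probe ion charge, e.
#' @param vm_noise_sd SD of a single voltage measurement, mV.
#' @param n_replicates measurements averaged per (position, imbalance).
#' @param imbalances integer charge-imbalance ladder, e.
#' @param seed integer RNG seed.
#' @return an object of class `compel_spec`.
#' @export
compel_spec <- function(delta, C_m = 4.0, q_ion = 1,
                        vm_noise_sd = 10, n_replicates = 50,
                        imbalances = -4:4, seed = 1) {
  stopifnot(inherits(delta, "delta_profile"), C_m > 0,
            n_replicates >= 1, vm_noise_sd >= 0)
  if (length(unique(imbalances)) < 3)
    stop("compel_spec: need >= 3 distinct imbalance values")
  structure(list(delta = delta, C_m = C_m, q_ion = q_ion,
                 vm_noise_sd = vm_noise_sd, n_replicates = n_replicates,
                 imbalances = imbalances, seed = seed),
            class = "compel_spec")
}

#' Charge-imbalance / voltage series at one probe-ion position
#'
#' @param position_z probe ion position, Angstrom.
#' @param imbalance_e integer bulk charge imbalances, e.
#' @param vm_mV mean membrane voltage per imbalance, mV.
#' @param se_mV standard error of each mean, mV.
#' @param n replicates per point.
#' @return object of class `qv_series` (also a data.frame).
#' @export
qv_series <- function(position_z, imbalance_e, vm_mV, se_mV, n = NA_integer_) {
  stopifnot(length(imbalance_e) == length(vm_mV),
            length(vm_mV) == length(se_mV))
  if (length(unique(imbalance_e)) < 3)
    stop("qv_series: need >= 3 distinct imbalance values")
  if (any(se_mV < 0)) stop("qv_series: negative SE")
  df <- data.frame(position_z = position_z, imbalance_e = imbalance_e,
                   vm_mV = vm_mV, se_mV = se_mV, n = n)
  class(df) <- c("qv_series", "data.frame")
  df
}

#' Synthetic double-bilayer Q-V ensembles
#'
#' For each probe-ion position z_i and bulk charge imbalance dq, the
#' measured membrane voltage is drawn around the capacitor-model mean
#' \deqn{V_m = (dq - q_{ion}\,\delta(z_i)) / C_m}
#' (in volts, reported in mV): restraining the ion a fraction
#' delta(z_i) of the way across the field cancels that fraction of one
#' carrier charge from the bulk imbalance. The reported mean is an
#' average of `n_replicates` noisy measurements, so its SE is
#' `vm_noise_sd / sqrt(n_replicates)`.
#'
#' @param spec a [compel_spec].
#' @param ion_positions probe positions (Angstrom) within the delta
#'   profile domain.
#' @return list of [qv_series], one per position, in input order.
#' @examples
#' d <- make_delta_profile("dor_wt")
#' qv <- make_qv_ensemble(compel_spec(d, vm_noise_sd = 0), c(0, 12.5))
#' # noise-free offset between the two positions at any imbalance:
#' qv[[1]]$vm_mV[1] - qv[[2]]$vm_mV[1]   # +105 mV = 0.42/4 V
#' @export
make_qv_ensemble <- function(spec, ion_positions) {
  stopifnot(inherits(spec, "compel_spec"), length(ion_positions) >= 1)
  rng <- range(spec$delta$z)
  if (any(ion_positions < rng[1] | ion_positions > rng[2]))
    stop("ion position outside the delta-profile domain [",
         rng[1], ", ", rng[2], "]")
  if (length(spec$imbalances) == 0) stop("empty imbalance list")
  set.seed(as.integer(spec$seed))
  se <- spec$vm_noise_sd / sqrt(spec$n_replicates)
  lapply(ion_positions, function(zi) {
    d <- delta_eval(spec$delta, zi)
    mean_v <- 1000 * (spec$imbalances - spec$q_ion * d) / spec$C_m
    meas <- mean_v + stats::rnorm(length(mean_v), sd = se)
    qv_series(zi, spec$imbalances, meas, rep(se, length(mean_v)),
              n = spec$n_replicates)
  })
}
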