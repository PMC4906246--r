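#' Landmark free-energy features of a reconstructed profile
#'
#' Convenience wrapper around [barrier_analysis] extracting the
#' quantities the voltage-sensing analysis reports for a pocket
#' profile, all measured from the allosteric state minimum:
#' \describe{
#'   \item{main_barrier}{highest point on the outward path from the
#'     allosteric to the transient state (the total barrier for
#'     allosteric -> orthosteric/transient transfer)}
#'   \item{deep_barrier}{confining barrier between the allosteric
#'     minimum and the deeper intracellular minimum}
#'   \item{confinement_barrier}{first maximum encountered moving
#'     outward from the allosteric minimum (the local barrier holding
#'     the ion at the crystallographic site)}
#'   \item{transient_offset}{free energy of the transient-site minimum
#'     relative to the allosteric minimum}
#' }
#'
#' @param curve a [pmf_curve] (reconstructed or analytic).
#' @param ... passed to [barrier_analysis].
#' @return named list of the four features (NA when the corresponding
#'   state is absent from the profile).
#' @export
pmf_site_report <- function(curve, ...) {
  ba <- barrier_analysis(curve, ...)
  st <- ba$states
  get_state <- function(lab) {
    i <- which(st$label == lab)
    if (length(i)) st[i, ] else NULL
  }
  allo <- get_state("allosteric")
  deep <- get_state("deep")
  trans <- get_state("transient")
  out <- list(main_barrier = NA_real_, deep_barrier = NA_real_,
              confinement_barrier = NA_real_, transient_offset = NA_real_)
  if (is.null(allo)) return(out)
  bar <- function(to) {
    i <- which(ba$barriers$from == "allosteric" & ba$barriers$to == to)
    if (length(i)) ba$barriers$barrier[i] else NA_real_
  }
  if (!is.null(trans)) {
    out$main_barrier <- bar("transient")
    out$transient_offset <- trans$G - allo$G
  }
  if (!is.null(deep)) out$deep_barrier <- bar("deep")
  ext <- ba$extrema
  first_max <- ext$G[ext$type == "max" & ext$z > allo$z]
  if (length(first_max)) out$confinement_barrier <- first_max[1] - allo$G
  out
}
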