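# Two-component toy attenuation curves: a photoelectric-like E^-3 term plus a
# slowly varying Compton-like term, both anchored at 60 keV. Coefficients are
# a modelling convenience calibrated so that the diagnostic-vs-megavoltage
# contrast ordering between aluminium, brass and the plastics behaves like
# published tabulations in shape; they are not reference data.
.mu_params <- list(
  aluminum    = c(pe = 0.0600, cp = 0.0240, cexp = 0.08),
  brass       = c(pe = 1.3000, cp = 0.0620, cexp = 0.18),
  acrylic     = c(pe = 0.0060, cp = 0.0130, cexp = 0.20),
  # nearly grey on purpose: the electron filter must barely reshape the
  # photon spectrum (its job is stopping electrons, not filtering photons)
  polystyrene = c(pe = 0.0015, cp = 0.0100, cexp = 0.02),
  water       = c(pe = 0.0055, cp = 0.0125, cexp = 0.20)
)

#' Toy linear attenuation coefficient
#'
#' Parametric photon attenuation curve \eqn{\mu(E) = a (E/60)^{-3} +
#' b (E/60)^{-c}} in 1/mm, with `E` in keV. The first term mimics
#' photoelectric absorption (dominant below ~100 keV, where it drives the
#' subject contrast of the aluminium-target beam), the second the slowly
#' falling Compton regime that dominates at megavoltage energies.
#'
#' @param material One of `"aluminum"`, `"brass"`, `"acrylic"`,
#'   `"polystyrene"`, `"water"`.
#' @param energy_kev Photon energy (keV), vectorised.
#' @return Linear attenuation coefficient(s), 1/mm.
#' @export
#' @examples
#' attenuation_coefficient("aluminum", c(60, 150, 2000))
attenuation_coefficient <- function(material, energy_kev) {
  material <- match.arg(material, names(.mu_params))
  if (any(energy_kev <= 0)) {
    stop("`energy_kev` must be positive", call. = FALSE)
  }
  p <- .mu_params[[material]]
  p[["pe"]] * (energy_kev / 60)^-3 + p[["cp"]] * (energy_kev / 60)^-p[["cexp"]]
}
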