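#' Interpret a net O2 : sulfide flux ratio in a mixed community
#'
#' In mats where one dominant sulfur oxidizer coexists with heterotrophs,
#' the steady-state SOB activity alone consumes O2 : H2S = 2y (complete
#' oxidation to sulfate, x = 0 at steady state).  Any excess of the
#' observed ratio over 2y must be aerobic respiration of organic carbon.
#' Relative to the SOB biomass production of 2(1 - y) CH2O per H2S, the
#' recycled fraction is `(observed - 2y) / (2(1 - y))`: exactly 1 at an
#' observed ratio of 2 independent of y (complete internal recycling),
#' below 1 when biomass is exported, above 1 when external reductant is
#' imported and respired within the zone.
#'
#' @param y Fraction of the sulfide pool used for energy generation by the
#'   dominant SOB, in (0, 1\].
#' @param observed_ratio Measured net O2 : sulfide consumption ratio.
#' @param tol Half-width of the "exactly 2" classification band.
#' @return List with `recycled_fraction`, `heterotrophic_o2_share` (moles
#'   O2 per mole sulfide not attributable to the SOB) and a
#'   `classification` string.
#' @examples
#' interpret_o2_h2s(0.8, 2.0)   # complete internal recycling
#' interpret_o2_h2s(0.8, 2.4)   # external reductant import
#' @export
interpret_o2_h2s <- function(y, observed_ratio, tol = 1e-9) {
  if (y <= 0 || y > 1) stop("y must lie in (0, 1]", call. = FALSE)
  if (observed_ratio < 0) {
    stop("observed_ratio must be >= 0", call. = FALSE)
  }
  het <- observed_ratio - 2 * y
  if (het < -tol) {
    stop(sprintf(paste0(
      "observed ratio %.3f is below the SOB-only ratio 2y = %.3f: ",
      "negative heterotrophy; re-estimate y"), observed_ratio, 2 * y),
      call. = FALSE)
  }
  recycled <- if (y == 1) {
    if (het > tol) Inf else 0
  } else {
    het / (2 * (1 - y))
  }
  classification <- if (abs(observed_ratio - 2) <= tol) {
    "complete internal recycling"
  } else if (observed_ratio < 2) {
    "organic carbon export"
  } else {
    "external reductant import"
  }
  list(recycled_fraction = recycled, heterotrophic_o2_share = het,
       classification = classification)
}
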