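#' Tree allometry
#'
#' Derives height, crown diameter, leaf area and above-ground biomass from
#' stem diameter for a given plant functional type. All geometry is a
#' deterministic function of `(pft, dbh)`:
#' \deqn{H = h_0 D^{h_1}, \quad CD = c_0 D, \quad LA = la_0 D^{la_1},}
#' \deqn{B = \frac{\pi}{4} D^2 H \cdot form \cdot \rho}
#' (geometric stem-volume allometry; `B` in t organic dry matter).
#'
#' @param pft a [pft_params()] object.
#' @param dbh stem diameter at breast height (m); vectorized. Must satisfy
#'   `0 < dbh <= d_max`.
#' @return A list with numeric vectors `height` (m), `crown_diameter` (m),
#'   `leaf_area` (m2) and `biomass` (t ODM).
#' @examples
#' p <- default_pfts()[[2]]
#' allometry(p, 0.3)
#' @export
allometry <- function(pft, dbh) {
  if (any(dbh <= 0) || any(dbh > pft$d_max))
    stop("dbh must lie in (0, d_max]")
  height <- pft$h0 * dbh^pft$h1
  list(
    height = height,
    crown_diameter = pft$c0 * dbh,
    leaf_area = pft$la0 * dbh^pft$la1,
    biomass = (pi / 4) * dbh^2 * height * pft$form * pft$rho
  )
}

#' Invert the biomass allometry
#'
#' Recovers stem diameter from above-ground biomass. Because
#' `B = (pi/4) h0 form rho * D^(2 + h1)` is a pure power law, the
#' inversion is closed form; the simulator uses it to convert the
#' stem-allocated share of NPP into a diameter increment.
#'
#' @param pft a [pft_params()] object.
#' @param biomass above-ground biomass (t ODM); vectorized, `>= 0`.
#' @return Stem diameter (m).
#' @export
dbh_from_biomass <- function(pft, biomass) {
  if (any(biomass < 0)) stop("biomass must be >= 0")
  c_b <- (pi / 4) * pft$h0 * pft$form * pft$rho
  (biomass / c_b)^(1 / (2 + pft$h1))
}
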