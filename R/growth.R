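#' Leaf-level light response
#'
#' Saturating light response of leaf-level production,
#' \deqn{p(I) = \frac{\alpha I \, p_{max}}{\alpha I + p_{max}},}
#' with initial slope `alpha` and asymptote `pmax` (t ODM m-2 yr-1).
#'
#' @param light relative light at the crown top, in `[0, 1]`; vectorized.
#' @param alpha initial slope.
#' @param pmax maximum rate.
#' @return Production rate per unit leaf area (t ODM m-2 yr-1).
#' @export
light_response <- function(light, alpha, pmax) {
  if (any(light < 0 | light > 1)) stop("light must lie in [0, 1]")
  num <- alpha * light * pmax
  den <- alpha * light + pmax
  ifelse(den > 0, num / den, 0)
}

#' Annual carbon fluxes of a tree
#'
#' Gross primary production is the leaf-level rate at the light available
#' to the crown top times the tree's leaf area; net primary production is
#' GPP minus maintenance respiration (proportional to biomass), reduced by
#' the growth respiration fraction:
#' \deqn{GPP = p(I) \cdot LA, \qquad
#'       NPP = (1 - r_{growth}) (GPP - r_{main} B).}
#' The reported NPP is floored at zero; a non-positive raw NPP means the
#' tree cannot grow and (via its stalled diameter increment) accumulates
#' stress, which raises its mortality in the simulator.
#'
#' @param pft a [pft_params()] object.
#' @param dbh stem diameter(s) (m).
#' @param light relative light at the crown top, in `[0, 1]`.
#' @return List with vectors `gpp`, `npp` (t ODM yr-1, `npp` floored at 0)
#'   and `npp_raw` (unfloored balance).
#' @export
tree_annual_fluxes <- function(pft, dbh, light) {
  al <- allometry(pft, dbh)
  p <- light_response(light, pft$alpha, pft$pmax)
  gpp <- p * al$leaf_area
  npp_raw <- (1 - pft$r_growth) * (gpp - pft$r_main * al$biomass)
  list(gpp = gpp, npp = pmax(npp_raw, 0), npp_raw = npp_raw)
}
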