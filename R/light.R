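#' Vertical light profile of a patch
#'
#' Computes relative light intensity in vertical layers of a 20 x 20 m
#' patch following a Lambert-Beer extinction through the leaf area of all
#' crowns. A tree's crown occupies the height interval
#' `[height * (1 - f_crown), height]` with its leaf area spread uniformly
#' over the covered layers. Light at the top boundary of layer `j` is
#' \deqn{I(z_j) = \exp(-k \cdot LAI_{above}(z_j))}
#' where `LAI_above` is the summed leaf area strictly above `z_j` divided
#' by the patch area. The profile is non-increasing from the canopy top
#' downward and equals 1 wherever no leaf area lies above.
#'
#' @param heights tree heights (m); may be empty.
#' @param leaf_areas per-tree leaf areas (m2), same length.
#' @param f_crown crown length fraction(s), recycled to the tree count.
#' @param k light extinction coefficient (default 0.6).
#' @param area patch ground area (m2, default 400).
#' @param layer_width internal vertical discretization (m, default 0.5).
#' @param ceiling top of the profile (m, default 100); all trees must be
#'   shorter.
#' @return Numeric vector of length `ceiling / layer_width`; entry `j` is
#'   the relative light at the top boundary of layer `j` (layer `j` spans
#'   `((j-1) * layer_width, j * layer_width]`).
#' @examples
#' compute_light_profile(numeric(0), numeric(0))[1]  # empty patch: 1
#' @export
compute_light_profile <- function(heights, leaf_areas, f_crown = 0.4,
                                  k = 0.6, area = 400, layer_width = 0.5,
                                  ceiling = 100) {
  lad <- leaf_area_density(heights, leaf_areas, f_crown, layer_width,
                           ceiling)
  light_from_lad(lad, k, area)
}

## leaf area per vertical layer (m2), via a range-update difference array
leaf_area_density <- function(heights, leaf_areas, f_crown, layer_width,
                              ceiling) {
  nz <- as.integer(round(ceiling / layer_width))
  if (length(heights) == 0L) return(numeric(nz))
  if (any(heights >= ceiling))
    stop("tree height at or above the profile ceiling")
  f_crown <- rep_len(f_crown, length(heights))
  j_top <- pmax(1L, as.integer(base::ceiling(heights / layer_width)))
  j_bot <- pmin(j_top, as.integer(floor(heights * (1 - f_crown) /
                                          layer_width)) + 1L)
  per_layer <- leaf_areas / (j_top - j_bot + 1L)
  d <- numeric(nz + 1L)
  add <- rowsum(c(per_layer, -per_layer), c(j_bot, j_top + 1L))
  d[as.integer(rownames(add))] <- add[, 1L]
  cumsum(d)[seq_len(nz)]
}

## relative light at each layer's top boundary given a leaf-area-density
## vector; vectorized over the layers of one patch
light_from_lad <- function(lad, k, area) {
  nz <- length(lad)
  ## leaf area strictly above the top boundary of layer j
  la_above <- rev(cumsum(rev(lad)))  # includes layer j itself
  la_above <- c(la_above[-1L], 0)
  exp(-k * la_above / area)
}

## relative light at the forest floor (below all crowns)
floor_light <- function(lad, k, area) exp(-k * sum(lad) / area)
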