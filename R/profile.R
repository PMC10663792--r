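#' Profile discretization specification
#'
#' Fixes the vertical layer width and horizontal cell size at which tree
#' lists are converted into biomass profiles. The profile ceiling is
#' 100 m; simulated trees stay well below it.
#'
#' @param dh vertical layer width (m); one of 2, 10, 20, 100 in the study
#'   design, but any divisor of `ceiling` is accepted.
#' @param cell_edge horizontal cell edge length (m); must be a multiple of
#'   the 20 m patch size.
#' @param ceiling profile top (m, default 100).
#' @return A `profile_spec` list.
#' @export
profile_spec <- function(dh, cell_edge, ceiling = 100) {
  if (ceiling %% dh != 0)
    stop("profile ceiling must be divisible by dh")
  if (cell_edge %% 20 != 0)
    stop("cell_edge must be a multiple of the 20 m patch size")
  structure(list(dh = dh, cell_edge = cell_edge, ceiling = ceiling),
            class = "profile_spec")
}

#' Distribute one tree's biomass over height layers
#'
#' Biomass is assumed uniformly distributed over the height of the tree,
#' so layer `i` (spanning `[i*dh, (i+1)*dh)`, half-open) receives
#' `biomass * overlap([i*dh, (i+1)*dh), [0, height]) / height`. A 56 m
#' tree at `dh = 20` therefore places equal biomass in the 0-20 and
#' 20-40 m layers and 16/56 of it in the 40-60 m layer.
#'
#' @param height tree height (m), `0 < height <= ceiling`.
#' @param biomass tree biomass (t), `>= 0`.
#' @param dh layer width (m).
#' @param ceiling profile top (m, default 100).
#' @return Numeric vector of per-layer biomass (t), length
#'   `ceiling / dh`; sums to `biomass`.
#' @export
tree_layer_biomass <- function(height, biomass, dh, ceiling = 100) {
  if (height <= 0 || height > ceiling)
    stop("height must lie in (0, ceiling]")
  if (biomass < 0) stop("biomass must be >= 0")
  lower <- seq(0, ceiling - dh, by = dh)
  overlap <- pmax(0, pmin(lower + dh, height) - lower)
  biomass * overlap / height
}

## fraction of each tree's height falling into each layer:
## ntrees x nlayer matrix
layer_overlap_frac <- function(heights, dh, ceiling = 100) {
  nl <- as.integer(round(ceiling / dh))
  lower <- seq(0, ceiling - dh, by = dh)
  out <- vapply(seq_len(nl), function(l)
    pmax(0, pmin(lower[l] + dh, heights) - lower[l]) / heights,
    numeric(length(heights)))
  matrix(out, nrow = length(heights), ncol = nl)
}

#' Vertical biomass profile of one forest stand
#'
#' Sums the per-tree layer decompositions of [tree_layer_biomass()] over
#' all trees of one cell and converts to densities (t per hectare of cell
#' ground area).
#'
#' @param trees a data.frame with columns `height` (m) and `biomass` (t);
#'   may have zero rows (empty cell, valid).
#' @param spec a [profile_spec()].
#' @return List with `layers` (t ha-1, length `ceiling / dh`), `agb`
#'   (total density, t ha-1) and the discretization settings.
#' @export
stand_profile <- function(trees, spec) {
  area_ha <- spec$cell_edge^2 / 1e4
  nl <- as.integer(round(spec$ceiling / spec$dh))
  if (nrow(trees) == 0L) {
    layers <- numeric(nl)
  } else {
    if (any(trees$height <= 0)) stop("tree height must be > 0")
    frac <- layer_overlap_frac(trees$height, spec$dh, spec$ceiling)
    layers <- colSums(frac * trees$biomass) / area_ha
  }
  list(layers = layers, agb = sum(layers), spec = spec)
}

## batch version over patches: npatch x nlayer matrix of t/ha densities
patch_profiles <- function(heights, biomass, patch, npatch, dh,
                           ceiling = 100, area_ha = 0.04) {
  nl <- as.integer(round(ceiling / dh))
  out <- matrix(0, npatch, nl)
  if (length(heights) > 0L) {
    frac <- layer_overlap_frac(heights, dh, ceiling)
    acc <- rowsum(frac * biomass, patch)
    out[as.integer(rownames(acc)), ] <- acc
  }
  out / area_ha
}

#' Assign 20 m patches to analysis cells
#'
#' Tiles each simulated plot into square cells of edge `cell_edge`,
#' mapping every 20 m patch to exactly one cell. Patch coordinates are
#' 0-based indices of the 20 m grid within the plot.
#'
#' @param patch_x,patch_y 0-based patch column/row indices.
#' @param cell_edge cell edge length (m); must divide `plot_edge`.
#' @param plot_edge plot edge length (m, default 200).
#' @return data.table with 0-based `cell_x`, `cell_y`.
#' @export
tile_cells <- function(patch_x, patch_y, cell_edge, plot_edge = 200) {
  if (plot_edge %% cell_edge != 0)
    stop("cell_edge must divide plot_edge")
  if (cell_edge %% 20 != 0)
    stop("cell_edge must be a multiple of the 20 m patch size")
  if (any(patch_x < 0 | patch_x >= plot_edge / 20) ||
      any(patch_y < 0 | patch_y >= plot_edge / 20))
    stop("patch coordinates outside plot bounds")
  data.table(cell_x = (patch_x * 20L) %/% as.integer(cell_edge),
             cell_y = (patch_y * 20L) %/% as.integer(cell_edge))
}

#' Coarsen a layer matrix to a wider layer width
#'
#' Sums nested fine layers into coarse layers; exact because layer edges
#' are nested (`to_dh` a multiple of `from_dh`).
#'
#' @param mat matrix with one column per fine layer (or a vector).
#' @param from_dh,to_dh fine and coarse layer widths; `to_dh` must be a
#'   multiple of `from_dh`.
#' @return Matrix with `ncol(mat) * from_dh / to_dh` columns.
#' @export
coarsen_layers <- function(mat, from_dh, to_dh) {
  if (to_dh %% from_dh != 0)
    stop("to_dh must be a multiple of from_dh")
  if (is.vector(mat)) mat <- matrix(mat, nrow = 1)
  fac <- as.integer(to_dh / from_dh)
  nl <- ncol(mat) %/% fac
  out <- matrix(0, nrow(mat), nl)
  for (l in seq_len(nl))
    out[, l] <- rowSums(mat[, ((l - 1L) * fac + 1L):(l * fac),
                            drop = FALSE])
  out
}
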