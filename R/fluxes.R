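#' Aggregate per-tree fluxes to a cell
#'
#' @param trees data.frame with columns `biomass` (t), `gpp_year`,
#'   `npp_year` (t yr-1); zero rows allowed.
#' @param area_ha cell ground area (ha), `> 0`.
#' @return Named numeric vector `agb`, `gpp`, `npp` (t ha-1 (yr-1)).
#' @export
aggregate_fluxes <- function(trees, area_ha) {
  if (area_ha <= 0) stop("area must be > 0")
  c(agb = sum(trees$biomass) / area_ha,
    gpp = sum(trees$gpp_year) / area_ha,
    npp = sum(trees$npp_year) / area_ha)
}

#' Carbon turnover time
#'
#' The carbon turnover time of a stand is its above-ground biomass
#' divided by its gross primary production, `tau = AGB / GPP` (years).
#' Undefined where `GPP = 0`; such records are flagged `NA` and excluded
#' from turnover analyses. A stand with zero biomass has `tau = 0`.
#'
#' @param agb above-ground biomass density (t ha-1); vectorized.
#' @param gpp gross primary production (t ha-1 yr-1).
#' @return Turnover time (yr), `NA` where `gpp == 0`.
#' @export
turnover_time <- function(agb, gpp) {
  ifelse(gpp > 0, agb / gpp, NA_real_)
}

#' Classify stand-years as disturbed or mature
#'
#' Stands younger than the equilibrium onset are "disturbed" (recovering
#' succession); stands at or beyond it are "mature". The boundary year
#' itself is assigned to the mature class.
#'
#' @param year stand age (yr); vectorized.
#' @param boundary equilibrium onset (yr, default 160).
#' @return Character vector, `"disturbed"` or `"mature"`.
#' @export
categorize_by_age <- function(year, boundary = 160) {
  ifelse(year >= boundary, "mature", "disturbed")
}

#' Build the stand-year analysis table
#'
#' Re-grids the simulator's patch-year records to a chosen horizontal
#' cell size and vertical layer width: cell densities are the
#' (area-weighted, here equal-area) means over member patches, and coarse
#' layers are exact sums of the recorded fine layers. Adds turnover time
#' and the disturbed/mature category. This single table is the input to
#' the relationship and boosted-regression-tree analyses.
#'
#' @param sim a `canopy_sim` from [run_succession()].
#' @param cell_edge cell edge length (m): 200 (4 ha), 100 (1 ha) or
#'   20 (0.04 ha).
#' @param dh layer width (m): 100, 20, 10 or 2; must be a multiple of the
#'   recorded profile width.
#' @param boundary mature/disturbed age boundary (yr, default 160).
#' @param drop_year0 drop the bare-ground year-0 rows (default TRUE).
#' @return data.table with `replicate`, `year`, `cell_x`, `cell_y`,
#'   `agb`, `gpp`, `npp`, `tau`, `category` and layer columns `b01` ...
#'   (t ha-1).
#' @export
stand_year_table <- function(sim, cell_edge, dh, boundary = 160,
                             drop_year0 = TRUE) {
  if (dh %% sim$dh_record != 0)
    stop("dh must be a multiple of the recorded profile width")
  spec <- profile_spec(dh, cell_edge, sim$config$ceiling)
  nl_rec <- as.integer(round(sim$config$ceiling / sim$dh_record))
  rec_cols <- sprintf("b%02d", seq_len(nl_rec))

  dt <- sim$patches
  if (drop_year0) dt <- dt[year > 0]
  cells <- tile_cells(dt$patch_x, dt$patch_y, cell_edge,
                      sim$config$plot_edge)
  dt <- cbind(dt[, c("replicate", "year", "agb", "gpp", "npp", rec_cols),
                 with = FALSE], cells)
  agg <- dt[, lapply(.SD, mean),
            by = .(replicate, year, cell_x, cell_y),
            .SDcols = c("agb", "gpp", "npp", rec_cols)]
  layers <- coarsen_layers(as.matrix(agg[, rec_cols, with = FALSE]),
                           sim$dh_record, dh)
  nl <- ncol(layers)
  out <- agg[, c("replicate", "year", "cell_x", "cell_y",
                 "agb", "gpp", "npp"), with = FALSE]
  out[, tau := turnover_time(agb, gpp)]
  out[, category := categorize_by_age(year, boundary)]
  out <- cbind(out, as.data.table(layers))
  setnames(out, tail(names(out), nl), sprintf("b%02d", seq_len(nl)))
  out[]
}

layer_cols <- function(tab) grep("^b[0-9]+$", names(tab), value = TRUE)
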