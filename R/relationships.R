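#' Coefficient of determination of a simple linear fit
#'
#' The squared Pearson correlation of `x` and `y`, which equals the R2 of
#' an ordinary least-squares line of `y` on `x`. Pairs with missing
#' values are dropped.
#'
#' @param x,y numeric vectors, at least 3 complete pairs; `x` must not be
#'   constant. A constant `y` gives 0 by convention.
#' @return R2 in `[0, 1]`.
#' @export
linear_r2 <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (sd(x) == 0) stop("x is constant; R2 undefined")
  if (sd(y) == 0) return(0)
  cor(x, y)^2
}

#' Biomass-flux relationships over succession
#'
#' Computes the pairwise relationships between biomass predictors and the
#' carbon-flux targets across all stand-years of a table at `dh = 20` m:
#' total AGB versus GPP, NPP and turnover time, and the upper-canopy
#' (40-60 m) layer biomass versus GPP, NPP, turnover time and total AGB.
#' Each result carries the OLS R2 and the raw scatter for plotting.
#'
#' @param tab a [stand_year_table()] built with `dh = 20`.
#' @return data.table with `predictor`, `target`, `n`, `r2`, and a
#'   `scatter` list-column of `(x, y, year)` tables.
#' @export
relationship_suite <- function(tab) {
  lc <- layer_cols(tab)
  if (length(lc) != 5)
    stop("expected a dh = 20 table (5 layer columns)")
  layer46 <- tab[[lc[3]]]  # 40-60 m layer
  cases <- list(
    list(p = "agb",        x = tab$agb, t = "gpp"),
    list(p = "agb",        x = tab$agb, t = "npp"),
    list(p = "agb",        x = tab$agb, t = "tau"),
    list(p = "layer_40_60", x = layer46, t = "gpp"),
    list(p = "layer_40_60", x = layer46, t = "npp"),
    list(p = "layer_40_60", x = layer46, t = "tau"),
    list(p = "layer_40_60", x = layer46, t = "agb")
  )
  rbindlist(lapply(cases, function(cs) {
    y <- tab[[cs$t]]
    ok <- is.finite(cs$x) & is.finite(y)
    ## a degenerate (constant) predictor is reported as NA, not an error
    r2 <- tryCatch(linear_r2(cs$x, y), error = function(e) NA_real_)
    data.table(predictor = cs$p, target = cs$t, n = sum(ok),
               r2 = r2,
               scatter = list(data.table(x = cs$x[ok], y = y[ok],
                                         year = tab$year[ok])))
  }))
}
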