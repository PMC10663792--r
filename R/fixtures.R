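#' Laplace-distributed random numbers
#'
#' Inverse-CDF sampler for the double-exponential distribution with
#' location 0 and scale `b` (variance `2 b^2`). Included because the BRT
#' stage uses an absolute-error (Laplace) loss, so recovery tests can
#' exercise the matched-noise case.
#'
#' @param n number of draws.
#' @param b scale parameter, `>= 0`.
#' @return Numeric vector.
#' @export
rlaplace <- function(n, b) {
  if (b < 0) stop("scale must be >= 0")
  u <- runif(n) - 0.5
  -b * sign(u) * log(1 - 2 * abs(u))
}

#' Synthetic tree list for one stand
#'
#' Generates a reproducible standalone tree list with prescribed height
#' and biomass distributions, for unit-testing the profile and flux
#' stages without running the simulator. Heights are uniform or
#' truncated log-normal on `(0, 100]`; biomass follows a power-law
#' coupling `b0 * height^b_exp` with optional log-normal multiplicative
#' scatter.
#'
#' @param n_trees number of trees (0 allowed).
#' @param height_dist `"uniform"` or `"lognormal"`.
#' @param hmin,hmax uniform bounds (m).
#' @param meanlog,sdlog log-normal parameters (truncated to
#'   `(0, 100]`).
#' @param b0,b_exp biomass-height coupling coefficients (t, -).
#' @param b_cv log-scale standard deviation of multiplicative biomass
#'   scatter (0 = deterministic coupling).
#' @param seed optional RNG seed.
#' @return data.table with columns `height` (m), `biomass` (t),
#'   `gpp_year`, `npp_year` (t yr-1, proportional to biomass) and
#'   `patch` (all 1).
#' @export
make_stand <- function(n_trees, height_dist = "uniform", hmin = 2,
                       hmax = 50, meanlog = 2.5, sdlog = 0.6,
                       b0 = 0.002, b_exp = 2.2, b_cv = 0,
                       seed = NULL) {
  height_dist <- match.arg(height_dist, c("uniform", "lognormal"))
  if (!is.null(seed)) set.seed(seed)
  if (n_trees == 0L)
    return(data.table(height = numeric(0), biomass = numeric(0),
                      gpp_year = numeric(0), npp_year = numeric(0),
                      patch = integer(0)))
  h <- if (height_dist == "uniform") runif(n_trees, hmin, hmax)
  else {
    x <- rlnorm(n_trees, meanlog, sdlog)
    while (any(bad <- x > 100 | x <= 0))
      x[bad] <- rlnorm(sum(bad), meanlog, sdlog)
    x
  }
  b <- b0 * h^b_exp
  if (b_cv > 0) b <- b * rlnorm(n_trees, -b_cv^2 / 2, b_cv)
  data.table(height = h, biomass = b, gpp_year = 0.15 * b,
             npp_year = 0.05 * b, patch = 1L)
}

#' Feature-target regression fixture with a known generating function
#'
#' Draws independent features, applies a known generating function and
#' adds noise with a known variance, returning the analytic R2 ceiling
#' `var(f) / (var(f) + var(noise))` that any regression can at best
#' attain on held-out data (signal variance taken from the realized
#' sample; Laplace noise has variance `2 b^2`).
#'
#' @param n_rows number of rows.
#' @param n_features number of independent features (uniform on
#'   `[0, 1]`).
#' @param fun generating function: `"linear"` (weighted sum),
#'   `"saturating"` (Michaelis-Menten in the feature sum) or
#'   `"layered_sum"` (sum of the first two features, mimicking two
#'   informative biomass layers).
#' @param noise `"none"`, `"gaussian"` or `"laplace"`.
#' @param noise_scale standard deviation (gaussian) or scale `b`
#'   (laplace); `>= 0`.
#' @param seed optional RNG seed.
#' @return List: `features` (matrix), `target`, `f` (noise-free signal),
#'   `r2_ceiling`, `noise_var`.
#' @export
make_regression_fixture <- function(n_rows, n_features = 5,
                                    fun = "layered_sum",
                                    noise = "none", noise_scale = 0,
                                    seed = NULL) {
  fun <- match.arg(fun, c("linear", "saturating", "layered_sum"))
  noise <- match.arg(noise, c("none", "gaussian", "laplace"))
  if (noise_scale < 0) stop("noise scale must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(runif(n_rows * n_features), n_rows, n_features,
              dimnames = list(NULL, sprintf("b%02d", seq_len(n_features))))
  f <- switch(fun,
    linear = drop(x %*% seq_len(n_features)),
    saturating = { s <- rowSums(x); 3 * s / (1 + s) },
    layered_sum = x[, 1] + x[, pmin(2L, n_features)])
  eps <- switch(noise,
    none = rep(0, n_rows),
    gaussian = rnorm(n_rows, 0, noise_scale),
    laplace = rlaplace(n_rows, noise_scale))
  noise_var <- switch(noise, none = 0, gaussian = noise_scale^2,
                      laplace = 2 * noise_scale^2)
  vf <- var(f)
  list(features = x, target = f + eps, f = f,
       r2_ceiling = if (vf + noise_var == 0) 0
       else vf / (vf + noise_var),
       noise_var = noise_var)
}
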