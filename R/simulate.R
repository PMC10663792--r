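#' Simulation configuration
#'
#' Settings for the gap-model run. The study design simulates 25
#' replicate 200 x 200 m plots (100 ha total) over 320 years at an annual
#' time step; the model's internal horizontal resolution is the 20 x 20 m
#' patch.
#'
#' @param plot_edge plot edge length (m, default 200); must be a multiple
#'   of 20.
#' @param n_replicates number of independent replicate plots (default 25).
#' @param years simulated years (default 320, `>= 1`).
#' @param rng_seed root seed; each replicate derives its own stream as
#'   `rng_seed + 10000 * replicate`.
#' @param k light extinction coefficient (default 0.6).
#' @param light_layer_width internal vertical light discretization
#'   (m, default 0.5).
#' @param ceiling vertical profile top (m, default 100).
#' @param dbh_min stem diameter of newly established trees (m, default
#'   0.01).
#' @param stress_rel_incr relative annual diameter increment below which a
#'   year counts as a stress year (default 0.003).
#' @param stress_years consecutive stress years that trigger elevated
#'   mortality (default 2).
#' @param stress_mort extra annual mortality probability under sustained
#'   stress (default 0.1).
#' @param f_stem fraction of NPP available to stem growth before the
#'   size-dependent allocation factor (default 0.52); the remainder goes
#'   to leaves, roots and reproduction, which are not tracked.
#' @param crowd_mort_max cap on the annual crowding mortality probability
#'   (default 0.03).
#' @param p_fall probability that a dying tree above `fall_height` falls
#'   (default 0.4).
#' @param fall_height minimum height (m) for treefall (default 18).
#' @param damage_p damage probability scaling for trees in the impacted
#'   area (default 0.8).
#' @param pfts list of [pft_params()]; default [default_pfts()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(plot_edge = 200, n_replicates = 25, years = 320,
                       rng_seed = 1, k = 0.6, light_layer_width = 0.5,
                       ceiling = 100, dbh_min = 0.01,
                       stress_rel_incr = 0.003, stress_years = 2,
                       stress_mort = 0.1, f_stem = 0.52,
                       crowd_mort_max = 0.03, p_fall = 0.5,
                       fall_height = 18, damage_p = 0.6,
                       pfts = default_pfts()) {
  if (plot_edge %% 20 != 0) stop("plot_edge must be divisible by 20")
  if (years < 1) stop("years must be >= 1")
  for (p in pfts) validate_pft(p, ceiling)
  structure(list(
    plot_edge = plot_edge, n_replicates = n_replicates, years = years,
    rng_seed = rng_seed, k = k, light_layer_width = light_layer_width,
    ceiling = ceiling, dbh_min = dbh_min,
    stress_rel_incr = stress_rel_incr, stress_years = stress_years,
    stress_mort = stress_mort, f_stem = f_stem,
    crowd_mort_max = crowd_mort_max, p_fall = p_fall,
    fall_height = fall_height, damage_p = damage_p, pfts = pfts
  ), class = "sim_config")
}

## per-pft parameter vectors for vectorized lookup
pft_vectors <- function(pfts) {
  g <- function(f) vapply(pfts, `[[`, numeric(1), f)
  list(h0 = g("h0"), h1 = g("h1"), c0 = g("c0"), f_crown = g("f_crown"),
       la0 = g("la0"), la1 = g("la1"), rho = g("rho"), form = g("form"),
       alpha = g("alpha"), pmax = g("pmax"), r_main = g("r_main"),
       r_growth = g("r_growth"), m_b = g("m_b"), d_max = g("d_max"),
       i_seed = g("i_seed"), i_min = g("i_min"),
       c_b = (pi / 4) * g("h0") * g("form") * g("rho"))
}

#' Empty landscape (bare ground)
#'
#' @param config a [sim_config()].
#' @return A `landscape` state: a data.table with one row per living tree
#'   (`pft`, `patch`, `dbh`, `biomass`, `stress`, `gpp`, `npp`, `alloc`).
#' @export
new_landscape <- function(config) {
  data.table(pft = integer(0), patch = integer(0), dbh = numeric(0),
             biomass = numeric(0), stress = integer(0), gpp = numeric(0),
             npp = numeric(0), alloc = numeric(0))
}

#' Advance the landscape by one year
#'
#' Executes, per patch: (1) the vertical light profile; (2) per-tree
#' fluxes and growth — the stem-allocated share
#' `f_stem * (1 - dbh / d_max)` of a
#' tree's NPP is added to its biomass and inverted through the allometry
#' into a diameter increment; (3) mortality — background, stress (two
#' consecutive years of relative diameter increment below threshold),
#' crown crowding at the tree's own canopy level, and treefall
#' damage from dying tall trees; (4) establishment — Poisson seedling
#' ingrowth per PFT in patches whose floor light exceeds the type's
#' minimum. All stochastic draws use R's global RNG; seed it for
#' reproducibility.
#'
#' @param state a landscape data.table (see [new_landscape()]).
#' @param config a [sim_config()].
#' @return List: `state` (next year's landscape), `patch` (data.table
#'   with per-patch `agb` in t — end of year — and `gpp`, `npp` in t yr-1
#'   summed over trees alive during growth), `floor_light` (per patch).
#' @export
annual_step <- function(state, config) {
  pv <- pft_vectors(config$pfts)
  np_side <- config$plot_edge %/% 20L
  npatch <- np_side * np_side
  area <- 400                      # patch ground area, m2
  lw <- config$light_layer_width
  nz <- as.integer(round(config$ceiling / lw))
  k <- config$k

  n <- nrow(state)
  pid <- state$pft
  pidx <- state$patch
  dbh <- state$dbh
  biomass <- state$biomass

  ## ---- (1) light ----
  height <- pv$h0[pid] * dbh^pv$h1[pid]
  la <- pv$la0[pid] * dbh^pv$la1[pid]
  lad <- matrix(0, nz + 1L, npatch)
  if (n > 0L) {
    j_top <- pmax(1L, as.integer(ceiling(height / lw)))
    j_bot <- pmin(j_top, as.integer(floor(height *
      (1 - pv$f_crown[pid]) / lw)) + 1L)
    per_layer <- la / (j_top - j_bot + 1L)
    idx <- c(j_bot, j_top + 1L) + (nz + 1L) * (rep(pidx, 2L) - 1L)
    add <- rowsum(c(per_layer, -per_layer), idx)
    lad[as.integer(rownames(add))] <- add[, 1L]
  }
  lad <- apply(lad, 2L, cumsum)[seq_len(nz), , drop = FALSE]
  cum_above <- apply(lad[nz:1L, , drop = FALSE], 2L, cumsum)[nz:1L, ,
                                                             drop = FALSE]
  light_mat <- exp(-k / area * rbind(cum_above[-1L, , drop = FALSE],
                                     rep(0, npatch)))
  fl <- exp(-k / area * cum_above[1L, ])  # forest-floor light

  ## ---- (2) fluxes and growth ----
  if (n > 0L) {
    light <- light_mat[cbind(j_top, pidx)]
    p_leaf <- pv$alpha[pid] * light * pv$pmax[pid] /
      (pv$alpha[pid] * light + pv$pmax[pid])
    gpp <- p_leaf * la
    npp_raw <- (1 - pv$r_growth[pid]) * (gpp - pv$r_main[pid] * biomass)
    npp <- pmax(npp_raw, 0)
    alloc <- config$f_stem * pmax(0, 1 - dbh / pv$d_max[pid])
    b_new <- biomass + alloc * npp
    dbh_new <- (b_new / pv$c_b[pid])^(1 / (2 + pv$h1[pid]))
    rel_incr <- (dbh_new - dbh) / dbh
    stress <- ifelse(rel_incr < config$stress_rel_incr,
                     state$stress + 1L, 0L)
    gpp_patch <- patch_sum(gpp, pidx, npatch)
    npp_patch <- patch_sum(npp, pidx, npatch)

    ## ---- (3) mortality ----
    ## crowding: a tree competes for horizontal space with the crowns
    ## that overlap its own crown-top level; when their summed projection
    ## area exceeds the patch area the excess is thinned. Computed on the
    ## 0.5 m layer grid via a crown-area density matrix.
    cd_new <- pv$c0[pid] * dbh_new
    ca <- (pi / 4) * cd_new^2
    h_new <- pv$h0[pid] * dbh_new^pv$h1[pid]
    jt2 <- pmax(1L, as.integer(ceiling(h_new / lw)))
    jb2 <- pmin(jt2, as.integer(floor(h_new *
      (1 - pv$f_crown[pid]) / lw)) + 1L)
    cad <- matrix(0, nz + 1L, npatch)
    idx2 <- c(jb2, jt2 + 1L) + (nz + 1L) * (rep(pidx, 2L) - 1L)
    add2 <- rowsum(c(ca, -ca), idx2)
    cad[as.integer(rownames(add2))] <- add2[, 1L]
    cad <- apply(cad, 2L, cumsum)
    cca <- cad[cbind(jt2, pidx)] - ca  # competing crown area at own top
    p_crowd <- pmin(config$crowd_mort_max,
                    pmax(0, 1 - area / (cca + ca)))
    p_crowd[cca <= 0] <- 0
    p_bg <- pv$m_b[pid]
    p_stress <- ifelse(stress >= config$stress_years,
                       config$stress_mort, 0)
    p_die <- 1 - (1 - p_bg) * (1 - p_stress) * (1 - p_crowd)
    dies <- runif(n) < p_die

    ## treefall: dying tall trees may fall onto their own or a
    ## neighbouring patch (toroidal 20 m grid) and damage the trees there
    faller <- which(dies & h_new > config$fall_height &
                      runif(n) < config$p_fall)
    pressure <- numeric(npatch)
    if (length(faller) > 0L) {
      dirs <- sample.int(5L, length(faller), replace = TRUE)
      tgt <- neighbour_patch(pidx[faller], dirs, np_side)
      dmg <- rowsum(config$damage_p * ca[faller] / area, tgt)
      pressure[as.integer(rownames(dmg))] <- pmin(1, dmg[, 1L])
    }
    crushed <- runif(n) < pressure[pidx]
    dies <- dies | crushed

    keep <- !dies
    state_next <- data.table(
      pft = pid[keep], patch = pidx[keep], dbh = dbh_new[keep],
      biomass = b_new[keep], stress = stress[keep], gpp = gpp[keep],
      npp = npp[keep], alloc = alloc[keep])
  } else {
    gpp_patch <- npp_patch <- numeric(npatch)
    state_next <- new_landscape(config)
  }

  ## ---- (4) establishment ----
  recruits <- vector("list", length(config$pfts))
  for (f in seq_along(config$pfts)) {
    open <- which(fl >= pv$i_min[f])
    if (length(open) == 0L) next
    n_new <- rpois(length(open), pv$i_seed[f] * area / 1e4)
    tot <- sum(n_new)
    if (tot == 0L) next
    d0 <- config$dbh_min
    b0 <- pv$c_b[f] * d0^(2 + pv$h1[f])
    recruits[[f]] <- data.table(
      pft = rep(f, tot), patch = rep(open, n_new),
      dbh = rep(d0, tot), biomass = rep(b0, tot),
      stress = rep(0L, tot), gpp = rep(0, tot), npp = rep(0, tot),
      alloc = rep(1, tot))
  }
  recruits <- recruits[!vapply(recruits, is.null, logical(1))]
  if (length(recruits) > 0L)
    state_next <- rbindlist(c(list(state_next), recruits))

  agb_patch <- patch_sum(state_next$biomass, state_next$patch, npatch)
  list(state = state_next,
       patch = data.table(patch = seq_len(npatch), agb = agb_patch,
                          gpp = gpp_patch, npp = npp_patch),
       floor_light = fl)
}

patch_sum <- function(x, patch, npatch) {
  out <- numeric(npatch)
  if (length(x) > 0L) {
    s <- rowsum(x, patch)
    out[as.integer(rownames(s))] <- s[, 1L]
  }
  out
}

## von Neumann neighbour on a toroidal patch grid; dir 5 = stay
neighbour_patch <- function(patch, dir, np_side) {
  px <- (patch - 1L) %% np_side
  py <- (patch - 1L) %/% np_side
  px <- px + (dir == 1L) - (dir == 2L)
  py <- py + (dir == 3L) - (dir == 4L)
  px <- px %% np_side
  py <- py %% np_side
  py * np_side + px + 1L
}

#' Simulate forest succession from bare ground
#'
#' Runs the gap model for each replicate plot with an independent seeded
#' RNG stream and records annual state. Two recording modes: `"patch"`
#' (default) stores one row per patch-year with AGB, GPP, NPP and the
#' fine (`dh = 2` m) vertical biomass profile, from which all coarser
#' analysis resolutions derive; `"trees"` additionally stores full
#' per-tree tables every `thin_years` years.
#'
#' @param config a [sim_config()].
#' @param record `"patch"` or `"trees"`.
#' @param dh_record layer width of the recorded patch profiles
#'   (m, default 2).
#' @param thin_years tree-table recording interval (default 1).
#' @return A `canopy_sim` list: `plots` (per replicate-year AGB/GPP/NPP in
#'   t ha-1 (yr-1), including a zero year-0 row), `patches` (per
#'   patch-year densities plus profile columns `b01`, `b02`, ...),
#'   `trees` (NULL unless requested), `config`.
#' @export
run_succession <- function(config = sim_config(), record = "patch",
                           dh_record = 2, thin_years = 1) {
  record <- match.arg(record, c("patch", "trees"))
  np_side <- config$plot_edge %/% 20L
  npatch <- np_side * np_side
  nl <- as.integer(round(config$ceiling / dh_record))
  pv <- pft_vectors(config$pfts)
  plot_area_ha <- config$plot_edge^2 / 1e4

  patch_list <- vector("list", config$n_replicates)
  tree_list <- list()
  for (rep_i in seq_len(config$n_replicates)) {
    set.seed(config$rng_seed + 10000L * rep_i)
    state <- new_landscape(config)
    yearly <- vector("list", config$years)
    for (yr in seq_len(config$years)) {
      step <- annual_step(state, config)
      state <- step$state
      h <- pv$h0[state$pft] * state$dbh^pv$h1[state$pft]
      prof <- patch_profiles(h, state$biomass, state$patch, npatch,
                             dh_record, config$ceiling, 0.04)
      yearly[[yr]] <- cbind(year = yr, patch = seq_len(npatch),
                            agb = step$patch$agb / 0.04,
                            gpp = step$patch$gpp / 0.04,
                            npp = step$patch$npp / 0.04, prof)
      if (record == "trees" && yr %% thin_years == 0L) {
        tree_list[[length(tree_list) + 1L]] <- data.table(
          replicate = rep_i, year = yr, patch = state$patch,
          pft = state$pft, dbh = state$dbh, height = h,
          biomass = state$biomass, gpp_year = state$gpp,
          npp_year = state$npp)
      }
    }
    m <- do.call(rbind, yearly)
    dt <- as.data.table(m)
    setnames(dt, 6:(5 + nl), sprintf("b%02d", seq_len(nl)))
    dt[, replicate := rep_i]
    ## bare-ground year-0 rows
    zero <- dt[year == 1][, c("agb", "gpp", "npp",
                              sprintf("b%02d", seq_len(nl))) := 0]
    zero[, year := 0]
    patch_list[[rep_i]] <- rbindlist(list(zero, dt))
  }
  patches <- rbindlist(patch_list)
  setcolorder(patches, c("replicate", "year", "patch"))
  patches[, `:=`(patch_x = as.integer((patch - 1L) %% np_side),
                 patch_y = as.integer((patch - 1L) %/% np_side))]
  plots <- patches[, .(agb = mean(agb), gpp = mean(gpp),
                       npp = mean(npp)), by = .(replicate, year)]
  structure(list(plots = plots, patches = patches,
                 trees = if (record == "trees") rbindlist(tree_list),
                 config = config, dh_record = dh_record),
            class = "canopy_sim")
}
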