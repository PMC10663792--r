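#' Write and read tree-state tables
#'
#' CSV interchange for per-tree annual records with columns `replicate`,
#' `year`, `patch_x`, `patch_y`, `pft`, `dbh_m`, `height_m`, `biomass_t`,
#' `gpp_t_yr`, `npp_t_yr` (one row per tree-year). Numbers are written
#' with 6 significant digits.
#'
#' @param trees a tree table as produced by
#'   `run_succession(record = "trees")$trees`.
#' @param path output file.
#' @param plot_edge plot edge (m) used to derive patch coordinates.
#' @return `path`, invisibly.
#' @export
write_tree_table <- function(trees, path, plot_edge = 200) {
  np_side <- plot_edge %/% 20L
  out <- data.table(
    replicate = trees$replicate, year = trees$year,
    patch_x = as.integer((trees$patch - 1L) %% np_side),
    patch_y = as.integer((trees$patch - 1L) %/% np_side),
    pft = trees$pft,
    dbh_m = signif(trees$dbh, 6), height_m = signif(trees$height, 6),
    biomass_t = signif(trees$biomass, 6),
    gpp_t_yr = signif(trees$gpp_year, 6),
    npp_t_yr = signif(trees$npp_year, 6))
  fwrite(out, path)
  invisible(path)
}

#' @rdname write_tree_table
#' @export
read_tree_table <- function(path) fread(path)

#' Default configuration
#'
#' The full configuration of the study pipeline as a nested list with
#' sections `simulation` (see [sim_config()]), `pfts` (the calibrated
#' four-type set), `profile` (layer widths and cell edges), `brt` (grid
#' axes, split rule, folds) and `fixtures`.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  sc <- unclass(sim_config())
  list(
    simulation = sc[setdiff(names(sc), "pfts")],
    pfts = lapply(default_pfts(), function(p) unclass(p)),
    profile = list(dhs = c(100, 20, 10, 2),
                   cell_edges = c(200, 100, 20)),
    brt = list(learning_rates = c(0.05, 0.01, 0.005),
               bag_fractions = c(0.3, 0.5, 0.66),
               cv_folds = 10, fraction = 0.5, cap = 15900,
               boundary = 160),
    fixtures = list(n_trees = 100, height_dist = "uniform")
  )
}

#' Write or read a configuration file
#'
#' Configurations are stored as YAML (key-value with nesting).
#'
#' @param config a configuration list (see [default_config()]).
#' @param path file path.
#' @return `read_config` returns the configuration list; `write_config`
#'   returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) yaml::read_yaml(path)

config_to_sim <- function(config) {
  s <- config$simulation
  pfts <- lapply(config$pfts, function(p) do.call(pft_params, p))
  do.call(sim_config, c(s, list(pfts = pfts)))
}

#' Run the full virtual experiment
#'
#' End-to-end pipeline: simulate succession, derive stand-year tables at
#' all resolution combinations, compute the biomass-flux relationship
#' R2 table, run the BRT resolution sweep for all forest categories, and
#' write every result as CSV plus a JSON run manifest.
#'
#' @param out_dir output directory (created if missing).
#' @param config configuration list (default [default_config()]).
#' @param seed overrides the configured root seed if non-NULL.
#' @param quick reduced setting for smoke runs: 5 replicates and 2
#'   learning rates (as in the study's reduced sweep).
#' @param verbose print progress.
#' @return Invisibly, a list with the in-memory results (`sim`,
#'   `relationships`, `sweep`, `manifest`).
#' @export
reproduce_study <- function(out_dir, config = default_config(),
                            seed = NULL, quick = FALSE,
                            verbose = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(seed)) config$simulation$rng_seed <- seed
  if (quick) {
    config$simulation$n_replicates <- 5
    config$brt$learning_rates <- c(0.05, 0.01)
    config$brt$cv_folds <- min(config$brt$cv_folds, 5)
  }
  cfg <- config_to_sim(config)
  say <- function(...) if (verbose) message(sprintf(...))

  say("simulating %d replicates x %d years ...",
      cfg$n_replicates, cfg$years)
  sim <- run_succession(cfg)

  paths <- list(config = file.path(out_dir, "config.yaml"),
                plots = file.path(out_dir, "plot_series.csv"),
                relationships = file.path(out_dir,
                                          "relationship_r2.csv"),
                sweep = file.path(out_dir, "brt_r2_matrix.csv"),
                scatter = file.path(out_dir,
                                    "brt_prediction_scatter.csv"),
                manifest = file.path(out_dir, "manifest.json"))
  write_config(config, paths$config)
  fwrite(sim$plots[, lapply(.SD, signif, 6)], paths$plots)

  say("biomass-flux relationships at the coarsest cell size, dh = 20 ...")
  tab20 <- stand_year_table(sim, max(config$profile$cell_edges), 20,
                            boundary = config$brt$boundary)
  rel <- relationship_suite(tab20)
  fwrite(rel[, .(predictor, target, n, r2 = signif(r2, 6))],
         paths$relationships)

  say("BRT resolution sweep ...")
  sweep <- resolution_sweep(
    sim, cell_edges = config$profile$cell_edges,
    dhs = config$profile$dhs, seed = cfg$rng_seed,
    learning_rates = config$brt$learning_rates,
    bag_fractions = config$brt$bag_fractions,
    cv_folds = config$brt$cv_folds,
    fraction = config$brt$fraction, cap = config$brt$cap,
    boundary = config$brt$boundary, keep_predictions = TRUE,
    verbose = verbose)
  out_sweep <- sweep[, !"scatter"]
  num <- vapply(out_sweep, is.numeric, logical(1))
  out_sweep[, names(out_sweep)[num] := lapply(.SD, signif, 6),
            .SDcols = num]
  fwrite(out_sweep, paths$sweep)

  ## per-panel prediction scatters (NPP at the four headline cases)
  sc <- sweep[target == "npp" & category == "all" &
                cell_edge %in% c(200, 20) & dh %in% c(20, 2) &
                !vapply(scatter, is.null, logical(1))]
  sc_tab <- if (nrow(sc) > 0) {
    rbindlist(lapply(seq_len(nrow(sc)), function(i)
      cbind(sc[i, .(target, cell_edge, dh)], sc$scatter[[i]])))
  } else {
    data.table(target = character(0), cell_edge = numeric(0),
               dh = numeric(0), predicted = numeric(0),
               reference = numeric(0), year = numeric(0))
  }
  num_sc <- vapply(sc_tab, is.numeric, logical(1))
  if (nrow(sc_tab) > 0)
    sc_tab[, names(sc_tab)[num_sc] := lapply(.SD, signif, 6),
           .SDcols = names(sc_tab)[num_sc]]
  fwrite(sc_tab, paths$scatter)

  manifest <- list(
    package_version = as.character(utils::packageVersion("canopyflux")),
    rng_seed = cfg$rng_seed, quick = quick,
    timestamp = format(Sys.time(), tz = "UTC"),
    outputs = lapply(paths[names(paths) != "manifest"], normalizePath))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  for (p in unlist(paths))
    if (!file.exists(p) || file.size(p) == 0)
      stop("manifest check failed: missing or empty output ", p)
  invisible(list(sim = sim, relationships = rel, sweep = sweep,
                 manifest = manifest))
}
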