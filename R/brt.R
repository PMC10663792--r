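#' Hyperparameter grid for boosted regression trees
#'
#' Enumerates the tested combinations of learning rate, bag fraction and
#' tree complexity. Tree complexity depends on the vertical resolution of
#' the feature set: 3 for layer widths of 20 and 100 m, 5 for 10 m, and
#' both 5 and 7 for 2 m — giving 9 grid points for `dh` in
#' \{100, 20, 10\} and 18 for `dh = 2`.
#'
#' @param dh vertical layer width (m) of the feature set.
#' @param learning_rates shrinkage values (default `c(0.05, 0.01,
#'   0.005)`).
#' @param bag_fractions stochastic subsample fractions (default
#'   `c(0.3, 0.5, 0.66)`).
#' @param tree_complexities override the depth set implied by `dh`.
#' @return data.table with columns `learning_rate`, `bag_fraction`,
#'   `tree_complexity`.
#' @export
brt_grid <- function(dh, learning_rates = c(0.05, 0.01, 0.005),
                     bag_fractions = c(0.3, 0.5, 0.66),
                     tree_complexities = NULL) {
  if (is.null(tree_complexities)) {
    tree_complexities <- if (dh %in% c(20, 100)) 3
    else if (dh == 10) 5
    else if (dh == 2) c(5, 7)
    else stop("no tree-complexity rule for dh = ", dh)
  }
  as.data.table(expand.grid(learning_rate = learning_rates,
                            bag_fraction = bag_fractions,
                            tree_complexity = tree_complexities,
                            KEEP.OUT.ATTRS = FALSE))
}

#' Random training/validation split with a cap
#'
#' Uniformly random split without replacement: the training set holds
#' `floor(fraction * n)` points but at most `cap` (15 900 in the study
#' design); the remainder is the validation set.
#'
#' @param n number of rows.
#' @param fraction training fraction (default 0.5).
#' @param cap maximum training size (default 15900).
#' @param seed optional seed for a reproducible split.
#' @return List with integer index vectors `train` and `validation`.
#' @export
split_train_validation <- function(n, fraction = 0.5, cap = 15900,
                                   seed = NULL) {
  if (n < 2) stop("need at least 2 rows to split")
  if (!is.null(seed)) set.seed(seed)
  n_train <- min(floor(fraction * n), cap)
  train <- sort(sample.int(n, n_train))
  list(train = train, validation = setdiff(seq_len(n), train))
}

#' Fit a boosted regression tree ensemble
#'
#' Stage-wise gradient boosting of depth-limited regression trees with
#' shrinkage and stochastic subsampling, minimizing absolute-error
#' (Laplace) loss. The number of boosting stages is chosen by k-fold
#' cross-validated early stopping on the training data; the final
#' ensemble is refit on the full training set with that stage count.
#'
#' @param x numeric feature matrix.
#' @param y numeric target vector.
#' @param learning_rate shrinkage per stage.
#' @param bag_fraction row subsample fraction per stage.
#' @param tree_complexity maximum tree depth.
#' @param cv_folds folds for stage selection (default 10).
#' @param nrounds_max stage budget; default scales inversely with the
#'   learning rate (`min(4000, round(10 / learning_rate))`).
#' @param early_stopping stop after this many stages without CV
#'   improvement (default 30).
#' @param seed integer seed for xgboost's internal RNG (bagging).
#' @param nthread threads (default 1, reproducible).
#' @return A `brt_fit` list: `model` (xgboost handle or a constant),
#'   `best_iter`, `cv_loss` (minimum cross-validated mean absolute
#'   error), `config`, `constant`.
#' @export
fit_brt <- function(x, y, learning_rate, bag_fraction, tree_complexity,
                    cv_folds = 10, nrounds_max = NULL,
                    early_stopping = 30, seed = 0, nthread = 1) {
  x <- as.matrix(x)
  if (length(unique(y)) < 2) {
    warning("constant target; returning a constant predictor")
    return(structure(list(model = y[1], best_iter = 0L, cv_loss = 0,
                          constant = TRUE,
                          config = list(learning_rate = learning_rate,
                                        bag_fraction = bag_fraction,
                                        tree_complexity = tree_complexity)),
                     class = "brt_fit"))
  }
  if (is.null(nrounds_max))
    nrounds_max <- min(4000, round(10 / learning_rate))
  ## CV fold assignment draws from R's RNG; pin it so a fit is a pure
  ## function of (data, config, seed), restoring the caller's stream
  if (exists(".Random.seed", envir = globalenv())) {
    old_rng <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_rng, envir = globalenv()))
  }
  set.seed(seed + 1L)
  params <- xgboost::xgb.params(
    objective = "reg:absoluteerror", eta = learning_rate,
    max_depth = tree_complexity, subsample = bag_fraction,
    tree_method = "hist", nthread = nthread, seed = seed)
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = nthread)
  cv <- xgboost::xgb.cv(params = params, data = dtrain,
                        nrounds = nrounds_max, nfold = cv_folds,
                        early_stopping_rounds = early_stopping,
                        verbose = 0)
  log <- cv$evaluation_log
  loss_col <- grep("^test_.*_mean$", names(log), value = TRUE)[1]
  best_iter <- if (!is.null(cv$best_iteration)) cv$best_iteration
  else which.min(log[[loss_col]])
  cv_loss <- log[[loss_col]][best_iter]
  model <- xgboost::xgb.train(params = params, data = dtrain,
                              nrounds = best_iter, verbose = 0)
  structure(list(model = model, best_iter = best_iter,
                 cv_loss = cv_loss, constant = FALSE,
                 config = list(learning_rate = learning_rate,
                               bag_fraction = bag_fraction,
                               tree_complexity = tree_complexity)),
            class = "brt_fit")
}

#' @export
predict.brt_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (isTRUE(object$constant))
    return(rep(object$model, nrow(newdata)))
  predict(object$model, newdata)
}

#' Prediction accuracy on a validation set
#'
#' @param predicted,reference numeric vectors of equal positive length.
#' @return List: `r2` (squared Pearson correlation; 0 by convention if
#'   the predictions are constant), `rmse` (same units as the target),
#'   and `r2_ss` (`1 - SSres / SStot`, reported for transparency).
#' @export
evaluate_predictions <- function(predicted, reference) {
  if (length(predicted) == 0L || length(predicted) != length(reference))
    stop("predicted and reference must be non-empty and equal length")
  r2 <- if (sd(predicted) == 0 || sd(reference) == 0) 0
  else cor(predicted, reference)^2
  list(r2 = r2,
       rmse = sqrt(mean((predicted - reference)^2)),
       r2_ss = 1 - sum((reference - predicted)^2) /
         sum((reference - mean(reference))^2))
}

#' Grid search over BRT hyperparameters
#'
#' Cross-validates every grid point and keeps the configuration with the
#' smallest cross-validated loss; ties break toward the lower (more
#' conservative) learning rate. The winning configuration is refit on
#' the full training set.
#'
#' @param x,y training features and target.
#' @param grid a [brt_grid()] table.
#' @inheritParams fit_brt
#' @return The winning `brt_fit`, with the searched grid and losses
#'   attached as `grid_results`.
#' @export
fit_best_brt <- function(x, y, grid, cv_folds = 10, seed = 0,
                         nthread = 1, early_stopping = 30,
                         nrounds_max = NULL) {
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fits[[i]] <- fit_brt(x, y, grid$learning_rate[i],
                         grid$bag_fraction[i], grid$tree_complexity[i],
                         cv_folds = cv_folds, seed = seed,
                         nthread = nthread,
                         early_stopping = early_stopping,
                         nrounds_max = nrounds_max)
  }
  losses <- vapply(fits, `[[`, numeric(1), "cv_loss")
  ord <- order(losses, grid$learning_rate)
  best <- fits[[ord[1]]]
  best$grid_results <- cbind(as.data.table(grid),
                             cv_loss = losses,
                             best_iter = vapply(fits, `[[`, numeric(1),
                                                "best_iter"))
  best
}

#' BRT accuracy across resolutions, targets and forest categories
#'
#' For every combination of target (GPP, NPP, turnover time), horizontal
#' cell size, vertical layer width and forest category, trains a
#' grid-searched BRT on a random half of the stand-year records (capped
#' at 15 900) of that category and evaluates the squared Pearson R2 and
#' RMSE on the held-out records of the same category. For `dh = 100` the
#' single feature is total AGB.
#'
#' @param sim a `canopy_sim` from [run_succession()].
#' @param targets subset of `c("gpp", "npp", "tau")`.
#' @param cell_edges horizontal resolutions (m).
#' @param dhs vertical layer widths (m).
#' @param categories subset of `c("all", "disturbed", "mature")`.
#' @param seed root seed for splits and bagging.
#' @param learning_rates,bag_fractions grid axes (see [brt_grid()]);
#'   reduced sets shorten the sweep.
#' @param cv_folds folds for stage selection.
#' @param nrounds_max,early_stopping stage budget and patience passed to
#'   [fit_brt()].
#' @param fraction,cap training split rule (see
#'   [split_train_validation()]).
#' @param min_n skip combinations with fewer records (default 50).
#' @param boundary mature/disturbed boundary year.
#' @param keep_predictions store validation scatter tables (default
#'   FALSE).
#' @param verbose print progress lines.
#' @return data.table with one row per combination: the winning
#'   hyperparameters, `n_train`, `n_validation`, `r2`, `rmse`, `r2_ss`
#'   (and a `scatter` list-column when requested). Skipped combinations
#'   appear with `NA` accuracy and a `skip_reason`.
#' @export
resolution_sweep <- function(sim, targets = c("gpp", "npp", "tau"),
                             cell_edges = c(200, 100, 20),
                             dhs = c(100, 20, 10, 2),
                             categories = c("all", "disturbed", "mature"),
                             seed = 1,
                             learning_rates = c(0.05, 0.01, 0.005),
                             bag_fractions = c(0.3, 0.5, 0.66),
                             cv_folds = 10, fraction = 0.5, cap = 15900,
                             min_n = 50, boundary = 160,
                             nrounds_max = NULL, early_stopping = 30,
                             keep_predictions = FALSE, verbose = FALSE) {
  rows <- list()
  combo_id <- 0L
  for (ce in cell_edges) {
    for (dh in dhs) {
      tab <- stand_year_table(sim, ce, dh, boundary = boundary)
      lc <- layer_cols(tab)
      grid <- brt_grid(dh, learning_rates, bag_fractions)
      for (cat in categories) {
        sub <- if (cat == "all") tab else tab[category == cat]
        for (tg in targets) {
          combo_id <- combo_id + 1L
          y_all <- sub[[tg]]
          ok <- is.finite(y_all)
          d <- sub[ok]
          y_all <- y_all[ok]
          base <- data.table(target = tg, cell_edge = ce, dh = dh,
                             category = cat)
          if (nrow(d) < min_n) {
            rows[[combo_id]] <- cbind(base, data.table(
              learning_rate = NA_real_, bag_fraction = NA_real_,
              tree_complexity = NA_real_, n_trees = NA_integer_,
              n_train = NA_integer_, n_validation = NA_integer_,
              r2 = NA_real_, rmse = NA_real_, r2_ss = NA_real_,
              skip_reason = sprintf("only %d records", nrow(d))))
            next
          }
          x <- as.matrix(d[, lc, with = FALSE])
          sp <- split_train_validation(nrow(d), fraction, cap,
                                       seed = seed + combo_id)
          fit <- fit_best_brt(x[sp$train, , drop = FALSE],
                              y_all[sp$train], grid,
                              cv_folds = cv_folds, seed = seed,
                              early_stopping = early_stopping,
                              nrounds_max = nrounds_max)
          pred <- predict(fit, x[sp$validation, , drop = FALSE])
          ev <- evaluate_predictions(pred, y_all[sp$validation])
          row <- cbind(base, data.table(
            learning_rate = fit$config$learning_rate,
            bag_fraction = fit$config$bag_fraction,
            tree_complexity = fit$config$tree_complexity,
            n_trees = fit$best_iter,
            n_train = length(sp$train),
            n_validation = length(sp$validation),
            r2 = ev$r2, rmse = ev$rmse, r2_ss = ev$r2_ss,
            skip_reason = NA_character_))
          if (keep_predictions)
            row[, scatter := list(list(data.table(
              predicted = pred, reference = y_all[sp$validation],
              year = d$year[sp$validation])))]
          rows[[combo_id]] <- row
          if (verbose)
            message(sprintf("%s ce=%d dh=%d %s: R2=%.3f (%d trees)",
                            tg, ce, dh, cat, ev$r2, fit$best_iter))
        }
      }
    }
  }
  rbindlist(rows, fill = TRUE)
}
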