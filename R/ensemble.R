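# Replicate model runs, ensemble prediction, thresholding and variable
# importance.

#' Fit an ensemble of replicate presence-only models
#'
#' Each run shuffles the occurrences, trains on a random
#' `round(train_fraction * n)` of them and evaluates on the remainder: test
#' AUC against a shared bias-weighted background evaluation sample, and the
#' 10th-percentile minimum-training-presence threshold on the training
#' scores. The ensemble records per-run results plus the mean/sd test AUC
#' and the mean threshold (the suitability cut-off used downstream).
#'
#' @param occ a [si_occurrences()] (>= 8 points).
#' @param env an [env_stack()].
#' @param bias a `si_biasgrid`; `NULL` means uniform background.
#' @param n_runs number of replicate runs (default 50).
#' @param train_fraction fraction of occurrences used for training
#'   (default 0.75).
#' @param seed integer RNG seed for background sampling and splits.
#' @param background_n background sample size (default 10000, capped at the
#'   number of valid cells).
#' @param spec a [feature_spec()]; default linear + quadratic terms of all
#'   layers.
#' @param reg_lambda L1 penalty passed to [fit_maxent()].
#' @param mtp_percentile threshold percentile (default 10).
#' @return object of class `si_ensemble`.
#' @export
run_ensemble <- function(occ, env, bias = NULL, n_runs = 50,
                         train_fraction = 0.75, seed = 1,
                         background_n = 10000, spec = NULL,
                         reg_lambda = NULL, mtp_percentile = 10) {
  n <- nrow(occ$points)
  if (n < 8) stop("parameter error: need at least 8 occurrences")
  grid <- env$grid
  if (is.null(bias)) bias <- uniform_bias_grid(grid)
  if (is.null(spec)) spec <- feature_spec(names(env$layers))

  idx <- cell_index(grid, occ$points[, 1], occ$points[, 2])
  if (any(is.na(idx$row))) stop("parameter error: occurrences outside grid extent")
  occ_cells <- (idx$col - 1L) * grid$n_rows + idx$row

  n_valid <- sum(is.finite(bias$layer$values) & bias$layer$values > 0)
  bg_cells <- sample_background(grid, bias, min(background_n, n_valid),
                                seed = child_seed(seed, 1))
  st <- feature_standardization(env, bg_cells)
  xb <- build_features(env, bg_cells, spec, st)
  xp_all <- build_features(env, occ_cells, spec, st)

  n_train <- round(train_fraction * n)
  runs <- with_seed(child_seed(seed, 2), {
    lapply(seq_len(n_runs), function(r) {
      perm <- sample.int(n)
      train <- perm[seq_len(n_train)]
      test <- perm[-seq_len(n_train)]
      fit <- tryCatch(fit_maxent(xp_all[train, , drop = FALSE], xb,
                                 reg_lambda = reg_lambda),
                      error = function(e) e)
      if (inherits(fit, "error")) {
        log_info("run %d failed to converge and is excluded: %s", r,
                 conditionMessage(fit))
        return(list(converged = FALSE, train_indices = train,
                    test_indices = test))
      }
      train_scores <- predict(fit, xp_all[train, , drop = FALSE])
      test_scores <- predict(fit, xp_all[test, , drop = FALSE])
      bg_scores <- predict(fit, xb)
      list(converged = TRUE, model = fit,
           train_indices = train, test_indices = test,
           test_auc = compute_auc(test_scores, bg_scores),
           mtp10_threshold = mtp_threshold(train_scores, mtp_percentile))
    })
  })
  ok <- vapply(runs, function(r) isTRUE(r$converged), logical(1))
  if (!any(ok)) stop("ensemble error: no run converged")
  aucs <- vapply(runs[ok], `[[`, numeric(1), "test_auc")
  thrs <- vapply(runs[ok], `[[`, numeric(1), "mtp10_threshold")
  log_info("ensemble: %d/%d runs converged; mean test AUC %.3f (sd %.3f)",
           sum(ok), n_runs, mean(aucs), stats::sd(aucs))
  structure(list(runs = runs, n_runs = n_runs,
                 train_fraction = train_fraction,
                 mean_test_auc = mean(aucs), sd_test_auc = stats::sd(aucs),
                 mean_threshold = mean(thrs),
                 background_cells = bg_cells, standardization = st,
                 spec = spec, occ_cells = occ_cells, grid = grid,
                 mtp_percentile = mtp_percentile),
            class = "si_ensemble")
}

#' @export
print.si_ensemble <- function(x, ...) {
  ok <- sum(vapply(x$runs, function(r) isTRUE(r$converged), logical(1)))
  cat(sprintf("<si_ensemble> %d/%d converged runs (train fraction %.2f)\n",
              ok, x$n_runs, x$train_fraction))
  cat(sprintf("  mean test AUC %.3f (sd %.3f); mean %g%% MTP threshold %.4f\n",
              x$mean_test_auc, x$sd_test_auc, x$mtp_percentile,
              x$mean_threshold))
  invisible(x)
}

converged_models <- function(ensemble) {
  lapply(Filter(function(r) isTRUE(r$converged), ensemble$runs), `[[`, "model")
}

#' Ensemble suitability surface and suitable/unsuitable mask
#'
#' Suitability at a cell is the mean logistic output across converged runs;
#' the binary mask marks cells with suitability at or above the ensemble's
#' mean minimum-training-presence threshold (closed lower bound). Nodata in
#' any environment layer propagates.
#'
#' @param ensemble a fitted `si_ensemble`.
#' @param env the [env_stack()] to predict over.
#' @param threshold override for the suitability cut-off (default: the
#'   ensemble's mean threshold).
#' @return list of class `si_suitability`: `suitability` ([si_raster()],
#'   0-1), `suitable_mask` ([si_raster()], 0/1), `threshold_used`.
#' @export
predict_and_binarize <- function(ensemble, env, threshold = NULL) {
  models <- converged_models(ensemble)
  if (!length(models)) stop("ensemble error: no converged runs")
  grid <- env$grid
  cells <- seq_len(grid$n_rows * grid$n_cols)
  x <- build_features(env, cells, ensemble$spec, ensemble$standardization)
  preds <- vapply(models, function(m) predict(m, x), numeric(length(cells)))
  suit <- matrix(rowMeans(preds), grid$n_rows, grid$n_cols)
  nodata <- Reduce(`|`, lapply(env$layers, `[[`, "nodata_mask"))
  thr <- threshold %||% ensemble$mean_threshold
  mask <- (suit >= thr) & !nodata
  structure(list(
    suitability = si_raster(suit, grid, nodata_mask = nodata,
                            name = "suitability", units = "logistic 0-1"),
    suitable_mask = si_raster(mask * 1, grid, nodata_mask = nodata,
                              name = "suitable_mask", units = "0/1"),
    threshold_used = thr), class = "si_suitability")
}

#' Jackknife gains and permutation-based percent contribution
#'
#' Two complementary importance views, computed on the full occurrence set
#' against the ensemble's background sample. Jackknife: for each variable,
#' the training gain of a model using only that variable's features
#' (`gain_alone`) and of a model using all other variables (`gain_without`);
#' gain is the unpenalized log-likelihood improvement over the uniform null.
#' Percent contribution: the drop in full-model training gain when the
#' variable's (standardized) values are permuted across evaluation cells,
#' normalized over variables to sum to 100.
#'
#' @param ensemble a fitted `si_ensemble`.
#' @param env the [env_stack()] used to fit it.
#' @param seed integer RNG seed for the permutation.
#' @param n_perm permutations averaged per variable (default 5).
#' @return data.frame with columns `variable`, `gain_alone`, `gain_without`,
#'   `percent_contribution`. `gain_without` is NA for single-variable models.
#' @export
variable_importance <- function(ensemble, env, seed = 1, n_perm = 5) {
  st <- ensemble$standardization
  vars <- st$variables
  spec <- ensemble$spec
  bg <- ensemble$background_cells
  occ <- ensemble$occ_cells
  xb <- build_features(env, bg, spec, st)
  xp <- build_features(env, occ, spec, st)

  gain <- function(model, xp_, xb_) {
    eta_p <- as.vector(xp_ %*% model$beta)
    eta_b <- as.vector(xb_ %*% model$beta)
    m <- max(eta_b)
    mean(eta_p) - (log(mean(exp(eta_b - m))) + m)
  }
  sub_spec <- function(keep) spec[spec$var1 %in% keep &
                                    (is.na(spec$var2) | spec$var2 %in% keep), ,
                                  drop = FALSE]
  fit_on <- function(sp) {
    xb_ <- build_features(env, bg, sp, st)
    xp_ <- build_features(env, occ, sp, st)
    m <- fit_maxent(xp_, xb_)
    gain(m, xp_, xb_)
  }
  gain_alone <- vapply(vars, function(v) fit_on(sub_spec(v)), numeric(1))
  gain_without <- if (length(vars) > 1) {
    vapply(vars, function(v) fit_on(sub_spec(setdiff(vars, v))), numeric(1))
  } else stats::setNames(rep(NA_real_, length(vars)), vars)

  full <- fit_maxent(xp, xb)
  g_full <- gain(full, xp, xb)
  term_cols <- function(v) which(spec$var1 == v | (!is.na(spec$var2) & spec$var2 == v))
  n_all <- nrow(xp) + nrow(xb)
  drops <- with_seed(seed, {
    vapply(vars, function(v) {
      cols <- term_cols(v)
      mean(vapply(seq_len(n_perm), function(k) {
        perm <- sample.int(n_all)
        allx <- rbind(xp, xb)
        allx[, cols] <- allx[perm, cols, drop = FALSE]
        g_full - gain(full, allx[seq_len(nrow(xp)), , drop = FALSE],
                      allx[-seq_len(nrow(xp)), , drop = FALSE])
      }, numeric(1)))
    }, numeric(1))
  })
  drops <- pmax(drops, 0)
  pct <- if (sum(drops) > 0) 100 * drops / sum(drops)
         else rep(100 / length(vars), length(vars))
  data.frame(variable = vars, gain_alone = gain_alone,
             gain_without = gain_without, percent_contribution = pct,
             row.names = NULL, stringsAsFactors = FALSE)
}
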