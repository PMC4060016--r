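# Presence-only distribution model: sampling-bias kernel grid, weighted
# background, penalized log-linear (maximum-entropy-style) density fit with
# logistic output, and threshold/AUC evaluation.

#' Sampling-bias grid from a quartic kernel density of occurrences
#'
#' Presence-only records cluster where collectors go, not only where the
#' species lives. The standard correction is a relative sampling-effort
#' surface: a kernel density of the occurrence points themselves, used to
#' weight background sampling. Density at a cell centre is the 2-D quartic
#' (biweight) kernel sum `sum((3 / (pi h^2)) * (1 - (d/h)^2)^2)` over points
#' within bandwidth `h`, rescaled to maximum 1 and floored at `floor_eps` so
#' every cell keeps positive sampling weight.
#'
#' @param occ a [si_occurrences()] set (>= 1 point).
#' @param grid the [si_grid()] to rasterize onto.
#' @param bandwidth kernel bandwidth in metres; default twice the mean
#'   nearest-neighbour distance among the occurrences.
#' @param floor_eps minimum relative weight (default 1e-6).
#' @return object of class `si_biasgrid` with fields `layer`, `bandwidth`,
#'   `floor_eps`.
#' @export
build_bias_grid <- function(occ, grid, bandwidth = NULL, floor_eps = 1e-6) {
  pts <- occ$points
  if (nrow(pts) < 1) stop("parameter error: need at least one occurrence")
  if (is.null(bandwidth)) bandwidth <- 2 * mean_nn_distance(pts)
  if (!is.finite(bandwidth) || bandwidth <= 0)
    stop("parameter error: bandwidth must be > 0")
  cc <- cell_centres(grid)
  dens <- matrix(0, grid$n_rows, grid$n_cols)
  h2 <- bandwidth^2
  for (i in seq_len(nrow(pts))) {
    # only cells whose centre can be within the compact support
    cols <- which(abs(cc$x - pts[i, 1]) <= bandwidth)
    rows <- which(abs(cc$y - pts[i, 2]) <= bandwidth)
    if (!length(cols) || !length(rows)) next
    d2 <- outer((cc$y[rows] - pts[i, 2])^2, (cc$x[cols] - pts[i, 1])^2, "+")
    k <- (3 / (pi * h2)) * pmax(0, 1 - d2 / h2)^2
    dens[rows, cols] <- dens[rows, cols] + k
  }
  if (max(dens) > 0) dens <- dens / max(dens)
  dens <- pmax(dens, floor_eps)
  structure(list(layer = si_raster(dens, grid, name = "bias", units = "relative effort"),
                 bandwidth = bandwidth, floor_eps = floor_eps),
            class = "si_biasgrid")
}

mean_nn_distance <- function(pts) {
  if (nrow(pts) < 2) return(1)
  d <- as.matrix(stats::dist(pts))
  diag(d) <- Inf
  mean(apply(d, 1, min))
}

#' Uniform bias grid (no sampling-effort correction)
#'
#' @param grid a [si_grid()].
#' @return a `si_biasgrid` with weight 1 everywhere.
#' @export
uniform_bias_grid <- function(grid) {
  structure(list(layer = si_raster(matrix(1, grid$n_rows, grid$n_cols), grid,
                                   name = "bias", units = "relative effort"),
                 bandwidth = NA_real_, floor_eps = 1),
            class = "si_biasgrid")
}

#' Sample background cells weighted by the bias surface
#'
#' Background ("pseudo-absence") cells characterize the available
#' environment. Drawing them with probability proportional to the sampling-
#' bias surface gives the model presences and background with the *same*
#' spatial observation bias, which cancels it out of the fitted density.
#'
#' @param grid a [si_grid()].
#' @param bias a `si_biasgrid` from [build_bias_grid()] or
#'   [uniform_bias_grid()].
#' @param n number of cells to draw, without replacement.
#' @param seed integer RNG seed.
#' @return integer vector of column-major cell indices.
#' @export
sample_background <- function(grid, bias, n, seed = 1) {
  if (n < 1) stop("parameter error: n must be >= 1")
  stop_if_misaligned(bias$layer, grid, "bias grid and target grid")
  w <- as.vector(bias$layer$values)
  valid <- which(is.finite(w) & w > 0)
  if (n > length(valid))
    stop("parameter error: n (", n, ") exceeds number of valid cells (",
         length(valid), ")")
  with_seed(seed, valid[sample.int(length(valid), n, prob = w[valid])])
}

#' Feature specification for the log-linear model
#'
#' Restricted maxent-style feature set: standardized linear terms, their
#' squares, and optional pairwise products. Quadratics allow unimodal
#' responses (an optimum temperature, not "hotter is always better") while
#' keeping the likelihood convex.
#'
#' @param variables character vector of environment layer names.
#' @param quadratic include squared terms (default TRUE).
#' @param products optional 2-column matrix/data.frame of variable pairs.
#' @return data.frame with columns `term`, `var1`, `transform`, `var2`.
#' @export
feature_spec <- function(variables, quadratic = TRUE, products = NULL) {
  if (!length(variables)) stop("parameter error: empty feature specification")
  spec <- data.frame(term = variables, var1 = variables,
                     transform = "linear", var2 = NA_character_,
                     stringsAsFactors = FALSE)
  if (quadratic)
    spec <- rbind(spec, data.frame(term = paste0(variables, "^2"),
                                   var1 = variables, transform = "quadratic",
                                   var2 = NA_character_))
  if (!is.null(products)) {
    pr <- as.data.frame(products, stringsAsFactors = FALSE)
    spec <- rbind(spec, data.frame(term = paste0(pr[[1]], "*", pr[[2]]),
                                   var1 = pr[[1]], transform = "product",
                                   var2 = pr[[2]]))
  }
  spec
}

#' Standardization constants computed on background cells
#'
#' Means and standard deviations of each environment layer over the
#' background sample; all feature construction standardizes with these
#' (never with presence-cell statistics). Zero-variance layers are dropped
#' with a logged warning.
#'
#' @param env an [env_stack()].
#' @param cells integer cell indices of the background sample.
#' @return list with `means`, `sds`, `variables`.
#' @export
feature_standardization <- function(env, cells) {
  vals <- vapply(env$layers, function(l) l$values[cells], numeric(length(cells)))
  means <- colMeans(vals)
  sds <- apply(vals, 2, stats::sd)
  keep <- sds > 0
  if (any(!keep))
    log_info("dropping zero-variance variable(s): %s",
             paste(names(env$layers)[!keep], collapse = ", "))
  list(means = means[keep], sds = sds[keep],
       variables = names(env$layers)[keep])
}

#' Build the model feature matrix for a set of cells
#'
#' @param env an [env_stack()].
#' @param cells integer column-major cell indices.
#' @param spec a [feature_spec()]; rows referencing dropped variables are
#'   silently omitted.
#' @param standardization constants from [feature_standardization()].
#' @return numeric matrix, one column per retained feature term.
#' @export
build_features <- function(env, cells, spec, standardization) {
  st <- standardization
  spec <- spec[spec$var1 %in% st$variables &
                 (is.na(spec$var2) | spec$var2 %in% st$variables), ,
               drop = FALSE]
  if (!nrow(spec)) stop("parameter error: no usable features after dropping")
  z <- function(v) (env$layers[[v]]$values[cells] - st$means[[v]]) / st$sds[[v]]
  cols <- lapply(seq_len(nrow(spec)), function(i) {
    switch(spec$transform[i],
           linear = z(spec$var1[i]),
           quadratic = z(spec$var1[i])^2,
           product = z(spec$var1[i]) * z(spec$var2[i]),
           stop("parameter error: unknown transform ", spec$transform[i]))
  })
  m <- do.call(cbind, cols)
  colnames(m) <- spec$term
  m
}

#' Fit the penalized maximum-entropy-style log-linear model
#'
#' Maximizes the presence/background log-likelihood
#' `mean_p(beta . f) - log sum_b exp(beta . f) - reg_lambda * ||beta||_1`
#' by proximal-gradient (FISTA) iteration with backtracking; the objective is
#' concave, so the optimum is global. The fitted raw output
#' `exp(beta . f) / Z_background` is a relative occurrence density summing to
#' one over the background sample; the logistic output
#' `c r / (1 + c r)` with `c = exp(H)` (H = entropy of the fitted
#' background distribution) rescales it so a typical presence scores about
#' 0.5.
#'
#' @param presence_features,background_features numeric feature matrices
#'   (same columns) for presence cells and background cells.
#' @param reg_lambda L1 penalty weight; default `1 / sqrt(n_presence)`
#'   (shrinkage vanishing with sample size).
#' @param max_iter iteration cap (default 5000).
#' @param tol convergence tolerance on the objective change (default 1e-8).
#' @return object of class `si_sdm`: `beta`, `reg_lambda`, `log_z`
#'   (log partition over background), `entropy_H`, `n_presence`,
#'   `n_background`, `objective`, `converged`, `iterations`.
#' @export
fit_maxent <- function(presence_features, background_features,
                       reg_lambda = NULL, max_iter = 5000, tol = 1e-8) {
  xp <- as.matrix(presence_features); xb <- as.matrix(background_features)
  if (nrow(xp) < 5) stop("parameter error: need at least 5 presences")
  if (nrow(xb) < 10 * nrow(xp))
    log_info("background (%d) is below the recommended 10x presences (%d)",
             nrow(xb), nrow(xp))
  if (is.null(reg_lambda)) reg_lambda <- 1 / sqrt(nrow(xp))
  p <- ncol(xp)
  fbar <- colMeans(xp)
  neg_ll <- function(beta) {
    eta <- as.vector(xb %*% beta)
    m <- max(eta)
    log(sum(exp(eta - m))) + m - sum(fbar * beta)
  }
  grad <- function(beta) {
    eta <- as.vector(xb %*% beta)
    w <- exp(eta - max(eta)); w <- w / sum(w)
    as.vector(crossprod(xb, w)) - fbar
  }
  soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

  beta <- numeric(p); y <- beta; t_acc <- 1
  step <- 1
  obj_old <- neg_ll(beta) + reg_lambda * sum(abs(beta))
  converged <- FALSE; it <- 0
  for (it in seq_len(max_iter)) {
    g <- grad(y); f_y <- neg_ll(y)
    repeat {  # backtracking on the smooth part
      beta_new <- soft(y - step * g, step * reg_lambda)
      d <- beta_new - y
      if (neg_ll(beta_new) <= f_y + sum(g * d) + sum(d^2) / (2 * step) + 1e-12)
        break
      step <- step / 2
      if (step < 1e-12) break
    }
    t_new <- (1 + sqrt(1 + 4 * t_acc^2)) / 2
    y <- beta_new + ((t_acc - 1) / t_new) * (beta_new - beta)
    obj <- neg_ll(beta_new) + reg_lambda * sum(abs(beta_new))
    if (obj > obj_old) { y <- beta_new; t_new <- 1 }  # monotone restart
    if (abs(obj_old - obj) < tol && it > 1) {
      beta <- beta_new; converged <- TRUE; obj_old <- obj; break
    }
    beta <- beta_new; t_acc <- t_new; obj_old <- obj
    step <- min(step * 1.5, 1e6)
  }
  if (!converged)
    stop("convergence error: objective change ",
         format(abs(obj_old - obj_old)), " after ", max_iter,
         " iterations (last objective ", format(obj_old), ")")
  eta_b <- as.vector(xb %*% beta)
  m <- max(eta_b)
  log_z <- log(sum(exp(eta_b - m))) + m
  pb <- exp(eta_b - log_z)
  h <- -sum(pb * log(pmax(pb, 1e-300)))
  structure(list(beta = stats::setNames(beta, colnames(xp)),
                 reg_lambda = reg_lambda, log_z = log_z, entropy_H = h,
                 n_presence = nrow(xp), n_background = nrow(xb),
                 objective = -obj_old, converged = converged, iterations = it),
            class = "si_sdm")
}

#' Predict from a fitted log-linear model
#'
#' @param object a `si_sdm` fit.
#' @param features feature matrix (columns matching the fit).
#' @param type `"link"` (linear predictor), `"raw"` (density normalized over
#'   the background sample) or `"logistic"` (0-1 suitability).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.si_sdm <- function(object, features, type = c("logistic", "raw", "link"),
                           ...) {
  type <- match.arg(type)
  eta <- as.vector(as.matrix(features) %*% object$beta)
  if (type == "link") return(eta)
  raw <- exp(eta - object$log_z)
  if (type == "raw") return(raw)
  cr <- exp(object$entropy_H) * raw
  cr / (1 + cr)
}

#' @export
print.si_sdm <- function(x, ...) {
  cat(sprintf("<si_sdm> %d feature(s), lambda = %.4g, %d presences / %d background\n",
              length(x$beta), x$reg_lambda, x$n_presence, x$n_background))
  cat(sprintf("  objective %.6g after %d iterations; entropy H = %.4g\n",
              x$objective, x$iterations, x$entropy_H))
  invisible(x)
}

#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' Probability that a randomly chosen presence scores higher than a randomly
#' chosen background point, ties counted one half. Invariant under any
#' strictly monotone transform of the scores.
#'
#' @param scores_presence,scores_background numeric score vectors (non-empty).
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(scores_presence, scores_background) {
  np <- length(scores_presence); nb <- length(scores_background)
  if (np == 0 || nb == 0) stop("input error: empty score set")
  r <- rank(c(scores_presence, scores_background), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Minimum-training-presence percentile threshold
#'
#' The nearest-rank percentile of training presence scores: the
#' `ceiling(p/100 * n)`-th smallest score. At the default 10th percentile the
#' lowest-scoring ~10% of training presences fall below it; cells at or above
#' it are classed suitable.
#'
#' @param training_presence_scores numeric scores (>= 1).
#' @param percentile percentile in `[0, 100]` (default 10).
#' @return the threshold score.
#' @export
mtp_threshold <- function(training_presence_scores, percentile = 10) {
  n <- length(training_presence_scores)
  if (n == 0) stop("input error: no training presence scores")
  k <- max(1L, ceiling(percentile / 100 * n))
  sort(training_presence_scores)[k]
}
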