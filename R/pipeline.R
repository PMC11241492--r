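# Serialized four-stage feature-selection pipeline:
#   variance threshold -> univariate F selection -> RFECV (ridge) -> PCA,
# followed by a ridge model on the principal-component scores.  The six
# tunable parameters (variance threshold, percentile, RFECV step, minimum
# feature count, CV scoring criterion, number of components) form the search
# space the Dung Beetle Optimizer explores.

SCORING_OPTIONS <- c("r2", "mse", "rmse", "mae")

#' Pipeline parameters
#'
#' The six-dimensional search point the optimizer tunes.  Ranges follow the
#' default search space: variance threshold in \[0, 1e-4\] (binary features
#' are near-constant below it), percentile in \[1, 100\], RFECV step in
#' \[1, 10\], minimum features to select in \[100, 300\], scoring criterion
#' one of R2/MSE/RMSE/MAE, and a component count that must stay below the
#' sample count.
#'
#' @param variance_threshold Variance cutoff for the first stage.
#' @param percentile Percent of features the univariate F stage keeps.
#' @param rfecv_step Features removed per RFECV round.
#' @param min_features Minimum features RFECV may keep.
#' @param scoring CV scoring criterion (`"r2"`, `"mse"`, `"rmse"`, `"mae"`;
#'   case-insensitive).
#' @param n_components Number of principal components retained.
#' @return An object of class `pipeline_params`.
#' @export
pipeline_params <- function(variance_threshold, percentile, rfecv_step,
                            min_features, scoring, n_components) {
  scoring <- tolower(scoring)
  if (!scoring %in% SCORING_OPTIONS) {
    abort(sprintf("scoring must be one of %s",
                  paste(SCORING_OPTIONS, collapse = ", ")))
  }
  if (variance_threshold < 0 || variance_threshold > 1e-4) {
    abort("variance_threshold must be in [0, 1e-4]")
  }
  if (percentile < 1 || percentile > 100) abort("percentile must be in [1, 100]")
  if (rfecv_step < 1 || rfecv_step > 10) abort("rfecv_step must be in [1, 10]")
  if (min_features < 100 || min_features > 300) {
    abort("min_features must be in [100, 300]")
  }
  if (n_components < 1) abort("n_components must be >= 1")
  structure(
    list(variance_threshold = variance_threshold,
         percentile = as.integer(percentile),
         rfecv_step = as.integer(rfecv_step),
         min_features = as.integer(min_features),
         scoring = scoring,
         n_components = as.integer(n_components)),
    class = "pipeline_params"
  )
}

#' @export
print.pipeline_params <- function(x, ...) {
  cat(sprintf(paste0("<pipeline_params> vt=%.3g percentile=%d step=%d ",
                     "min_features=%d scoring=%s n_components=%d\n"),
              x$variance_threshold, x$percentile, x$rfecv_step,
              x$min_features, x$scoring, x$n_components))
  invisible(x)
}

#' DBO search space for the pipeline parameters
#'
#' Builds the bounds / dimension-kind description [dbo_optimize()] and
#' [decode_position()] need for the six pipeline parameters.
#'
#' @param n_samples Sample count; caps the component dimension at
#'   `n_samples - 1`.
#' @param min_features_range Lower/upper bound of the RFECV floor (the
#'   default range is 100–300; small panels may narrow it).
#' @param max_components Optional tighter cap on the component dimension.
#' @return A list with `bounds`, `dim_kinds` and `categories`, ready to pass
#'   to [dbo_config()].
#' @export
pipeline_param_space <- function(n_samples,
                                 min_features_range = c(100, 300),
                                 max_components = NULL) {
  hi_comp <- min(n_samples - 1, max_components %||% (n_samples - 1))
  bounds <- rbind(
    variance_threshold = c(0, 1e-4),
    percentile = c(1, 100),
    rfecv_step = c(1, 10),
    min_features = min_features_range,
    scoring = c(0, length(SCORING_OPTIONS)),
    n_components = c(1, hi_comp)
  )
  list(bounds = bounds,
       dim_kinds = c("continuous", "integer", "integer", "integer",
                     "categorical", "integer"),
       categories = list(NULL, NULL, NULL, NULL, as.list(SCORING_OPTIONS), NULL))
}

#' Decode a DBO position into pipeline parameters
#'
#' @param position Numeric vector of length 6 within the space's bounds.
#' @param config A [dbo_config()] built from [pipeline_param_space()].
#' @return A [pipeline_params()] object.
#' @export
decode_pipeline_params <- function(position, config) {
  v <- decode_position(position, config)
  pipeline_params(v$variance_threshold, v$percentile, v$rfecv_step,
                  v$min_features, v$scoring[[1]], v$n_components)
}

# --- stages ------------------------------------------------------------------

#' Variance-threshold filter
#'
#' Keeps feature `j` iff its population variance (divide-by-n) is at least
#' `threshold`; features strictly below are removed.  Operates on the raw 0/1
#' values, where a Bernoulli(p) feature has variance `p(1-p)`.
#'
#' @param G Numeric matrix, samples x features.
#' @param threshold Non-negative variance cutoff.
#' @return Named logical vector over the columns of `G`.
#' @export
variance_filter <- function(G, threshold) {
  if (threshold < 0) abort("threshold must be >= 0")
  v <- col_pop_var(as.matrix(G))
  mask <- v >= threshold
  if (!any(mask)) {
    abort(sprintf("variance filter at threshold %g removed every feature",
                  threshold))
  }
  names(mask) <- colnames(G)
  mask
}

# Column-wise standardization to zero mean and unit population variance;
# zero-variance columns become all-zero (they carry no signal).
standardize_features <- function(X) {
  X <- as.matrix(X)
  m <- colMeans(X)
  s <- sqrt(col_pop_var(X))
  Xs <- sweep(X, 2, m)
  nz <- s > 0
  Xs[, nz] <- sweep(Xs[, nz, drop = FALSE], 2, s[nz], "/")
  Xs[, !nz] <- 0
  attr(Xs, "center") <- m
  attr(Xs, "scale") <- ifelse(nz, s, 1)
  Xs
}

#' Univariate F selection
#'
#' Scores each feature by the simple-regression F statistic
#' `F_j = r_j^2 (n-2) / (1 - r_j^2)` with `r_j` the Pearson correlation
#' against `y`, and keeps the top `percentile` percent
#' (`max(1, ceiling(p * percentile / 100))` features).  Constant features
#' score 0; a perfectly correlated feature scores `+Inf`; score ties break
#' toward the lower feature index.
#'
#' @param X Numeric matrix, samples x features.
#' @param y Numeric response with nonzero variance.
#' @param percentile Integer in \[1, 100\].
#' @return Named logical vector over the columns of `X`.
#' @export
univariate_f_select <- function(X, y, percentile) {
  X <- as.matrix(X)
  if (percentile < 1 || percentile > 100) abort("percentile must be in [1, 100]")
  n <- nrow(X)
  if (var(y) == 0) abort("y has zero variance")
  sx <- sqrt(col_pop_var(X))
  if (all(sx == 0)) abort("all features are constant")
  yc <- y - mean(y)
  r <- rep(0, ncol(X))
  nz <- sx > 0
  r[nz] <- drop(crossprod(X[, nz, drop = FALSE], yc)) /
    (n * sx[nz] * sqrt(mean(yc^2)))
  r <- pmin(pmax(r, -1), 1)
  f <- ifelse(abs(r) >= 1, Inf, r^2 * (n - 2) / (1 - r^2))
  f[!nz] <- 0
  n_keep <- max(1L, ceiling(ncol(X) * percentile / 100))
  keep_idx <- order(-f, seq_along(f))[seq_len(n_keep)]
  mask <- logical(ncol(X))
  mask[keep_idx] <- TRUE
  names(mask) <- colnames(X)
  mask
}

#' Recursive feature elimination with cross-validation (ridge estimator)
#'
#' Standardizes the features, then repeatedly fits ridge regression
#' (penalty `lambda`, unpenalized intercept) and removes the `step` features
#' with the smallest absolute coefficients, never dropping below
#' `min_features`.  At every visited feature count the mean `cv_folds`-fold
#' CV score is recorded (error metrics negated); the returned mask is the
#' feature count with the best mean CV score, ties resolved toward fewer
#' features.
#'
#' The elimination path runs on the n x n gram matrix in compiled code, so
#' cost scales with the sample count rather than the feature count.
#'
#' @param X Numeric matrix with at least `min_features` columns.
#' @param y Numeric response.
#' @param step Features removed per round (>= 1).
#' @param min_features Floor on the retained feature count.
#' @param scoring CV scoring criterion (see [pipeline_params()]).
#' @param cv_folds Number of CV folds (default 10).
#' @param lambda Ridge penalty (default 1).
#' @param fold_seed Seed for the fold shuffle.
#' @return Named logical mask over the columns of `X`, with attributes
#'   `path` (tibble of `n_features`, `cv_score` along the elimination
#'   schedule) and `best_count`.
#' @export
rfecv_select <- function(X, y, step, min_features, scoring = "r2",
                         cv_folds = 10, lambda = 1, fold_seed = 2024) {
  X <- as.matrix(X)
  scoring <- tolower(scoring)
  if (!scoring %in% SCORING_OPTIONS) abort("unknown scoring criterion")
  if (ncol(X) < min_features) {
    abort(sprintf("X has %d features, fewer than min_features = %d",
                  ncol(X), min_features))
  }
  if (cv_folds > nrow(X)) {
    abort(sprintf("cannot run %d folds on %d samples", cv_folds, nrow(X)))
  }
  folds <- kfold_assign(nrow(X), cv_folds, fold_seed)
  Xs <- standardize_features(X)
  path <- rfecv_path_cpp(Xs, y, as.integer(folds), lambda,
                         as.integer(step), as.integer(min_features))
  scores <- score_pred_path(path$preds, y, folds, scoring)
  best_i <- max(which(scores == max(scores)))   # ties -> fewer features
  surv <- path_survivors(path, path$counts[best_i])
  mask <- logical(ncol(X))
  mask[surv] <- TRUE
  names(mask) <- colnames(X)
  attr(mask, "path") <- tibble::tibble(n_features = path$counts,
                                       cv_score = scores)
  attr(mask, "best_count") <- path$counts[best_i]
  mask
}

# Survivor (column) indices at feature count m along an elimination path:
# within each round features are dropped in increasing |coefficient| order,
# so the survivors at any count are the complement of a prefix of
# elim_order.
path_survivors <- function(path, m) {
  drop_n <- path$counts[1] - m
  if (drop_n == 0) return(seq_len(path$counts[1]))
  setdiff(seq_len(path$counts[1]), path$elim_order[seq_len(drop_n)])
}

# Mean CV score per path column from out-of-fold predictions (error metrics
# negated so every criterion is maximized).
score_pred_path <- function(preds, y, folds, scoring) {
  preds <- as.matrix(preds)
  k <- max(folds)
  per_fold <- vapply(seq_len(k), function(f) {
    te <- folds == f
    E <- preds[te, , drop = FALSE] - y[te]
    switch(scoring,
           r2 = {
             ss_tot <- sum((y[te] - mean(y[te]))^2)
             if (ss_tot <= 0) rep(-Inf, ncol(preds)) else
               1 - colSums(E^2) / ss_tot
           },
           mse = -colMeans(E^2),
           rmse = -sqrt(colMeans(E^2)),
           mae = -colMeans(abs(E)))
  }, numeric(ncol(preds)))
  rowMeans(matrix(per_fold, ncol = k))
}

#' Principal component analysis reduction
#'
#' Mean-centers the columns and projects onto the top right singular
#' vectors.  Loadings are orthonormal; explained variance is non-increasing
#' across components.
#'
#' @param X Numeric matrix, samples x features.
#' @param n_components Integer in \[1, min(n_samples - 1, n_features)\].
#' @return List with `scores` (samples x components), `loadings`
#'   (features x components, orthonormal), `center` (column means) and
#'   `explained_variance`.
#' @export
pca_reduce <- function(X, n_components) {
  X <- as.matrix(X)
  max_nc <- min(nrow(X) - 1, ncol(X))
  if (n_components < 1 || n_components > max_nc) {
    abort(sprintf("n_components must be in [1, %d], got %d", max_nc,
                  as.integer(n_components)))
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = n_components)
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       loadings = pc$rotation[, seq_len(n_components), drop = FALSE],
       center = pc$center,
       explained_variance = pc$sdev[seq_len(n_components)]^2)
}

# Mean k-fold CV score of ridge on a (small) design matrix; used for the
# fitness model on component scores and stage-wise reporting.
cv_ridge_score <- function(X, y, folds, scoring = "r2", lambda = 1) {
  X <- as.matrix(X)
  k <- max(folds)
  sc <- vapply(seq_len(k), function(f) {
    tr <- folds != f; te <- !tr
    fit <- ridge_fit(X[tr, , drop = FALSE], y[tr], lambda)
    pred <- ridge_predict(fit, X[te, , drop = FALSE])
    m <- compute_metrics(y[te], pred)
    switch(scoring, r2 = m$r2, mse = -m$mse, rmse = -m$rmse, mae = -m$mae)
  }, numeric(1))
  mean(sc)
}

# --- fitness and fitting -----------------------------------------------------

run_stages <- function(params, G, y, cv_folds = 10, fold_seed = 2024,
                       lambda = 1) {
  G <- as.matrix(G)
  p <- ncol(G)
  vt <- variance_filter(G, params$variance_threshold)
  Xs <- standardize_features(G[, vt, drop = FALSE])

  ufs_local <- univariate_f_select(Xs, y, params$percentile)
  if (sum(ufs_local) < params$min_features) {
    abort(sprintf("univariate stage kept %d features, below min_features = %d",
                  sum(ufs_local), params$min_features))
  }
  X_ufs <- Xs[, ufs_local, drop = FALSE]

  rf_local <- rfecv_select(X_ufs, y, params$rfecv_step, params$min_features,
                           params$scoring, cv_folds, lambda, fold_seed)
  X_sel <- X_ufs[, rf_local, drop = FALSE]

  if (params$n_components > min(nrow(G) - 1, ncol(X_sel))) {
    abort(sprintf("n_components = %d exceeds min(n_samples - 1, %d survivors)",
                  params$n_components, ncol(X_sel)))
  }
  pca <- pca_reduce(X_sel, params$n_components)

  to_global <- function(local_mask, parent_mask) {
    out <- logical(p)
    out[which(parent_mask)[local_mask]] <- TRUE
    names(out) <- colnames(G)
    out
  }
  ufs <- to_global(ufs_local, vt)
  rfecv <- to_global(rf_local[seq_len(sum(ufs_local))], ufs)

  list(vt_mask = vt, ufs_mask = ufs, rfecv_mask = rfecv,
       Xs = Xs, X_sel = X_sel, pca = pca,
       rfecv_path = attr(rf_local, "path"))
}

#' Pipeline fitness for the optimizer
#'
#' Runs the four stages with the decoded parameters, then scores a ridge
#' model on the component scores by `cv_folds`-fold CV using the parameter's
#' scoring criterion (R2 maximized, error metrics negated).  Any stage
#' failure — including an infeasible component count — scores `-Inf` so the
#' optimizer can keep searching near constraint boundaries.  Deterministic
#' given `fold_seed`.
#'
#' @param params A [pipeline_params()] (or a raw position plus `config`).
#' @param G Genotype matrix (samples x features, 0/1).
#' @param y Numeric phenotype vector.
#' @param cv_folds,fold_seed,lambda CV geometry and ridge penalty shared with
#'   the final evaluation.
#' @return Scalar fitness (larger is better), `-Inf` on any failure.
#' @export
pipeline_fitness <- function(params, G, y, cv_folds = 10, fold_seed = 2024,
                             lambda = 1) {
  tryCatch({
    if (var(y) == 0) return(-Inf)
    st <- run_stages(params, G, y, cv_folds, fold_seed, lambda)
    folds <- kfold_assign(nrow(as.matrix(G)), cv_folds, fold_seed)
    cv_ridge_score(st$pca$scores, y, folds, params$scoring, lambda)
  }, error = function(e) -Inf)
}

#' Fit the full feature-selection pipeline
#'
#' Runs variance filtering, univariate F selection, RFECV and PCA on all
#' samples and fits the final ridge model on the component scores.  Stage
#' errors are propagated with the stage name.
#'
#' @inheritParams pipeline_fitness
#' @return An object of class `fitted_pipeline` holding the three nested
#'   survivor masks over the original feature ids, the standardization
#'   constants of the selected features, the PCA loading matrix and scores,
#'   and the ridge intercept/coefficients.
#' @export
fit_pipeline <- function(params, G, y, cv_folds = 10, fold_seed = 2024,
                         lambda = 1) {
  G <- as.matrix(G)
  st <- run_stages(params, G, y, cv_folds, fold_seed, lambda)
  ridge <- ridge_fit(st$pca$scores, y, lambda)
  sel_ids <- names(st$rfecv_mask)[st$rfecv_mask]
  ctr <- attr(st$Xs, "center"); scl <- attr(st$Xs, "scale")
  sel_in_vt <- match(sel_ids, colnames(st$Xs))
  structure(
    list(params = params,
         feature_ids = colnames(G),
         vt_mask = st$vt_mask, ufs_mask = st$ufs_mask,
         rfecv_mask = st$rfecv_mask,
         selected_ids = sel_ids,
         feature_center = ctr[sel_in_vt],
         feature_scale = scl[sel_in_vt],
         pca_center = st$pca$center,
         loading_matrix = st$pca$loadings,
         component_scores = st$pca$scores,
         explained_variance = st$pca$explained_variance,
         ridge_intercept = ridge$intercept,
         ridge_coefficients = ridge$coef,
         rfecv_path = st$rfecv_path,
         y = y),
    class = "fitted_pipeline"
  )
}

#' @export
print.fitted_pipeline <- function(x, ...) {
  cat(sprintf(paste0("<fitted_pipeline> %d -> %d (VT) -> %d (UFS) -> %d ",
                     "(RFECV) features -> %d components\n"),
              length(x$vt_mask), sum(x$vt_mask), sum(x$ufs_mask),
              sum(x$rfecv_mask), ncol(x$loading_matrix)))
  invisible(x)
}

#' Predict from a fitted pipeline
#'
#' @param object A `fitted_pipeline`.
#' @param newdata Genotype matrix containing the selected feature columns.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.fitted_pipeline <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    scores <- object$component_scores
  } else {
    X <- as.matrix(newdata)[, object$selected_ids, drop = FALSE]
    Xs <- sweep(sweep(X, 2, object$feature_center), 2, object$feature_scale, "/")
    scores <- sweep(Xs, 2, object$pca_center) %*% object$loading_matrix
  }
  drop(scores %*% object$ridge_coefficients) + object$ridge_intercept
}

#' @rdname fit_pipeline
#' @param x,object A `fitted_pipeline`.
#' @param ... Unused.
#' @export
tidy.fitted_pipeline <- function(x, ...) {
  tibble::tibble(component = colnames(x$loading_matrix) %||%
                   sprintf("PC%d", seq_along(x$ridge_coefficients)),
                 estimate = x$ridge_coefficients,
                 explained_variance = x$explained_variance)
}

#' @rdname fit_pipeline
#' @export
glance.fitted_pipeline <- function(x, ...) {
  m <- compute_metrics(x$y, predict(x))
  tibble::tibble(n_features = length(x$vt_mask),
                 n_vt = sum(x$vt_mask), n_ufs = sum(x$ufs_mask),
                 n_rfecv = sum(x$rfecv_mask),
                 n_components = ncol(x$loading_matrix),
                 r_squared = m$r2, rmse = m$rmse)
}

# --- DBO-driven optimization -------------------------------------------------

#' Optimize the pipeline parameters with the Dung Beetle Optimizer
#'
#' Wires [pipeline_fitness()] into [dbo_optimize()] over the search space of
#' [pipeline_param_space()].  Fitness evaluations are cached on the
#' equivalence class that determines the result (the variance-filter
#' survivor set plus the integer/categorical parameters), so positions that
#' decode to the same effective pipeline are not re-fitted.
#'
#' @param G Genotype matrix (samples x features, 0/1).
#' @param y Numeric phenotype vector.
#' @param pop_size,max_iter DBO budget (the default configuration is
#'   50 beetles / 100 iterations; planted-data studies use smaller budgets).
#' @param seed Seed for the optimizer.
#' @param min_features_range,max_components Passed to
#'   [pipeline_param_space()].
#' @param cv_folds,fold_seed,lambda Passed to [pipeline_fitness()].
#' @return A list of class `pipeline_search`: `best_params`
#'   ([pipeline_params()]), `best_fitness`, the `dbo` result, and
#'   `cache_stats` (distinct evaluations vs. total requests).
#' @export
optimize_pipeline <- function(G, y, pop_size = 50, max_iter = 100, seed = 1,
                              min_features_range = c(100, 300),
                              max_components = NULL,
                              cv_folds = 10, fold_seed = 2024, lambda = 1) {
  G <- as.matrix(G)
  space <- pipeline_param_space(nrow(G), min_features_range, max_components)
  config <- dbo_config(space$bounds, pop_size = pop_size, max_iter = max_iter,
                       dim_kinds = space$dim_kinds,
                       categories = space$categories, seed = seed)
  evaluator <- make_pipeline_evaluator(G, y, cv_folds, fold_seed, lambda,
                                       min_floor = min(min_features_range))
  cache <- new.env(parent = emptyenv())
  requests <- 0L
  objective <- function(pos) {
    requests <<- requests + 1L
    params <- decode_pipeline_params(pos, config)
    key <- paste(params$variance_threshold, params$percentile,
                 params$rfecv_step, params$min_features, params$scoring,
                 params$n_components, sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- evaluator(params)
    cache[[key]] <- val
    val
  }
  res <- dbo_optimize(objective, config)
  structure(
    list(best_params = decode_pipeline_params(res$best_position, config),
         best_fitness = res$best_fitness,
         dbo = res,
         cache_stats = c(distinct = length(ls(cache)), requests = requests)),
    class = "pipeline_search"
  )
}

#' @export
print.pipeline_search <- function(x, ...) {
  cat(sprintf("<pipeline_search> best fitness %.4f (%d distinct evaluations)\n",
              x$best_fitness, x$cache_stats[["distinct"]]))
  print(x$best_params)
  invisible(x)
}

# Memoized fitness evaluator for the optimizer.  Exploits the structure of
# the search space: the standardized VT survivors depend only on the
# variance threshold (via the survivor set), the univariate stage only on
# (survivors, percentile), and the elimination path with its out-of-fold
# predictions only on (survivors, percentile, step) — min_features truncates
# the path, the scoring criterion re-scores the cached predictions, and the
# PCA/ridge head reuses a cached SVD of the selected submatrix.  Every
# decoded parameter point therefore costs at most one expensive elimination
# path; results are bit-identical to evaluating [pipeline_fitness()] stage
# by stage.
make_pipeline_evaluator <- function(G, y, cv_folds = 10, fold_seed = 2024,
                                    lambda = 1, min_floor = 100L) {
  G <- as.matrix(G)
  n <- nrow(G)
  var_j <- col_pop_var(G)
  folds <- kfold_assign(n, cv_folds, fold_seed)
  std_cache <- new.env(parent = emptyenv())
  ufs_cache <- new.env(parent = emptyenv())
  path_cache <- new.env(parent = emptyenv())
  svd_cache <- new.env(parent = emptyenv())

  function(params) {
    tryCatch({
      if (var(y) == 0) return(-Inf)
      vt <- var_j >= params$variance_threshold
      if (!any(vt)) return(-Inf)
      vkey <- rlang::hash(which(vt))
      Xs <- std_cache[[vkey]]
      if (is.null(Xs)) {
        Xs <- standardize_features(G[, vt, drop = FALSE])
        std_cache[[vkey]] <- Xs
      }
      ukey <- paste(vkey, params$percentile)
      ufs <- ufs_cache[[ukey]]
      if (is.null(ufs)) {
        ufs <- univariate_f_select(Xs, y, params$percentile)
        ufs_cache[[ukey]] <- ufs
      }
      if (sum(ufs) < params$min_features) return(-Inf)
      pkey <- paste(ukey, params$rfecv_step)
      path <- path_cache[[pkey]]
      if (is.null(path)) {
        floor_k <- min(min_floor, params$min_features)
        path <- rfecv_path_cpp(Xs[, ufs, drop = FALSE], y,
                               as.integer(folds), lambda,
                               as.integer(params$rfecv_step),
                               as.integer(floor_k))
        path$ufs_idx <- which(ufs)
        path_cache[[pkey]] <- path
      }
      keep <- path$counts >= params$min_features
      if (!any(keep)) return(-Inf)   # path floor above request (cannot occur)
      scores <- score_pred_path(path$preds[, keep, drop = FALSE],
                                y, folds, params$scoring)
      counts_eval <- path$counts[keep]
      if (counts_eval[length(counts_eval)] > params$min_features) {
        # requested floor sits between grid counts: survivors there are the
        # complement of the elimination-order prefix; score them directly
        surv <- path_survivors(path, params$min_features)
        pred <- cv_gram_predictions(
          Xs[, path$ufs_idx[surv], drop = FALSE], y, folds, lambda)
        scores <- c(scores,
                    score_pred_path(matrix(pred, ncol = 1), y, folds,
                                    params$scoring))
        counts_eval <- c(counts_eval, params$min_features)
      }
      best <- max(which(scores == max(scores)))   # ties -> fewer features
      sel <- path$ufs_idx[path_survivors(path, counts_eval[best])]
      if (params$n_components > min(n - 1, length(sel))) return(-Inf)
      skey <- rlang::hash(sel)
      sv <- svd_cache[[skey]]
      if (is.null(sv)) {
        sv <- pca_reduce(Xs[, sel, drop = FALSE],
                         min(n - 1, length(sel)))
        svd_cache[[skey]] <- sv
      }
      cv_ridge_score(sv$scores[, seq_len(params$n_components), drop = FALSE],
                     y, folds, params$scoring, lambda)
    }, error = function(e) -Inf)
  }
}

#' Stage-wise cross-validated performance
#'
#' Reports the mean CV R2 of ridge regression on the surviving features after
#' each pipeline stage (no selection, variance threshold, univariate F,
#' RFECV, PCA), the stage-progression picture of the method.
#'
#' @inheritParams pipeline_fitness
#' @return Tibble with `stage`, `n_features`, `cv_r2`.
#' @export
stage_progression <- function(params, G, y, cv_folds = 10, fold_seed = 2024,
                              lambda = 1) {
  G <- as.matrix(G)
  st <- run_stages(params, G, y, cv_folds, fold_seed, lambda)
  folds <- kfold_assign(nrow(G), cv_folds, fold_seed)
  score_of <- function(X) cv_ridge_gram(as.matrix(X), y, folds, lambda)
  Xs_all <- standardize_features(G)
  tibble::tibble(
    stage = c("none", "vt", "ufs", "rfecv", "pca"),
    n_features = c(ncol(G), sum(st$vt_mask), sum(st$ufs_mask),
                   sum(st$rfecv_mask), ncol(st$pca$scores)),
    cv_r2 = c(score_of(Xs_all),
              score_of(st$Xs),
              score_of(st$Xs[, st$ufs_mask[st$vt_mask], drop = FALSE]),
              score_of(st$X_sel),
              cv_ridge_score(st$pca$scores, y, folds, "r2", lambda))
  )
}

# Out-of-fold dual (gram) ridge predictions in R; mirrors the compiled
# core's centered-gram formulation, for wide matrices where p can exceed n.
cv_gram_predictions <- function(Xs, y, folds, lambda = 1) {
  K <- tcrossprod(Xs)
  pred <- numeric(nrow(K))
  for (f in seq_len(max(folds))) {
    tr <- which(folds != f); te <- which(folds == f)
    Ktr <- K[tr, tr, drop = FALSE]
    m <- rowMeans(Ktr); g <- mean(m)
    Kc <- sweep(sweep(Ktr, 1, m), 2, m) + g
    diag(Kc) <- diag(Kc) + lambda
    ym <- mean(y[tr])
    a <- solve(Kc, y[tr] - ym)
    Kte <- K[te, tr, drop = FALSE]
    Kte_c <- sweep(sweep(Kte, 1, rowMeans(Kte)), 2, m) + g
    pred[te] <- drop(Kte_c %*% a) + ym
  }
  pred
}

cv_ridge_gram <- function(X, y, folds, lambda = 1) {
  pred <- cv_gram_predictions(standardize_features(X), y, folds, lambda)
  score_pred_path(matrix(pred, ncol = 1), y, folds, "r2")
}

#' @rdname stage_progression
#' @param data Tibble from [stage_progression()] (optionally row-bound over
#'   phenotypes with a `phenotype` column).
#' @return A ggplot object.
#' @export
plot_stage_progression <- function(data) {
  data$stage <- factor(data$stage, levels = c("none", "vt", "ufs", "rfecv", "pca"))
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$stage, y = .data$cv_r2,
                                          group = 1)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Selection stage", y = "Mean CV R²") +
    ggplot2::theme_minimal()
  if ("phenotype" %in% names(data)) {
    p <- p + ggplot2::facet_wrap(~phenotype, scales = "free_y") +
      ggplot2::aes(group = .data$phenotype)
  }
  p
}
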