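# Candidate regressor registry and 10-fold cross-validated model comparison.
#
# Ten classic regression families are compared on the pipeline's component
# scores; hyperparameters are frozen library defaults (kept in one registry so
# runs are reproducible), since the method's contribution is the feature
# selection, not model tuning.

#' Regression metrics
#'
#' Standard definitions: `r2 = 1 - SS_res / SS_tot` (total sum of squares
#' about the mean of `y_true`), `mae`, `mse`, and `rmse = sqrt(mse)`.
#'
#' @param y_true Observed values (length >= 2, nonzero variance).
#' @param y_pred Predicted values, same length.
#' @return A one-row tibble with `r2`, `mae`, `mse`, `rmse`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) abort("length mismatch")
  if (length(y_true) < 2) abort("need at least 2 observations")
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) abort("y_true has zero variance; R2 is undefined")
  err <- y_true - y_pred
  mse <- mean(err^2)
  tibble::tibble(r2 = 1 - sum(err^2) / ss_tot,
                 mae = mean(abs(err)),
                 mse = mse,
                 rmse = sqrt(mse))
}

#' Names of the candidate regressors
#' @return Character vector of the ten registry model names.
#' @export
model_names <- function() {
  c("ridge", "neural_net", "svr", "random_forest", "lasso",
    "gradient_boosting", "decision_tree", "xgboost",
    "k_nearest_neighbors", "elastic_net")
}

# Registry: each entry fits on (X, y) and returns a predict(newX) closure.
# Stochastic learners take an explicit seed so CV runs are reproducible.
model_registry <- function(seed = 1) {
  list(
    ridge = function(X, y) {
      fit <- ridge_fit(X, y, lambda = 1)
      function(newX) ridge_predict(fit, newX)
    },
    lasso = function(X, y) {
      fit <- glmnet::glmnet(X, y, alpha = 1, lambda = 0.01)
      function(newX) drop(predict(fit, as.matrix(newX)))
    },
    elastic_net = function(X, y) {
      fit <- glmnet::glmnet(X, y, alpha = 0.5, lambda = 0.01)
      function(newX) drop(predict(fit, as.matrix(newX)))
    },
    svr = function(X, y) {
      fit <- e1071::svm(as.matrix(X), y, type = "eps-regression",
                        kernel = "radial")
      function(newX) unname(predict(fit, as.matrix(newX)))
    },
    random_forest = function(X, y) {
      d <- data.frame(y = y, X)
      fit <- ranger::ranger(y ~ ., data = d, num.trees = 100,
                            seed = seed, num.threads = 1)
      function(newX) predict(fit, data.frame(as.matrix(newX)),
                             num.threads = 1)$predictions
    },
    gradient_boosting = function(X, y) {
      fit <- gb_fit(as.matrix(X), y, n_trees = 100, shrinkage = 0.1,
                    max_depth = 3)
      function(newX) gb_predict(fit, as.matrix(newX))
    },
    decision_tree = function(X, y) {
      d <- data.frame(y = y, X)
      fit <- rpart::rpart(y ~ ., data = d)
      function(newX) unname(predict(fit, data.frame(as.matrix(newX))))
    },
    xgboost = function(X, y) {
      fit <- withr::with_seed(seed, xgboost::xgboost(
        x = as.matrix(X), y = y, nrounds = 100, max_depth = 6,
        learning_rate = 0.3, nthreads = 1, verbosity = 0
      ))
      function(newX) predict(fit, as.matrix(newX))
    },
    k_nearest_neighbors = function(X, y) {
      fit <- caret::knnreg(as.matrix(X), y, k = 5)
      function(newX) predict(fit, as.matrix(newX))
    },
    neural_net = function(X, y) {
      fit <- withr::with_seed(seed, mlp_fit(as.matrix(X), y))
      function(newX) mlp_predict(fit, as.matrix(newX))
    }
  )
}

# Single-hidden-layer MLP regressor (tanh hidden layer, linear output)
# trained by full-batch Adam on the squared error with L2 weight decay.
# Written in-package because the neural-network fitters installed here use
# full-BFGS optimization, which is quadratic in the weight count and
# infeasible at the input dimensions the pipeline produces; full-batch Adam
# on matrix operations fits the same architecture in seconds.  All
# hyperparameters are frozen in the registry (64 hidden units, 300 epochs).
mlp_fit <- function(X, y, hidden = 64, epochs = 300, lr = 0.01,
                    decay = 1e-4) {
  n <- nrow(X); p <- ncol(X)
  ctr <- colMeans(X)
  scl <- pmax(apply(X, 2, sd), 1e-8)
  Xs <- scale(X, ctr, scl)
  ym <- mean(y); ys <- max(sd(y), 1e-8)
  yt <- (y - ym) / ys
  W1 <- matrix(rnorm(p * hidden, sd = 1 / sqrt(p)), p, hidden)
  b1 <- numeric(hidden)
  W2 <- matrix(rnorm(hidden, sd = 1 / sqrt(hidden)), hidden, 1)
  b2 <- 0
  mom <- lapply(c(W1 = 1, b1 = 1, W2 = 1, b2 = 1), function(.) 0)
  vel <- mom
  b1a <- 0.9; b2a <- 0.999; eps <- 1e-8
  params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  for (t in seq_len(epochs)) {
    H <- tanh(sweep(Xs %*% params$W1, 2, params$b1, "+"))
    pred <- drop(H %*% params$W2) + params$b2
    err <- pred - yt
    d_out <- matrix(err / n, n, 1)
    g <- list(
      W2 = crossprod(H, d_out) + decay * params$W2,
      b2 = sum(d_out),
      W1 = NULL, b1 = NULL)
    d_hid <- (d_out %*% t(params$W2)) * (1 - H^2)
    g$W1 <- crossprod(Xs, d_hid) + decay * params$W1
    g$b1 <- colSums(d_hid)
    for (nm in names(params)) {
      mom[[nm]] <- b1a * mom[[nm]] + (1 - b1a) * g[[nm]]
      vel[[nm]] <- b2a * vel[[nm]] + (1 - b2a) * g[[nm]]^2
      m_hat <- mom[[nm]] / (1 - b1a^t)
      v_hat <- vel[[nm]] / (1 - b2a^t)
      params[[nm]] <- params[[nm]] - lr * m_hat / (sqrt(v_hat) + eps)
    }
  }
  list(params = params, ctr = ctr, scl = scl, ym = ym, ys = ys)
}

mlp_predict <- function(fit, X) {
  Xs <- scale(X, fit$ctr, fit$scl)
  H <- tanh(sweep(Xs %*% fit$params$W1, 2, fit$params$b1, "+"))
  drop(H %*% fit$params$W2 + fit$params$b2) * fit$ys + fit$ym
}

# Least-squares gradient boosting over rpart base learners (Friedman-style:
# each tree fits the current residuals, added with a shrinkage factor).
gb_fit <- function(X, y, n_trees = 100, shrinkage = 0.1, max_depth = 3) {
  d <- data.frame(X)
  f0 <- mean(y)
  resid <- y - f0
  trees <- vector("list", n_trees)
  ctrl <- rpart::rpart.control(maxdepth = max_depth, cp = 0, minsplit = 5,
                               xval = 0)
  for (m in seq_len(n_trees)) {
    d$.resid <- resid
    tr <- rpart::rpart(.resid ~ ., data = d, control = ctrl)
    resid <- resid - shrinkage * unname(predict(tr, d))
    trees[[m]] <- tr
  }
  list(f0 = f0, trees = trees, shrinkage = shrinkage)
}

gb_predict <- function(fit, X) {
  d <- data.frame(X)
  pred <- rep(fit$f0, nrow(d))
  for (tr in fit$trees) pred <- pred + fit$shrinkage * unname(predict(tr, d))
  pred
}

# Per-fold metrics tolerant of degenerate folds: R2 needs at least two test
# samples with variance (leave-one-out folds report NA there); the error
# metrics are always defined.
fold_metrics_safe <- function(y_true, y_pred) {
  err <- y_true - y_pred
  mse <- mean(err^2)
  ss_tot <- sum((y_true - mean(y_true))^2)
  tibble::tibble(
    r2 = if (length(y_true) < 2 || ss_tot == 0) NA_real_ else
      1 - sum(err^2) / ss_tot,
    mae = mean(abs(err)), mse = mse, rmse = sqrt(mse))
}

#' Cross-validate one candidate regressor
#'
#' Shuffled k-fold CV: each sample appears in exactly one test fold; metrics
#' are computed per fold and averaged.  Folds too small to define R2
#' (leave-one-out) report `NA` for the fold-mean R2; the error metrics are
#' always defined.
#'
#' @param X Predictor matrix (typically the pipeline's component scores).
#' @param y Numeric response.
#' @param model One of [model_names()].
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold shuffle and any stochastic learner.
#' @return One-row tibble with `model` and fold-mean `r2`, `mae`, `mse`,
#'   `rmse`; the fold assignment is attached as attribute `folds`.
#' @export
cross_validate_model <- function(X, y, model = "ridge", k = 10, seed = 1) {
  X <- as.matrix(X)
  registry <- model_registry(seed)
  if (!model %in% names(registry)) {
    abort(sprintf("unknown model '%s'; registry: %s", model,
                  paste(model_names(), collapse = ", ")))
  }
  folds <- kfold_assign(nrow(X), k, seed)
  fold_metrics <- purrr::map(seq_len(k), function(f) {
    tr <- folds != f
    predict_fn <- registry[[model]](X[tr, , drop = FALSE], y[tr])
    fold_metrics_safe(y[!tr], predict_fn(X[!tr, , drop = FALSE]))
  }) %>% purrr::list_rbind()
  out <- dplyr::bind_cols(tibble::tibble(model = model),
                          dplyr::summarise(fold_metrics,
                                           dplyr::across(dplyr::everything(),
                                                         mean)))
  attr(out, "folds") <- folds
  out
}

#' Evaluate candidate regressors under cross-validation
#'
#' @param X Predictor matrix.
#' @param y Numeric response.
#' @param models Model names to evaluate (default: the full registry).
#' @param k,seed Passed to [cross_validate_model()].
#' @return Tibble with one row per model (class `eval_report`).
#' @export
evaluate_models <- function(X, y, models = model_names(), k = 10, seed = 1) {
  out <- purrr::map(models,
                    function(m) cross_validate_model(X, y, m, k, seed)) %>%
    purrr::list_rbind()
  class(out) <- c("eval_report", class(out))
  attr(out, "seed") <- seed
  out
}

#' Select the best model per phenotype
#'
#' The best model maximizes the mean fold R2; ties break to the
#' lexicographically first model name.
#'
#' @param report A tibble of per-model metrics (from [evaluate_models()]),
#'   optionally with a `phenotype` column for multi-phenotype reports.
#' @return Tibble with one row per phenotype: `phenotype` (if present),
#'   `best_model` and its metrics.
#' @export
select_best_model <- function(report) {
  if (nrow(report) == 0) abort("empty report")
  grp <- if ("phenotype" %in% names(report)) "phenotype" else character(0)
  report %>%
    dplyr::arrange(dplyr::desc(.data$r2), .data$model) %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) %>%
    dplyr::slice(1) %>%
    dplyr::ungroup() %>%
    dplyr::rename(best_model = "model")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d model evaluations\n", nrow(x)))
  NextMethod()
}
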