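test_that("metrics follow the standard definitions and identities", {
  m <- compute_metrics(c(1, 2, 3, 4), c(1, 2, 3, 5))
  expect_equal(m$mse, 0.25)
  expect_equal(m$mae, 0.25)
  expect_equal(m$rmse, 0.5)
  expect_equal(m$r2, 0.8)          # 1 - 0.25/1.25 on the population variance
  perfect <- compute_metrics(c(1, 5, 2), c(1, 5, 2))
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$mae + perfect$mse + perfect$rmse, 0)
  null_model <- compute_metrics(c(1, 2, 3), rep(2, 3))
  expect_equal(null_model$r2, 0)
  expect_error(compute_metrics(rep(1, 4), rnorm(4)), "zero variance")
  expect_error(compute_metrics(1:4, 1:3), "length")
})

test_that("fold partitions are disjoint, exhaustive and seed-stable", {
  for (k in c(2, 5, 10, 30)) {
    f <- pansense:::kfold_assign(30, k, seed = 3)
    expect_equal(sort(unique(f)), 1:k)
    expect_equal(length(f), 30)
    sizes <- table(f)
    expect_lte(diff(range(sizes)), 1)
  }
  expect_identical(pansense:::kfold_assign(50, 10, 7),
                   pansense:::kfold_assign(50, 10, 7))
  expect_error(pansense:::kfold_assign(5, 10, 1), "folds")
})

test_that("ridge agrees with an independent ridge implementation", {
  set.seed(41)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- drop(X %*% rnorm(6)) + rnorm(40)
  fit <- pansense:::ridge_fit(X, y, lambda = 2.5)
  want <- brute_ridge(X, y, lambda = 2.5)
  expect_equal(fit$coef, want$coef, tolerance = 1e-10)
  expect_equal(fit$intercept, want$intercept, tolerance = 1e-10)
  # MASS::lm.ridge as a second, external oracle (same centered formulation
  # when given pre-standardized inputs)
  Xs <- scale(X) * sqrt(40 / 39)   # population-sd standardization
  fit2 <- pansense:::ridge_fit(Xs, y, lambda = 2.5)
  mass <- MASS::lm.ridge(y ~ Xs, lambda = 2.5)
  expect_equal(unname(fit2$coef), unname(coef(mass)[-1]), tolerance = 1e-6)
  # dual and primal solves agree when p > n
  Xw <- matrix(rnorm(10 * 25), 10, 25)
  yw <- rnorm(10)
  dual <- pansense:::ridge_fit(Xw, yw, 1)
  xm <- colMeans(Xw); Xc <- sweep(Xw, 2, xm)
  primal <- solve(crossprod(Xc) + diag(25), crossprod(Xc, yw - mean(yw)))
  expect_equal(dual$coef, drop(primal), tolerance = 1e-8)
})

test_that("cross-validation covers each sample once and is reproducible", {
  set.seed(2)
  X <- matrix(rnorm(30 * 4), 30, 4)
  y <- drop(X %*% c(1, -2, 0.5, 0)) + rnorm(30, sd = 0.1)
  r <- cross_validate_model(X, y, "ridge", k = 30, seed = 5)  # leave-one-out
  folds <- attr(r, "folds")
  expect_equal(sort(unique(folds)), 1:30)
  expect_equal(as.vector(table(folds)), rep(1L, 30))
  expect_true(is.na(r$r2))              # R2 undefined on single-sample folds
  expect_true(is.finite(r$mae) && is.finite(r$rmse))
  r1 <- cross_validate_model(X, y, "ridge", k = 10, seed = 9)
  r2 <- cross_validate_model(X, y, "ridge", k = 10, seed = 9)
  expect_identical(r1$r2, r2$r2)
  expect_error(cross_validate_model(X, y, "kriging", 5, 1), "registry")
})

test_that("ridge recovers noise-free linear data almost perfectly under CV", {
  set.seed(13)
  X <- matrix(rnorm(60 * 5), 60, 5)
  y <- drop(X %*% c(2, -1, 0.5, 1, -2)) + 3
  r <- cross_validate_model(X, y, "ridge", k = 10, seed = 1)
  expect_gte(r$r2, 0.99)
})

test_that("all ten registry models run and their metric identities hold", {
  set.seed(77)
  X <- matrix(rnorm(60 * 4), 60, 4)
  colnames(X) <- paste0("PC", 1:4)
  y <- drop(X %*% c(1.5, -1, 0.8, 0)) + rnorm(60, sd = 0.4)
  rep <- evaluate_models(X, y, k = 5, seed = 3)
  expect_setequal(rep$model, model_names())
  expect_equal(nrow(rep), 10)
  expect_true(all(is.finite(rep$r2)))
  expect_true(all(rep$mae >= 0 & rep$mse >= 0))
  # per-fold identities: rmse^2 = mse and r2 = 1 - mse/var on each fold
  folds <- pansense:::kfold_assign(60, 5, 3)
  for (f in 1:5) {
    te <- folds == f
    fit <- pansense:::ridge_fit(X[!te, ], y[!te], 1)
    pred <- pansense:::ridge_predict(fit, X[te, ])
    m <- compute_metrics(y[te], pred)
    expect_equal(m$rmse^2, m$mse, tolerance = 1e-10)
    expect_equal(m$r2, 1 - m$mse / (mean((y[te] - mean(y[te]))^2)),
                 tolerance = 1e-10)
  }
})

test_that("best-model selection maximizes mean R2 with lexicographic ties", {
  rep <- tibble::tibble(model = c("svr", "ridge", "lasso"),
                        r2 = c(0.91, 0.92, 0.92),
                        mae = 1:3, mse = 1:3, rmse = 1:3)
  best <- select_best_model(rep)
  expect_equal(best$best_model, "lasso")   # tie 0.92 -> first alphabetically
  single <- select_best_model(rep[1, ])
  expect_equal(single$best_model, "svr")
  two_ph <- dplyr::bind_rows(
    dplyr::mutate(rep, phenotype = "a"),
    dplyr::mutate(rep, phenotype = "b", r2 = c(0.99, 0.1, 0.2)))
  best2 <- select_best_model(two_ph)
  expect_equal(best2$best_model[best2$phenotype == "b"], "svr")
})

test_that("linear models win on sparse linear signal more often than trees", {
  wins <- vapply(1:5, function(s) {
    set.seed(s)
    X <- matrix(rnorm(80 * 6), 80, 6)
    colnames(X) <- paste0("PC", 1:6)
    y <- drop(X[, 1:2] %*% c(2, -1.5)) + rnorm(80, sd = 0.3)
    rep <- evaluate_models(X, y, models = c("ridge", "lasso", "elastic_net",
                                            "decision_tree"),
                           k = 5, seed = s)
    best <- select_best_model(rep)
    best$best_model != "decision_tree"
  }, logical(1))
  expect_gte(mean(wins), 0.8)   # median over seeds: linear family wins
})

test_that("evaluation reports round-trip through CSV serialization", {
  set.seed(10)
  X <- matrix(rnorm(40 * 3), 40, 3)
  colnames(X) <- paste0("PC", 1:3)
  y <- rnorm(40)
  rep <- evaluate_models(X, y, models = c("ridge", "decision_tree"),
                         k = 4, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(rep, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(rep), tolerance = 1e-12,
               ignore_attr = TRUE)
})
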