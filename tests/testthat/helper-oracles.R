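# Independent brute-force oracles and small fixture builders.  The oracles
# deliberately avoid the package's computation paths: plain per-feature
# loops, primal closed-form ridge, and literal metric formulas.

small_panel <- function(n = 60, p = c(snp = 120, gene = 60, igr = 40),
                        n_phen = 2, n_causal = 10, seed = 5,
                        signal_fraction = 0.9) {
  d <- sim_design(n_samples = n, n_features = p, n_phenotypes = n_phen,
                  n_causal = n_causal, signal_fraction = signal_fraction,
                  seed = seed)
  G <- simulate_genotypes(d)
  P <- simulate_phenotypes(G, d)
  list(design = d, G = G, P = P)
}

# Per-feature Pearson-correlation F statistic, computed feature by feature.
brute_f_scores <- function(X, y) {
  n <- nrow(X)
  apply(X, 2, function(x) {
    if (sd(x) == 0) return(0)
    r <- cor(x, y)
    if (abs(r) >= 1) return(Inf)
    r^2 * (n - 2) / (1 - r^2)
  })
}

brute_ufs <- function(X, y, percentile) {
  f <- brute_f_scores(X, y)
  n_keep <- max(1L, ceiling(ncol(X) * percentile / 100))
  keep <- order(-f, seq_along(f))[seq_len(n_keep)]
  mask <- logical(ncol(X))
  mask[keep] <- TRUE
  mask
}

# Primal closed-form ridge with unpenalized intercept.
brute_ridge <- function(X, y, lambda = 1) {
  X <- as.matrix(X)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  beta <- solve(crossprod(Xc) + lambda * diag(ncol(X)), crossprod(Xc, yc))
  list(intercept = ym - sum(xm * beta), coef = drop(beta))
}

brute_metric <- function(y, pred, scoring) {
  switch(scoring,
         r2 = 1 - sum((y - pred)^2) / sum((y - mean(y))^2),
         mse = -mean((y - pred)^2),
         rmse = -sqrt(mean((y - pred)^2)),
         mae = -mean(abs(y - pred)))
}

# Literal RFECV: standardize, loop elimination rounds, score every count by
# k-fold CV of primal ridge, pick the best count (ties -> fewer features).
brute_rfecv <- function(X, y, step, min_features, scoring, folds,
                        lambda = 1) {
  X <- as.matrix(X)
  m <- colMeans(X)
  s <- sqrt(colMeans(X^2) - m^2)
  Xs <- sweep(X, 2, m)
  Xs <- sweep(Xs, 2, ifelse(s > 0, s, 1), "/")
  Xs[, s == 0] <- 0
  active <- seq_len(ncol(X))
  path <- list()
  repeat {
    cv <- mean(vapply(seq_len(max(folds)), function(f) {
      tr <- folds != f
      fit <- brute_ridge(Xs[tr, active, drop = FALSE], y[tr], lambda)
      pred <- drop(Xs[!tr, active, drop = FALSE] %*% fit$coef) + fit$intercept
      brute_metric(y[!tr], pred, scoring)
    }, numeric(1)))
    path[[length(path) + 1]] <- list(active = active, score = cv)
    if (length(active) <= min_features) break
    fit <- brute_ridge(Xs[, active, drop = FALSE], y, lambda)
    s_drop <- min(step, length(active) - min_features)
    ord <- order(abs(fit$coef), seq_along(active))
    active <- active[-ord[seq_len(s_drop)]]
  }
  scores <- vapply(path, `[[`, numeric(1), "score")
  best <- max(which(scores == max(scores)))   # fewer features on ties
  mask <- logical(ncol(X))
  mask[path[[best]]$active] <- TRUE
  list(mask = mask, scores = scores,
       counts = vapply(path, function(p) length(p$active), integer(1)))
}

rastrigin <- function(x) sum(x^2 - 10 * cos(2 * pi * x) + 10)
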