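# Internal numerical helpers shared across modules.

# Shuffled k-fold assignment: returns an integer vector in 1..k, one entry per
# sample, fold sizes differing by at most one.  All CV in the package goes
# through this so fitness evaluation and final evaluation share fold geometry
# for a given seed.
kfold_assign <- function(n, k, seed) {
  if (k > n) abort(sprintf("cannot make %d folds from %d samples", k, n))
  if (k < 2) abort("need at least 2 folds")
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  folds <- integer(n)
  folds[perm] <- rep_len(seq_len(k), n)
  folds
}

# Ridge regression with unpenalized intercept, penalty lambda * ||beta||^2 on
# the squared-error loss (plain penalized RSS, no 1/n scaling).  Primal solve
# for p <= n, dual (gram) solve otherwise; both are exact for lambda > 0.
ridge_fit <- function(X, y, lambda = 1) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  yc <- y - ym
  if (p <= n) {
    A <- crossprod(Xc)
    diag(A) <- diag(A) + lambda
    beta <- drop(solve(A, crossprod(Xc, yc)))
  } else {
    K <- tcrossprod(Xc)
    diag(K) <- diag(K) + lambda
    alpha <- solve(K, yc)
    beta <- drop(crossprod(Xc, alpha))
  }
  list(intercept = ym - sum(xm * beta), coef = beta)
}

ridge_predict <- function(fit, X) {
  drop(as.matrix(X) %*% fit$coef) + fit$intercept
}

# Population (divide-by-n) variance per column; the variance filter and the
# generator's calibration both use the population convention.
col_pop_var <- function(X) {
  n <- nrow(X)
  m <- colMeans(X)
  colMeans(X * X) - m * m
}

# Derive a stream-specific 32-bit seed from a base seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483587)
}
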