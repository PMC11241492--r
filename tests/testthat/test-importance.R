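fit_small_pipeline <- function(seed, n = 50, noise_free = FALSE,
                               n_components = 8) {
  pan <- small_panel(n = n, p = c(snp = 120, gene = 70, igr = 50),
                     n_phen = 1, n_causal = 10, seed = seed,
                     signal_fraction = if (noise_free) 1 else 0.9)
  fp <- fit_pipeline(pipeline_params(5e-5, 75, 5, 100, "r2", n_components),
                     pan$G, pan$P[[2]])
  list(fp = fp, pan = pan)
}

test_that("contributions are the loading-weighted coefficient sums", {
  fp <- fit_small_pipeline(1)$fp
  iv <- propagate_importance(fp)
  expect_equal(nrow(iv), sum(fp$rfecv_mask))
  expect_equal(iv$contribution,
               unname(drop(fp$loading_matrix %*% fp$ridge_coefficients)))
  # identity loadings -> contributions equal the coefficients
  fp2 <- fp
  k <- length(fp2$ridge_coefficients)
  fp2$loading_matrix <- diag(k)
  rownames(fp2$loading_matrix) <- fp2$selected_ids[1:k]
  fp2$selected_ids <- fp2$selected_ids[1:k]
  expect_equal(propagate_importance(fp2)$contribution,
               fp2$ridge_coefficients, ignore_attr = TRUE)
  # single component scalar multiply
  fp3 <- fp
  fp3$loading_matrix <- matrix(c(0.6, -0.8), 2, 1,
                               dimnames = list(fp$selected_ids[1:2], "PC1"))
  fp3$ridge_coefficients <- 2
  fp3$selected_ids <- fp$selected_ids[1:2]
  expect_equal(propagate_importance(fp3)$contribution, c(1.2, -1.6))
  # shape mismatch is an error
  fp4 <- fp
  fp4$ridge_coefficients <- fp$ridge_coefficients[-1]
  expect_error(propagate_importance(fp4), "components")
})

test_that("contributions match finite-difference slopes of the predictor", {
  # chain-rule oracle: perturb one standardized feature by +delta, recompute
  # scores and the ridge prediction, and take the slope
  for (s in 1:20) {
    fp <- fit_small_pipeline(s)$fp
    iv <- propagate_importance(fp)
    delta <- 1e-5
    Xs <- matrix(0, 1, length(fp$selected_ids))  # standardized origin
    base_scores <- sweep(Xs, 2, fp$pca_center) %*% fp$loading_matrix
    base_pred <- drop(base_scores %*% fp$ridge_coefficients)
    probe <- sample(length(fp$selected_ids), 5)
    for (j in probe) {
      Xp <- Xs
      Xp[1, j] <- Xp[1, j] + delta
      pred <- drop((sweep(Xp, 2, fp$pca_center) %*% fp$loading_matrix) %*%
                     fp$ridge_coefficients)
      slope <- (pred - base_pred) / delta
      expect_equal(slope, iv$contribution[j], tolerance = 1e-6)
    }
  }
})

test_that("prediction consistency: contributions reproduce component predictions", {
  for (s in c(3, 9)) {
    fp <- fit_small_pipeline(s)$fp
    iv <- propagate_importance(fp)
    via_components <- fp$component_scores %*% fp$ridge_coefficients
    Xsel <- fit_small_pipeline(s)$pan$G[, fp$selected_ids]
    Xsel <- sweep(sweep(Xsel, 2, fp$feature_center), 2, fp$feature_scale, "/")
    Xc <- sweep(Xsel, 2, fp$pca_center)
    via_features <- Xc %*% iv$contribution
    expect_equal(unname(drop(via_features)), unname(drop(via_components)),
                 tolerance = 1e-8)
  }
})

test_that("importance is linear in the coefficients and permutation-stable", {
  out <- fit_small_pipeline(5)
  fp <- out$fp
  iv <- propagate_importance(fp)
  fp_scaled <- fp
  fp_scaled$ridge_coefficients <- 3 * fp$ridge_coefficients
  expect_equal(propagate_importance(fp_scaled)$contribution,
               3 * iv$contribution)
  # permuting the input feature order permutes contributions identically
  pan <- out$pan
  perm <- withr::with_seed(8, sample(ncol(pan$G)))
  Gp <- pan$G[, perm]
  fp_p <- fit_pipeline(fp$params, Gp, pan$P[[2]])
  iv_p <- propagate_importance(fp_p)
  expect_equal(dplyr::arrange(as.data.frame(iv_p[c("feature_id", "contribution")]),
                              feature_id),
               dplyr::arrange(as.data.frame(iv[c("feature_id", "contribution")]),
                              feature_id),
               tolerance = 1e-6)
})

test_that("top-k ranking orders by absolute value with ties on feature id", {
  iv <- tibble::tibble(feature_id = c("F1", "F2", "F3"),
                       contribution = c(-3, 1, 2))
  top <- rank_top_k(iv, 2)
  expect_equal(top$feature_id, c("F1", "F3"))
  expect_equal(top$contribution, c(-3, 2))   # signs retained
  zeros <- tibble::tibble(feature_id = sprintf("F%02d", 5:1),
                          contribution = rep(0, 5))
  expect_equal(rank_top_k(zeros, 3)$feature_id, c("F01", "F02", "F03"))
  expect_equal(nrow(rank_top_k(iv, 10)), 3)
  expect_error(rank_top_k(iv, 0), "k")
})

test_that("top-ranked features are dominated by planted causal features", {
  hits <- vapply(1:5, function(s) {
    pan <- small_panel(n = 150, p = c(snp = 150, gene = 80, igr = 50),
                       n_phen = 1, n_causal = 20, seed = s,
                       signal_fraction = 1)
    fp <- fit_pipeline(pipeline_params(5e-5, 100, 5, 100, "r2", 95),
                       pan$G, pan$P[[2]])
    top <- rank_top_k(propagate_importance(fp), 20)
    causal <- pan$design$phenotype_specs[[1]]$causal_ids
    mean(top$feature_id %in% causal)
  }, numeric(1))
  expect_gte(median(hits), 0.8)
})
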