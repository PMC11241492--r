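test_that("genotype simulation is deterministic with correct shape and ids", {
  d <- sim_design(n_samples = 10, n_features = c(snp = 5, gene = 3, igr = 2),
                  n_phenotypes = 2, n_causal = 2, seed = 42)
  G1 <- simulate_genotypes(d)
  G2 <- simulate_genotypes(d)
  expect_identical(unclass(G1), unclass(G2))
  expect_equal(dim(G1), c(10L, 10L))
  expect_true(all(G1 %in% c(0L, 1L)))
  expect_equal(colnames(G1),
               c(sprintf("SNP_%06d", 1:5), sprintf("GENE_%06d", 1:3),
                 sprintf("IGR_%06d", 1:2)))
  expect_equal(as.integer(table(feature_classes(G1))[c("SNP", "GENE", "IGR")]),
               c(5L, 3L, 2L))
})

test_that("fixed presence probability gives the Bernoulli mean and variance", {
  n <- 1e5
  d <- sim_design(n_samples = n, n_features = c(snp = 4, gene = 3, igr = 3),
                  presence_prob_range = c(0.5, 0.5), n_phenotypes = 2,
                  n_causal = 2, seed = 7)
  G <- simulate_genotypes(d)
  expect_true(all(abs(colMeans(G) - 0.5) < 4 / sqrt(n)))
  # population variance converges to p(1-p) = 0.25
  v <- colMeans(G^2) - colMeans(G)^2
  expect_true(all(abs(v - 0.25) < 0.01))
})

test_that("invalid designs are rejected with the offending field named", {
  expect_error(sim_design(n_samples = 0), "n_samples")
  expect_error(sim_design(n_features = c(snp = 0, gene = 3, igr = 2)),
               "n_features")
  expect_error(sim_design(presence_prob_range = c(0, 0.5)),
               "presence_prob_range")
  expect_error(sim_design(noise_sd = -1), "noise_sd")
  d <- sim_design(n_samples = 10, n_features = c(snp = 5, gene = 3, igr = 2),
                  n_phenotypes = 1, n_causal = 2, seed = 1)
  expect_error(
    sim_design(n_samples = 10, n_features = c(snp = 5, gene = 3, igr = 2),
               phenotype_specs = list(list(name = "x",
                                           causal_ids = "SNP_999999",
                                           effects = 1))),
    "causal ids")
})

test_that("planted causal overlap matches the design overlap matrix", {
  d <- sim_design(n_samples = 20, n_features = c(snp = 400, gene = 200,
                                                 igr = 100),
                  n_phenotypes = 8, n_causal = 20, seed = 3)
  specs <- d$phenotype_specs
  for (i in seq_along(specs)) {
    expect_true(all(specs[[i]]$causal_ids %in% d$feature_ids))
    for (j in seq_along(specs)) {
      expect_identical(
        length(intersect(specs[[i]]$causal_ids, specs[[j]]$causal_ids)),
        as.integer(d$overlap_matrix[i, j]))
    }
  }
  # block design: consecutive pairs share 75% / 25% / 0% of 20 causal features
  expect_equal(d$overlap_matrix[1, 2], 15)
  expect_equal(d$overlap_matrix[3, 4], 5)
  expect_equal(d$overlap_matrix[5, 6], 0)
  expect_equal(d$overlap_matrix[1, 3], 0)
})

test_that("zero-noise phenotypes are exact linear functions of causal columns", {
  specs <- list(
    list(name = "copy", causal_ids = "SNP_000003", effects = 1, noise_sd = 0),
    list(name = "twin_a", causal_ids = c("GENE_000001", "IGR_000002"),
         effects = c(2, -1), noise_sd = 0),
    list(name = "twin_b", causal_ids = c("GENE_000001", "IGR_000002"),
         effects = c(2, -1), noise_sd = 0)
  )
  d <- sim_design(n_samples = 50, n_features = c(snp = 5, gene = 3, igr = 2),
                  phenotype_specs = specs, seed = 9)
  G <- simulate_genotypes(d)
  P <- simulate_phenotypes(G, d)
  expect_equal(P$copy, unname(G[, "SNP_000003"]))
  expect_equal(P$twin_a, P$twin_b)
  expect_equal(suppressWarnings(cor(P$twin_a, P$twin_b, method = "spearman")), 1)
  expect_equal(P$twin_a,
               unname(drop(G[, c("GENE_000001", "IGR_000002")] %*% c(2, -1))))
})

test_that("phenotype simulation rejects causal ids absent from the matrix", {
  d <- sim_design(n_samples = 10, n_features = c(snp = 5, gene = 3, igr = 2),
                  n_phenotypes = 1, n_causal = 2, seed = 1)
  G <- simulate_genotypes(d)
  drop_id <- d$phenotype_specs[[1]]$causal_ids[1]
  expect_error(simulate_phenotypes(G[, setdiff(colnames(G), drop_id)], d),
               "absent")
})

test_that("full causal overlap drives phenotype correlation above zero overlap", {
  # Monte-Carlo oracle on the generator itself: over 20 seeds, the pair with
  # an identical causal set is more rank-correlated (in absolute value) than
  # the pair with disjoint causal sets.
  wins <- vapply(1:20, function(s) {
    ids <- sprintf("SNP_%06d", 1:40)
    set.seed(s)
    w_shared <- runif(5, 0.5, 1.5) * sample(c(-1, 1), 5, TRUE)
    specs <- list(
      list(name = "a1", causal_ids = ids[1:5], effects = w_shared),
      list(name = "a2", causal_ids = ids[1:5], effects = w_shared),
      list(name = "b1", causal_ids = ids[11:15],
           effects = runif(5, 0.5, 1.5) * sample(c(-1, 1), 5, TRUE)),
      list(name = "b2", causal_ids = ids[21:25],
           effects = runif(5, 0.5, 1.5) * sample(c(-1, 1), 5, TRUE))
    )
    d <- sim_design(n_samples = 100,
                    n_features = c(snp = 40, gene = 1, igr = 1),
                    phenotype_specs = specs, signal_fraction = 0.8, seed = s)
    G <- simulate_genotypes(d)
    P <- simulate_phenotypes(G, d)
    full <- abs(cor(P$a1, P$a2, method = "spearman"))
    none <- abs(cor(P$b1, P$b2, method = "spearman"))
    full > none
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("planted signal fraction 0.9 supports OLS R2 >= 0.85 on causal columns", {
  r2s <- vapply(1:5, function(s) {
    pan <- small_panel(n = 194, p = c(snp = 150, gene = 100, igr = 50),
                       n_phen = 1, n_causal = 20, seed = s,
                       signal_fraction = 0.9)
    causal <- pan$design$phenotype_specs[[1]]$causal_ids
    fit <- lm(pan$P[[2]] ~ pan$G[, causal])
    summary(fit)$r.squared
  }, numeric(1))
  expect_gte(median(r2s), 0.85)
})
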