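sphere_config <- function(seed, dim = 5, pop = 30, iters = 100) {
  dbo_config(bounds = cbind(rep(-5, dim), rep(5, dim)), pop_size = pop,
             max_iter = iters, seed = seed)
}

test_that("config validation enforces the role split and bounds", {
  cfg <- dbo_config(cbind(0, 1), pop_size = 50)
  expect_equal(unname(cfg$role_counts), c(10L, 20L, 10L, 10L))
  expect_error(dbo_config(cbind(1, 0)), "low < high")
  expect_error(dbo_config(cbind(0, 1), role_fractions = c(0.5, 0.2, 0.2, 0.2)),
               "sum to 1")
  expect_error(dbo_config(cbind(0, 1), max_iter = 0), "max_iter")
  expect_error(dbo_config(cbind(0, Inf)), "finite")
})

test_that("sphere optimum is found and traces are monotone", {
  res <- vapply(1:10, function(s) {
    r <- dbo_optimize(function(x) -sum(x^2), sphere_config(s))
    expect_false(is.unsorted(r$trace$best_fitness))
    expect_true(all(r$best_position >= -5 & r$best_position <= 5))
    expect_equal(nrow(r$trace), 100)
    r$best_fitness
  }, numeric(1))
  expect_gte(median(res), -1e-3)
})

test_that("final sphere fitness improves >= 3 orders of magnitude over initial", {
  ratios <- vapply(1:10, function(s) {
    r <- dbo_optimize(function(x) -sum(x^2), sphere_config(s))
    abs(r$trace$best_fitness[1] / min(r$best_fitness, -1e-300))
  }, numeric(1))
  expect_gte(median(ratios), 1e3)
})

test_that("a single iteration yields a one-row trace with the running best", {
  cfg <- sphere_config(1, iters = 1)
  r <- dbo_optimize(function(x) -sum(x^2), cfg)
  expect_equal(nrow(r$trace), 1)
  expect_equal(r$trace$best_fitness[1], r$best_fitness)
  expect_equal(r$evaluations, 2L * cfg$pop_size)
})

test_that("rastrigin in 2-d gets near the grid-verified optimum", {
  # dense-grid oracle: the global minimum of the rastrigin surface
  gr <- seq(-5.12, 5.12, length.out = 201)
  grid_min <- min(outer(gr, gr, Vectorize(function(a, b) rastrigin(c(a, b)))))
  expect_lt(grid_min, 1e-10)
  res <- vapply(1:20, function(s) {
    cfg <- dbo_config(bounds = cbind(rep(-5.12, 2), rep(5.12, 2)),
                      pop_size = 50, max_iter = 100, seed = s)
    dbo_optimize(function(x) -rastrigin(x), cfg)$best_fitness
  }, numeric(1))
  expect_gte(median(res), -1.0)
})

test_that("objective failures score -Inf and the search continues", {
  flaky <- function(x) {
    if (x[1] > 0) stop("boom")
    if (x[2] > 0) return(NaN)
    -sum(x^2)
  }
  r <- dbo_optimize(flaky, sphere_config(4, dim = 2, pop = 20, iters = 30))
  expect_true(is.finite(r$best_fitness))
  expect_true(all(r$best_position <= 0))
})

test_that("population updates stay in bounds and are seed-deterministic", {
  cfg <- dbo_config(bounds = cbind(c(-2, 0, 10), c(3, 1, 20)),
                    pop_size = 20, max_iter = 50, seed = 11)
  set.seed(99)
  for (rep in 1:40) {
    P <- matrix(runif(20 * 3, rep(cfg$bounds[, 1], each = 20),
                      rep(cfg$bounds[, 2], each = 20)), 20, 3)
    fit <- runif(20)
    it <- sample(1:50, 1)
    out1 <- dbo_update_population(P, P, fit, P[which.max(fit), ], it, cfg)
    out2 <- dbo_update_population(P, P, fit, P[which.max(fit), ], it, cfg)
    expect_identical(out1, out2)
    expect_true(all(out1 >= matrix(cfg$bounds[, 1], 20, 3, byrow = TRUE) -
                      1e-12))
    expect_true(all(out1 <= matrix(cfg$bounds[, 2], 20, 3, byrow = TRUE) +
                      1e-12))
  }
})

test_that("degenerate spawning region keeps brood balls at the optimum", {
  # all beetles at the same point, final iteration (R = 0): offspring of the
  # reproducing block must stay exactly there
  cfg <- dbo_config(bounds = cbind(rep(-5, 3), rep(5, 3)), pop_size = 10,
                    max_iter = 50, seed = 2)
  P <- matrix(2, 10, 3)
  out <- dbo_update_population(P, P, rep(1, 10), P[1, ], 50, cfg)
  repro_rows <- (10 - cfg$role_counts[["reproduce"]] + 1):10
  expect_equal(out[repro_rows, ], P[repro_rows, ])
})

test_that("identical config and objective reproduce the whole trace", {
  r1 <- dbo_optimize(function(x) -sum((x - 1)^2), sphere_config(21))
  r2 <- dbo_optimize(function(x) -sum((x - 1)^2), sphere_config(21))
  expect_identical(r1$trace$best_fitness, r2$trace$best_fitness)
  expect_identical(r1$best_position, r2$best_position)
})

test_that("positions decode to typed values by the stated rules", {
  space <- pipeline_param_space(n_samples = 120)
  cfg <- dbo_config(space$bounds, pop_size = 10, max_iter = 5,
                    dim_kinds = space$dim_kinds,
                    categories = space$categories, seed = 1)
  # integer rounding is half-up, categorical mapping is floor + clamp
  v <- decode_position(c(5e-5, 2.4, 9.7, 150.5, 3.999, 10), cfg)
  expect_identical(v$percentile, 2L)
  expect_identical(v$rfecv_step, 10L)
  expect_identical(v$min_features, 151L)
  expect_identical(v$scoring[[1]], "mae")
  v2 <- decode_position(c(0, 1, 1, 100, 0, 1), cfg)
  expect_identical(v2$scoring[[1]], "r2")
  # random positions always decode inside the published ranges
  set.seed(8)
  for (i in 1:200) {
    pos <- runif(6, space$bounds[, 1], space$bounds[, 2])
    p <- decode_pipeline_params(pos, cfg)
    expect_true(p$variance_threshold >= 0 && p$variance_threshold <= 1e-4)
    expect_true(p$percentile >= 1 && p$percentile <= 100)
    expect_true(p$rfecv_step >= 1 && p$rfecv_step <= 10)
    expect_true(p$min_features >= 100 && p$min_features <= 300)
    expect_true(p$scoring %in% c("r2", "mse", "rmse", "mae"))
    expect_true(p$n_components >= 1 && p$n_components <= 119)
  }
})
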