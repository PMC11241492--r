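# Dung Beetle Optimizer (DBO).
#
# Population-based metaheuristic whose agents follow four behavior rules:
# ball-rolling (exploration, with occasional "dancing" reorientation),
# brood-ball reproduction inside a region that shrinks around the local best,
# foraging around the global best's region, and stealing (contraction toward
# the global best).  The population stays continuous; mixed integer /
# categorical search dimensions are handled by decoding at evaluation time.

#' DBO configuration
#'
#' @param bounds Numeric matrix (or 2-column data frame) with one row per
#'   search dimension and columns `low`, `high` (`low < high`, finite).
#' @param pop_size Population size (default 50 beetles).
#' @param role_fractions Fractions of the population assigned to the rolling,
#'   foraging, stealing and reproducing roles; must sum to 1.  The default
#'   20/40/20/20 split of 50 beetles gives 10/20/10/10.  Role membership is a
#'   static index block partition.
#' @param max_iter Number of update iterations (default 100).
#' @param dim_kinds Character vector per dimension: `"continuous"`,
#'   `"integer"` or `"categorical"`; defaults to all continuous.
#' @param categories For categorical dimensions, a list of category vectors
#'   (indexed by dimension); `NULL` entries elsewhere.
#' @param seed Integer seed; the whole optimization is deterministic given it.
#' @param k Defection (rolling) coefficient.
#' @param b Light-intensity (rolling) coefficient.
#' @param S Thief step scale.
#' @param obstacle_prob Probability that a rolling beetle meets an obstacle
#'   and reorients by dancing.
#'
#' @return An object of class `dbo_config`.
#' @export
dbo_config <- function(bounds,
                       pop_size = 50,
                       role_fractions = c(roll = 0.20, forage = 0.40,
                                          steal = 0.20, reproduce = 0.20),
                       max_iter = 100,
                       dim_kinds = NULL,
                       categories = NULL,
                       seed = 1,
                       k = 0.1, b = 0.3, S = 0.5,
                       obstacle_prob = 0.1) {
  bounds <- as.matrix(bounds)
  if (ncol(bounds) != 2) abort("bounds must have two columns (low, high)")
  colnames(bounds) <- c("low", "high")
  if (any(!is.finite(bounds))) abort("bounds must be finite")
  if (any(bounds[, 1] >= bounds[, 2])) abort("every dimension needs low < high")
  if (abs(sum(role_fractions) - 1) > 1e-8) abort("role_fractions must sum to 1")
  if (max_iter < 1) abort("max_iter must be >= 1")
  counts <- round(role_fractions * pop_size)
  counts[length(counts)] <- pop_size - sum(counts[-length(counts)])
  if (any(counts < 0) || sum(counts) != pop_size) {
    abort("role fractions do not partition the population")
  }
  if (is.null(dim_kinds)) dim_kinds <- rep("continuous", nrow(bounds))
  dim_kinds <- match.arg(dim_kinds, c("continuous", "integer", "categorical"),
                         several.ok = TRUE)
  structure(
    list(bounds = bounds, pop_size = as.integer(pop_size),
         role_counts = setNames(as.integer(counts),
                                c("roll", "forage", "steal", "reproduce")),
         max_iter = as.integer(max_iter),
         dim_kinds = dim_kinds, categories = categories,
         seed = as.integer(seed),
         k = k, b = b, S = S, obstacle_prob = obstacle_prob),
    class = "dbo_config"
  )
}

clamp_bounds <- function(P, bounds) {
  P <- pmax(P, matrix(bounds[, 1], nrow(P), ncol(P), byrow = TRUE))
  pmin(P, matrix(bounds[, 2], nrow(P), ncol(P), byrow = TRUE))
}

#' One DBO population update
#'
#' Applies the four behavior rules to the static role blocks (in order:
#' rolling, foraging, stealing, reproducing) and clamps every coordinate into
#' the bounds.  Exposed mainly for testing and instrumentation;
#' [dbo_optimize()] drives it.
#'
#' @param positions Current positions (pop_size x dim).
#' @param prev_positions Positions of the previous iteration (rolling uses
#'   them); the initial population may pass `positions` again.
#' @param fitnesses Current fitness per row (maximization).
#' @param global_best Incumbent best position (numeric vector).
#' @param iter_index Current iteration t (1-based).
#' @param config A [dbo_config()]; randomness is seeded from `config$seed`
#'   and `iter_index`, so identical inputs give identical outputs.
#' @return New positions matrix, all rows within bounds.
#' @export
dbo_update_population <- function(positions, prev_positions, fitnesses,
                                  global_best, iter_index, config) {
  withr::with_seed(
    derive_seed(config$seed, 7777L + iter_index),
    dbo_update_population_impl(positions, prev_positions, fitnesses,
                               global_best, iter_index, config)
  )
}

dbo_update_population_impl <- function(positions, prev_positions, fitnesses,
                                       global_best, iter_index, config) {
  P <- positions
  n <- nrow(P); d <- ncol(P)
  lo <- config$bounds[, 1]; hi <- config$bounds[, 2]
  nc <- config$role_counts
  idx_roll <- seq_len(nc[["roll"]])
  idx_forage <- seq_len(nc[["forage"]]) + nc[["roll"]]
  idx_steal <- seq_len(nc[["steal"]]) + nc[["roll"]] + nc[["forage"]]
  idx_repro <- seq_len(nc[["reproduce"]]) + nc[["roll"]] + nc[["forage"]] + nc[["steal"]]

  worst <- P[which.min(fitnesses), ]
  local_best <- P[which.max(fitnesses), ]   # best of the current iteration
  Xb <- global_best                         # incumbent
  R <- 1 - iter_index / config$max_iter
  newP <- P

  # Rolling: x <- x + alpha*k*x_prev + b*|x - worst|; with probability
  # obstacle_prob the beetle dances instead: x <- x + tan(theta)*|x - x_prev|.
  for (i in idx_roll) {
    if (runif(1) < config$obstacle_prob) {
      theta <- runif(1, 0, pi)
      while (abs(theta - pi / 2) < 1e-8) theta <- runif(1, 0, pi)
      newP[i, ] <- P[i, ] + tan(theta) * abs(P[i, ] - prev_positions[i, ])
    } else {
      alpha <- sample(c(1, -1), 1)
      newP[i, ] <- P[i, ] + alpha * config$k * prev_positions[i, ] +
        config$b * abs(P[i, ] - worst)
    }
  }

  # Foraging: move around the global best's shrinking region.
  lb_b <- pmin(pmax(Xb * (1 - R), lo), hi)
  ub_b <- pmax(pmin(Xb * (1 + R), hi), lo)
  for (i in idx_forage) {
    C1 <- rnorm(1)
    C2 <- runif(d)
    newP[i, ] <- P[i, ] + C1 * (P[i, ] - lb_b) + C2 * (P[i, ] - ub_b)
  }

  # Stealing: contract toward the global best.
  for (i in idx_steal) {
    g <- rnorm(d)
    newP[i, ] <- Xb + config$S * g *
      (abs(P[i, ] - local_best) + abs(P[i, ] - Xb))
  }

  # Reproduction: brood balls stay inside the region shrinking around the
  # local best.
  lb_s <- pmin(pmax(local_best * (1 - R), lo), hi)
  ub_s <- pmax(pmin(local_best * (1 + R), hi), lo)
  for (i in idx_repro) {
    b1 <- runif(d); b2 <- runif(d)
    cand <- local_best + b1 * (P[i, ] - lb_s) + b2 * (P[i, ] - ub_s)
    newP[i, ] <- pmin(pmax(cand, lb_s), ub_s)
  }

  clamp_bounds(newP, config$bounds)
}

#' Run the Dung Beetle Optimizer
#'
#' Maximizes `objective` over the bounded search space.  Evaluations that
#' raise an error or return a non-finite value are scored `-Inf` and the
#' search continues; the incumbent best is never replaced by a worse
#' position, so the best-so-far trace is monotone non-decreasing.
#'
#' @param objective Function taking a numeric position vector (in bounds) and
#'   returning a scalar fitness to maximize.
#' @param config A [dbo_config()].
#' @return A list of class `dbo_result`: `best_position`, `best_fitness`,
#'   `trace` (tibble with `iter`, `best_fitness` and a `best_position`
#'   list-column; `max_iter` rows), and `evaluations`.
#' @export
dbo_optimize <- function(objective, config) {
  stopifnot(inherits(config, "dbo_config"))
  d <- nrow(config$bounds)
  evals <- 0L
  score <- function(x) {
    evals <<- evals + 1L
    val <- tryCatch(objective(x), error = function(e) -Inf)
    if (!is.numeric(val) || length(val) != 1 || !is.finite(val)) -Inf else val
  }

  P <- withr::with_seed(derive_seed(config$seed, 11L), {
    matrix(runif(config$pop_size * d,
                 rep(config$bounds[, 1], each = config$pop_size),
                 rep(config$bounds[, 2], each = config$pop_size)),
           nrow = config$pop_size, ncol = d)
  })
  fit <- apply(P, 1, score)
  best_i <- which.max(fit)
  best_pos <- P[best_i, ]
  best_fit <- fit[best_i]
  prevP <- P

  trace_fit <- numeric(config$max_iter)
  trace_pos <- vector("list", config$max_iter)
  for (t in seq_len(config$max_iter)) {
    newP <- dbo_update_population(P, prevP, fit, best_pos, t, config)
    newfit <- apply(newP, 1, score)
    prevP <- P
    P <- newP
    fit <- newfit
    it_best <- which.max(fit)
    if (fit[it_best] > best_fit) {
      best_fit <- fit[it_best]
      best_pos <- P[it_best, ]
    }
    trace_fit[t] <- best_fit
    trace_pos[[t]] <- best_pos
  }

  structure(
    list(best_position = best_pos,
         best_fitness = best_fit,
         trace = tibble::tibble(iter = seq_len(config$max_iter),
                                best_fitness = trace_fit,
                                best_position = trace_pos),
         evaluations = evals,
         config = config),
    class = "dbo_result"
  )
}

#' @export
print.dbo_result <- function(x, ...) {
  cat(sprintf("<dbo_result> best fitness %.6g after %d evaluations (%d iters)\n",
              x$best_fitness, x$evaluations, nrow(x$trace)))
  invisible(x)
}

#' @rdname dbo_optimize
#' @param x A `dbo_result`.
#' @param ... Unused.
#' @export
tidy.dbo_result <- function(x, ...) {
  dplyr::select(x$trace, iter, best_fitness)
}

#' @rdname dbo_optimize
#' @export
glance.dbo_result <- function(x, ...) {
  tibble::tibble(best_fitness = x$best_fitness,
                 evaluations = x$evaluations,
                 iterations = nrow(x$trace))
}

#' @rdname dbo_optimize
#' @param object A `dbo_result`.
#' @export
autoplot.dbo_result <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(x = iter, y = best_fitness)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::labs(x = "Iteration", y = "Best fitness",
                  title = "DBO best-so-far trace") +
    ggplot2::theme_minimal()
}

#' Decode a continuous DBO position into typed parameters
#'
#' Continuous dimensions pass through; integer dimensions are rounded
#' half-up (`floor(x + 0.5)`) and clamped into their bounds; categorical
#' dimensions map by `floor` to an index into the category list, with the
#' upper bound landing on the last category.
#'
#' @param position Numeric vector within `config$bounds`.
#' @param config A [dbo_config()] carrying `dim_kinds` (and `categories` for
#'   categorical dimensions).
#' @return A list with one decoded value per dimension (named after the
#'   bounds rownames when present).
#' @export
decode_position <- function(position, config) {
  d <- nrow(config$bounds)
  stopifnot(length(position) == d)
  out <- vector("list", d)
  for (j in seq_len(d)) {
    lo <- config$bounds[j, 1]; hi <- config$bounds[j, 2]
    x <- min(max(position[j], lo), hi)
    out[[j]] <- switch(
      config$dim_kinds[j],
      continuous = x,
      integer = as.integer(min(max(floor(x + 0.5), ceiling(lo)), floor(hi))),
      categorical = {
        cats <- config$categories[[j]]
        idx <- min(floor(x) + 1L, length(cats))
        cats[[max(idx, 1L)]]
      }
    )
  }
  names(out) <- rownames(config$bounds)
  out
}
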