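# Synthetic genotype/phenotype generator.
#
# Emulates the statistical structure of a pan-genome association panel: a
# strains x features binary matrix in three feature classes (SNP, gene
# presence/absence, intergenic region), and real-valued sensory phenotypes
# driven by sparse planted causal features.  Pairs of phenotypes can share a
# controlled number of causal features, which is what makes phenotype
# correlation track causal overlap downstream.

#' Simulation design for synthetic pan-genome panels
#'
#' Describes a synthetic study: panel size, binary feature counts per class,
#' the Bernoulli frequency range of features, and a set of phenotypes each
#' driven by a sparse planted causal feature set.  Causal sets for phenotype
#' pairs can overlap by a planted number of features; a feature shared by two
#' phenotypes carries the same effect weight in both (consistent pleiotropy),
#' so causal overlap induces phenotype correlation.
#'
#' Noise is parameterized by the target signal fraction
#' `Var(signal) / Var(phenotype)`; the per-phenotype noise standard deviation
#' is derived from the realized genetic variance at simulation time.  Passing
#' `noise_sd` instead fixes the noise scale directly.
#'
#' @param n_samples Number of strains in the panel.
#' @param n_features Named integer vector `c(snp=, gene=, igr=)` of binary
#'   feature counts per class.
#' @param presence_prob_range Length-2 numeric strictly inside (0,1); each
#'   feature's Bernoulli frequency is drawn uniformly from this range.
#' @param n_phenotypes Number of phenotypes when `phenotype_specs` is not
#'   supplied.  Defaults to the 8 electronic-tongue channels.
#' @param n_causal Causal features per phenotype.
#' @param overlap_fractions Fractions of `n_causal` shared within consecutive
#'   phenotype pairs (recycled across pairs), giving a gradient of planted
#'   causal overlap; features are never shared across different pairs.
#' @param signal_fraction Target `Var(signal)/Var(y)` in (0,1].
#' @param noise_sd Optional fixed noise standard deviation (scalar or one per
#'   phenotype); overrides `signal_fraction` when non-`NULL`.
#' @param effect_size_range Magnitude range for causal effect weights; each
#'   weight gets a random sign.
#' @param phenotype_names Optional phenotype names; defaults to the
#'   electronic-tongue channel names for 8 phenotypes.
#' @param phenotype_specs Optional list of explicit specs, each a list with
#'   `name`, `causal_ids` (feature id character vector), `effects` (numeric,
#'   same length) and optionally `noise_sd` / `signal_fraction`.  When given,
#'   overrides the block-overlap construction.
#' @param seed Integer seed; the design (causal sets, weights) and the two
#'   simulation operations are all deterministic given the design.
#'
#' @return An object of class `sim_design`: a list with feature ids and
#'   classes, phenotype specs, the realized pairwise `overlap_matrix`, and all
#'   generation parameters.
#' @export
sim_design <- function(n_samples = 194,
                       n_features = c(snp = 2500, gene = 1500, igr = 1000),
                       presence_prob_range = c(0.1, 0.9),
                       n_phenotypes = 8,
                       n_causal = 20,
                       overlap_fractions = c(0.75, 0.25, 0),
                       signal_fraction = 0.9,
                       noise_sd = NULL,
                       effect_size_range = c(0.5, 1.5),
                       phenotype_names = NULL,
                       phenotype_specs = NULL,
                       seed = 1) {
  if (n_samples < 1) abort("n_samples must be positive")
  n_features <- vapply(n_features, as.integer, integer(1))
  if (length(n_features) != 3 || any(n_features < 1)) {
    abort("n_features must hold positive counts for the snp, gene and igr classes")
  }
  if (is.null(names(n_features))) names(n_features) <- c("snp", "gene", "igr")
  if (length(presence_prob_range) != 2 ||
      any(presence_prob_range <= 0) || any(presence_prob_range >= 1)) {
    abort("presence_prob_range must lie strictly inside (0, 1)")
  }
  if (!is.null(noise_sd) && any(noise_sd < 0)) abort("noise_sd must be >= 0")
  if (signal_fraction <= 0 || signal_fraction > 1) {
    abort("signal_fraction must be in (0, 1]")
  }

  feature_ids <- c(
    sprintf("SNP_%06d", seq_len(n_features[["snp"]])),
    sprintf("GENE_%06d", seq_len(n_features[["gene"]])),
    sprintf("IGR_%06d", seq_len(n_features[["igr"]]))
  )
  feature_class <- rep(c("SNP", "GENE", "IGR"), times = n_features)

  if (is.null(phenotype_specs)) {
    if (is.null(phenotype_names)) {
      phenotype_names <- if (n_phenotypes == 8) tongue_channels() else
        sprintf("phenotype_%02d", seq_len(n_phenotypes))
    }
    stopifnot(length(phenotype_names) == n_phenotypes)
    phenotype_specs <- withr::with_seed(
      derive_seed(seed, 101L),
      build_block_specs(phenotype_names, feature_ids, n_causal,
                        overlap_fractions, effect_size_range,
                        signal_fraction, noise_sd)
    )
  } else {
    phenotype_specs <- lapply(phenotype_specs, function(sp) {
      missing <- setdiff(sp$causal_ids, feature_ids)
      if (length(missing) > 0) {
        abort(sprintf("causal ids not in the feature space: %s",
                      paste(head(missing, 3), collapse = ", ")))
      }
      if (length(sp$effects) != length(sp$causal_ids)) {
        abort(sprintf("phenotype '%s': effects and causal_ids lengths differ", sp$name))
      }
      if (is.null(sp$signal_fraction)) sp$signal_fraction <- signal_fraction
      sp
    })
  }

  ov <- overlap_matrix_of(phenotype_specs)
  structure(
    list(n_samples = as.integer(n_samples),
         n_features = n_features,
         feature_ids = feature_ids,
         feature_class = feature_class,
         presence_prob_range = presence_prob_range,
         phenotype_specs = phenotype_specs,
         overlap_matrix = ov,
         signal_fraction = signal_fraction,
         seed = as.integer(seed)),
    class = "sim_design"
  )
}

#' Electronic-tongue channel names
#' @return Character vector of the 8 taste channels.
#' @export
tongue_channels <- function() {
  c("Sourness", "Bitterness", "Astringency", "Aftertaste-B",
    "Aftertaste-A", "Umami", "Richness", "Saltiness")
}

#' Electronic-nose sensor names
#' @return Character vector of the 10 metal-oxide sensor names.
#' @export
nose_sensors <- function() {
  c("W1C", "W5S", "W3C", "W6S", "W5C", "W1S", "W1W", "W2S", "W2W", "W3S")
}

# Block-overlap causal design: consecutive phenotype pairs share
# round(frac * n_causal) features, with fractions recycled across pairs.
# A shared feature carries one weight, used by both phenotypes.
build_block_specs <- function(names, feature_ids, n_causal, overlap_fractions,
                              effect_size_range, signal_fraction, noise_sd) {
  n_phen <- length(names)
  pool <- sample(feature_ids)   # randomized free pool
  take <- function(m) {
    if (m == 0) return(character(0))
    if (m > length(pool)) abort("not enough free features for the causal sets")
    ids <- pool[seq_len(m)]
    pool <<- pool[-seq_len(m)]
    ids
  }
  sets <- vector("list", n_phen)
  pair_idx <- 0L
  k <- 1L
  while (k <= n_phen) {
    if (k + 1L <= n_phen) {
      pair_idx <- pair_idx + 1L
      frac <- overlap_fractions[(pair_idx - 1L) %% length(overlap_fractions) + 1L]
      n_shared <- round(frac * n_causal)
      shared <- take(n_shared)
      sets[[k]] <- c(shared, take(n_causal - n_shared))
      sets[[k + 1L]] <- c(shared, take(n_causal - n_shared))
      k <- k + 2L
    } else {
      sets[[k]] <- take(n_causal)
      k <- k + 1L
    }
  }
  all_ids <- unique(unlist(sets))
  w <- runif(length(all_ids), effect_size_range[1], effect_size_range[2]) *
    sample(c(-1, 1), length(all_ids), replace = TRUE)
  names(w) <- all_ids
  purrr::map2(names, sets, function(nm, ids) {
    list(name = nm, causal_ids = ids, effects = unname(w[ids]),
         noise_sd = if (is.null(noise_sd)) NULL else
           noise_sd[min(length(noise_sd), match(nm, names))],
         signal_fraction = signal_fraction)
  })
}

overlap_matrix_of <- function(specs) {
  n <- length(specs)
  ov <- matrix(0L, n, n,
               dimnames = list(vapply(specs, `[[`, "", "name"),
                               vapply(specs, `[[`, "", "name")))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ov[i, j] <- length(intersect(specs[[i]]$causal_ids, specs[[j]]$causal_ids))
    }
  }
  ov
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf("<sim_design> %d samples x %d features (SNP %d / GENE %d / IGR %d)\n",
              x$n_samples, length(x$feature_ids),
              x$n_features[["snp"]], x$n_features[["gene"]], x$n_features[["igr"]]))
  cat(sprintf("  %d phenotypes, signal fraction %.2f, seed %d\n",
              length(x$phenotype_specs), x$signal_fraction, x$seed))
  invisible(x)
}

#' Simulate a binary genotype matrix
#'
#' Draws every feature independently: feature `j` gets a Bernoulli frequency
#' `p_j` uniform in the design's `presence_prob_range`, and each strain's
#' allele is an independent Bernoulli(`p_j`) draw.  No linkage structure is
#' generated.
#'
#' @param design A [sim_design()].
#' @return An integer matrix of class `genotype_matrix` (samples x features,
#'   values 0/1) with strain rownames, feature-id colnames, and a
#'   `feature_class` attribute (`"SNP"`, `"GENE"` or `"IGR"` per column).
#'   Identical designs give bitwise-identical matrices.
#' @export
simulate_genotypes <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  n <- design$n_samples
  p <- length(design$feature_ids)
  G <- withr::with_seed(derive_seed(design$seed, 202L), {
    pj <- runif(p, design$presence_prob_range[1], design$presence_prob_range[2])
    matrix(rbinom(n * p, 1L, rep(pj, each = n)), nrow = n, ncol = p)
  })
  dimnames(G) <- list(sprintf("strain_%04d", seq_len(n)), design$feature_ids)
  new_genotype_matrix(G, design$feature_class)
}

new_genotype_matrix <- function(mat, feature_class = NULL) {
  if (is.null(feature_class)) {
    feature_class <- class_from_prefix(colnames(mat))
  }
  structure(mat, feature_class = feature_class,
            class = c("genotype_matrix", class(mat)))
}

class_from_prefix <- function(ids) {
  cls <- rep("GENE", length(ids))
  cls[startsWith(ids, "SNP")] <- "SNP"
  cls[startsWith(ids, "IGR")] <- "IGR"
  cls
}

#' Feature class labels of a genotype matrix
#' @param G A `genotype_matrix` (or any matrix with prefixed feature ids).
#' @return Character vector, one of `"SNP"`, `"GENE"`, `"IGR"` per column.
#' @export
feature_classes <- function(G) {
  attr(G, "feature_class") %||% class_from_prefix(colnames(G))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.genotype_matrix <- function(x, ...) {
  cls <- table(feature_classes(x))
  cat(sprintf("<genotype_matrix> %d strains x %d features (%s)\n",
              nrow(x), ncol(x),
              paste(sprintf("%s %d", names(cls), cls), collapse = ", ")))
  invisible(x)
}

#' Simulate phenotypes from a genotype matrix
#'
#' Each phenotype is the additive signal of its planted causal features plus
#' Gaussian noise: `y_k = sum_j w_kj g_j + eps`, `eps ~ N(0, sd_k^2)`.  When a
#' phenotype spec carries `signal_fraction` rather than a fixed `noise_sd`,
#' the noise scale is calibrated against the realized signal variance so that
#' `Var(signal)/Var(y)` hits the target.
#'
#' @param G Genotype matrix from [simulate_genotypes()] (or any 0/1 matrix
#'   with matching feature ids).
#' @param design The [sim_design()] the matrix conforms to.
#' @return A tibble with `sample_id` and one numeric column per phenotype.
#' @export
simulate_phenotypes <- function(G, design) {
  stopifnot(inherits(design, "sim_design"))
  missing <- setdiff(unlist(lapply(design$phenotype_specs, `[[`, "causal_ids")),
                     colnames(G))
  if (length(missing) > 0) {
    abort(sprintf("causal ids absent from genotype matrix: %s",
                  paste(head(missing, 3), collapse = ", ")))
  }
  n <- nrow(G)
  ys <- withr::with_seed(derive_seed(design$seed, 303L), {
    lapply(design$phenotype_specs, function(sp) {
      signal <- unname(drop(G[, sp$causal_ids, drop = FALSE] %*% sp$effects))
      sd_k <- sp$noise_sd
      if (is.null(sd_k)) {
        f <- sp$signal_fraction %||% design$signal_fraction
        v_sig <- mean(signal^2) - mean(signal)^2
        sd_k <- if (f >= 1) 0 else sqrt(v_sig * (1 - f) / f)
      }
      signal + rnorm(n, 0, sd_k)
    })
  })
  names(ys) <- vapply(design$phenotype_specs, `[[`, "", "name")
  out <- tibble::as_tibble(ys, .name_repair = "minimal")
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(G) %||%
                                    sprintf("strain_%04d", seq_len(n))), out)
}
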