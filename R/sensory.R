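# Descriptive sensory analytics: phenotype distribution summaries, Spearman
# correlation matrices, shared selected-feature counts across phenotype
# pairs, and the association between phenotype correlation and causal-feature
# sharing.

phenotype_columns <- function(P) {
  P <- as.data.frame(P)
  if ("sample_id" %in% names(P)) P$sample_id <- NULL
  not_num <- names(P)[!vapply(P, is.numeric, logical(1))]
  if (length(not_num) > 0) {
    abort(sprintf("non-numeric phenotype columns: %s",
                  paste(not_num, collapse = ", ")))
  }
  P
}

#' Spearman correlation matrix of phenotypes
#'
#' Rank correlation on mid-ranks (ties get average ranks), computed across
#' all phenotype column pairs.
#'
#' @param P Phenotype table (tibble or data frame; a `sample_id` column is
#'   ignored).  Needs at least 3 samples and no constant column.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(P) {
  P <- phenotype_columns(P)
  if (nrow(P) < 3) abort("need at least 3 samples")
  const <- names(P)[vapply(P, function(x) var(x) == 0, logical(1))]
  if (length(const) > 0) {
    abort(sprintf("constant phenotype column(s): %s",
                  paste(const, collapse = ", ")))
  }
  cor(as.matrix(P), method = "spearman")
}

#' Box-plot statistics per phenotype
#'
#' Quartiles (type-7), whiskers at the most extreme data points within
#' 1.5 x IQR of the quartiles, and outliers beyond the whiskers.
#'
#' @param P Phenotype table with at least 5 samples.
#' @return Tibble with one row per phenotype: `phenotype`, `q1`, `median`,
#'   `q3`, `whisker_lo`, `whisker_hi`, `n_outliers`, and `outliers` (a
#'   list-column of sample ids, or indices when no `sample_id` is present).
#' @export
boxplot_stats <- function(P) {
  ids <- if ("sample_id" %in% names(as.data.frame(P))) {
    as.data.frame(P)$sample_id
  } else NULL
  P <- phenotype_columns(P)
  if (nrow(P) < 5) abort("need at least 5 samples")
  if (is.null(ids)) ids <- seq_len(nrow(P))
  purrr::imap(P, function(x, nm) {
    q <- unname(quantile(x, c(0.25, 0.5, 0.75)))
    iqr <- q[3] - q[1]
    lo_lim <- q[1] - 1.5 * iqr
    hi_lim <- q[3] + 1.5 * iqr
    inside <- x >= lo_lim & x <= hi_lim
    tibble::tibble(phenotype = nm, q1 = q[1], median = q[2], q3 = q[3],
                   whisker_lo = min(x[inside]), whisker_hi = max(x[inside]),
                   n_outliers = sum(!inside),
                   outliers = list(ids[!inside]))
  }) %>% purrr::list_rbind()
}

#' Shared selected-feature counts across phenotypes
#'
#' Counts, for every phenotype pair, the original features jointly retained
#' by the selection pipeline (post-RFECV survivors — principal components are
#' not original features).  The diagonal holds each phenotype's own survivor
#' count.
#'
#' @param masks Named list, one entry per phenotype: either a character
#'   vector of surviving feature ids or a named logical mask over a common
#'   feature id space.
#' @return Symmetric integer matrix of class `shared_feature_matrix`.
#' @export
shared_feature_counts <- function(masks) {
  if (is.null(names(masks)) || any(names(masks) == "")) {
    abort("masks must be a named list (one entry per phenotype)")
  }
  sets <- purrr::map(masks, function(m) {
    if (is.logical(m)) {
      if (is.null(names(m))) abort("logical masks must carry feature id names")
      names(m)[m]
    } else {
      as.character(m)
    }
  })
  if (length(sets) >= 2) {
    spaces <- purrr::map(masks, function(m) {
      if (is.logical(m)) sort(names(m)) else NULL
    })
    known <- purrr::compact(spaces)
    if (length(known) >= 2 &&
        !all(vapply(known[-1], identical, logical(1), known[[1]]))) {
      abort("logical masks are defined over different feature id spaces")
    }
  }
  n <- length(sets)
  M <- matrix(0L, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n)) {
    for (j in i:n) {
      M[i, j] <- M[j, i] <- length(intersect(sets[[i]], sets[[j]]))
    }
  }
  structure(M, class = c("shared_feature_matrix", class(M)))
}

#' Association between phenotype correlation and feature sharing
#'
#' Spearman rank correlation between the absolute pairwise phenotype
#' correlation and the shared selected-feature count, over all unordered
#' phenotype pairs.
#'
#' @param corr Phenotype correlation matrix (e.g. [spearman_matrix()]).
#' @param sfm Shared-feature matrix from [shared_feature_counts()] over the
#'   same phenotypes.
#' @return List with `pairs` (tibble: `phenotype_a`, `phenotype_b`,
#'   `abs_correlation`, `shared_features`) and `rho`.  When the shared
#'   counts are constant the association is undefined and `rho` is `NA` with
#'   an explanatory `note`.
#' @export
overlap_correlation_trend <- function(corr, sfm) {
  phen <- rownames(corr)
  if (is.null(phen)) phen <- colnames(corr)
  if (!setequal(phen, rownames(sfm))) {
    abort("correlation and shared-feature matrices cover different phenotypes")
  }
  if (length(phen) < 3) abort("need at least 3 phenotypes (3 pairs)")
  sfm <- sfm[phen, phen]
  pairs <- which(upper.tri(corr), arr.ind = TRUE)
  tbl <- tibble::tibble(
    phenotype_a = phen[pairs[, 1]],
    phenotype_b = phen[pairs[, 2]],
    abs_correlation = abs(corr[pairs]),
    shared_features = as.integer(sfm[pairs])
  )
  if (nrow(tbl) < 3) abort("need at least 3 phenotype pairs")
  if (var(tbl$shared_features) == 0 || var(tbl$abs_correlation) == 0) {
    return(list(pairs = tbl, rho = NA_real_,
                note = "association undefined: one variable is constant across pairs"))
  }
  rho <- cor(tbl$abs_correlation, tbl$shared_features, method = "spearman")
  list(pairs = tbl, rho = rho)
}

#' Correlation / shared-feature heatmap
#'
#' @param mat A square named matrix (correlations or shared-feature counts).
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_matrix_heatmap <- function(mat, title = NULL) {
  df <- as.data.frame(as.table(as.matrix(mat)))
  names(df) <- c("row", "col", "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = signif(.data$value, 2)), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#4575b4", mid = "white",
                                  high = "#d73027") +
    ggplot2::labs(x = NULL, y = NULL, title = title, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Phenotype distribution box plots
#'
#' @param P Phenotype table.
#' @return A ggplot object (one box per phenotype).
#' @export
plot_phenotype_distributions <- function(P) {
  long <- tidyr::pivot_longer(tibble::as_tibble(phenotype_columns(P)),
                              dplyr::everything(),
                              names_to = "phenotype", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$phenotype, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "#a6bddb") +
    ggplot2::labs(x = NULL, y = "Response value") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
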