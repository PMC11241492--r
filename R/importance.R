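# Feature-importance back-projection: ridge coefficients on the principal
# components are pushed back through the PCA loadings onto the selected
# original features, giving each feature a signed total contribution
# c_j = sum_k L_jk * beta_k.  Because scores = centered X_sel %*% L, the
# contribution vector reproduces the component-space prediction exactly:
# scores %*% beta = centered X_sel %*% c.

#' Back-propagate ridge coefficients through PCA loadings
#'
#' @param fp A [fit_pipeline()] result.
#' @return A tibble of class `importance_vector` with one row per RFECV
#'   survivor: `feature_id`, `class` (SNP/GENE/IGR), signed `contribution`,
#'   and `abs_rank` (1 = largest absolute contribution, ties broken by
#'   feature id).  Contributions are on the standardized-feature scale used
#'   by the pipeline fits.
#' @export
propagate_importance <- function(fp) {
  if (!inherits(fp, "fitted_pipeline")) abort("expected a fitted_pipeline")
  L <- fp$loading_matrix
  beta <- fp$ridge_coefficients
  if (ncol(L) != length(beta)) {
    abort(sprintf("loading matrix has %d components but %d coefficients",
                  ncol(L), length(beta)))
  }
  contr <- drop(L %*% beta)
  out <- tibble::tibble(
    feature_id = fp$selected_ids,
    class = class_from_prefix(fp$selected_ids),
    contribution = unname(contr)
  )
  ord <- order(-abs(out$contribution), out$feature_id)
  out$abs_rank <- integer(nrow(out))
  out$abs_rank[ord] <- seq_len(nrow(out))
  class(out) <- c("importance_vector", class(out))
  out
}

#' Top-k features by absolute contribution
#'
#' Orders by absolute contribution (descending), ties broken by feature id;
#' signed values are retained.
#'
#' @param iv An `importance_vector` from [propagate_importance()] (any tibble
#'   with `feature_id` and `contribution` works).
#' @param k Number of features to return (default 10).
#' @return Tibble of `min(k, nrow)` rows: `feature_id`, `class` (if
#'   present), `contribution`, `abs_rank`.
#' @export
rank_top_k <- function(iv, k = 10) {
  if (k < 1) abort("k must be >= 1")
  ord <- order(-abs(iv$contribution), iv$feature_id)
  out <- iv[ord[seq_len(min(k, nrow(iv)))], , drop = FALSE]
  out$abs_rank <- seq_len(nrow(out))
  tibble::as_tibble(out)
}

#' @rdname propagate_importance
#' @param object An `importance_vector`.
#' @param k Number of top features to draw.
#' @param ... Unused.
#' @export
autoplot.importance_vector <- function(object, k = 10, ...) {
  top <- rank_top_k(object, k)
  top$feature_id <- factor(top$feature_id,
                           levels = rev(top$feature_id))
  ggplot2::ggplot(top, ggplot2::aes(x = .data$contribution,
                                    y = .data$feature_id,
                                    fill = .data$contribution > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8",
                                          `FALSE` = "#d95f0e")) +
    ggplot2::labs(x = "Total contribution (standardized scale)",
                  y = NULL, title = sprintf("Top %d features", nrow(top))) +
    ggplot2::theme_minimal()
}
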