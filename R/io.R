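# Readers and writers for the tabular formats the package owns: Roary-style
# Rtab genotype matrices (features as rows, strains as columns), CSV genotype
# matrices (strains as rows), phenotype CSV tables, run configuration files
# (JSON or YAML), and a plain-text serialization of fitted pipelines.

#' Read a binary genotype matrix
#'
#' Rtab: tab-separated, first column the feature id, one column per strain,
#' cells 0/1 (the dialect of pan-genome presence/absence tools).  CSV: first
#' column the sample id, one column per feature.  Non-binary cells greater
#' than zero are coerced to 1 with a warning summarizing the count; negative
#' or non-numeric cells, ragged rows, and duplicate ids are errors.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"rtab"` or `"csv"`.
#' @return A `genotype_matrix` (samples x features) with feature classes
#'   inferred from the id prefixes (SNP_/GENE_/IGR_).
#' @export
read_genotype_matrix <- function(path, format = c("auto", "rtab", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.[Rr]tab$|\\.tsv$|\\.tab$", path)) "rtab" else "csv"
  }
  sep <- if (format == "rtab") "\t" else ","
  lines <- readLines(path)
  if (length(lines) < 2) abort(sprintf("%s: no data rows", path))
  cells <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(cells)
  if (any(widths != widths[1])) {
    bad <- which(widths != widths[1])[1]
    abort(sprintf("%s: ragged row at line %d (%d fields, expected %d)",
                  path, bad, widths[bad], widths[1]))
  }
  header <- cells[[1]]
  body <- cells[-1]
  row_ids <- vapply(body, `[[`, "", 1)
  col_ids <- header[-1]
  vals <- suppressWarnings(
    vapply(body, function(r) as.numeric(r[-1]), numeric(length(col_ids)))
  )
  # vals: columns of the file's rows -> matrix (file-cols x file-rows)
  M <- if (length(col_ids) == 1) matrix(vals, nrow = 1) else vals
  nn <- which(is.na(M))
  if (length(nn) > 0) {
    idx <- arrayInd(nn[1], dim(M))
    abort(sprintf("%s: non-numeric or missing cell at data row %d, column %d",
                  path, idx[2], idx[1] + 1))
  }
  if (any(M < 0)) abort(sprintf("%s: negative cells are not allowed", path))
  n_coerced <- sum(M > 0 & M != 1)
  if (n_coerced > 0) {
    warn(sprintf("%s: coerced %d non-binary cell(s) > 0 to 1", path, n_coerced))
    M[M > 0] <- 1
  }
  if (format == "rtab") {
    # file rows are features, file columns are strains
    G <- matrix(as.integer(M), nrow = length(col_ids),
                dimnames = list(col_ids, row_ids))
    sample_ids <- col_ids; feature_ids <- row_ids
  } else {
    # file rows are strains, file columns are features
    G <- matrix(as.integer(M), nrow = length(body), byrow = TRUE,
                dimnames = list(row_ids, col_ids))
    sample_ids <- row_ids; feature_ids <- col_ids
  }
  if (anyDuplicated(sample_ids)) {
    abort(sprintf("%s: duplicate sample id '%s'", path,
                  sample_ids[duplicated(sample_ids)][1]))
  }
  if (anyDuplicated(feature_ids)) {
    abort(sprintf("%s: duplicate feature id '%s'", path,
                  feature_ids[duplicated(feature_ids)][1]))
  }
  new_genotype_matrix(G)
}

#' Write a binary genotype matrix
#'
#' @param G Genotype matrix (samples x features).
#' @param path Output path.
#' @param format `"rtab"` (features as rows) or `"csv"` (samples as rows);
#'   `"auto"` picks by extension.
#' @return `path`, invisibly.
#' @export
write_genotype_matrix <- function(G, path, format = c("auto", "rtab", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.[Rr]tab$|\\.tsv$|\\.tab$", path)) "rtab" else "csv"
  }
  G <- as.matrix(G)
  if (format == "rtab") {
    out <- c(paste(c("feature_id", rownames(G)), collapse = "\t"),
             vapply(seq_len(ncol(G)), function(j) {
               paste(c(colnames(G)[j], G[, j]), collapse = "\t")
             }, character(1)))
  } else {
    out <- c(paste(c("sample_id", colnames(G)), collapse = ","),
             vapply(seq_len(nrow(G)), function(i) {
               paste(c(rownames(G)[i], G[i, ]), collapse = ",")
             }, character(1)))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a phenotype table
#'
#' CSV with the sample id in the first column and one numeric column per
#' sensor/taste channel.  Missing or non-numeric cells are rejected with
#' their coordinates.  When a genotype matrix is supplied the rows are
#' aligned to its strain order by id join (never by row order); any sample
#' set mismatch is an error listing the offenders.
#'
#' @param path CSV path.
#' @param genotypes Optional `genotype_matrix` to align against.
#' @return Tibble with `sample_id` plus numeric phenotype columns.
#' @export
read_phenotypes <- function(path, genotypes = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  P <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  names(P)[1] <- "sample_id"
  if (anyDuplicated(P$sample_id)) {
    abort(sprintf("%s: duplicate sample id '%s'", path,
                  P$sample_id[duplicated(P$sample_id)][1]))
  }
  for (j in seq(2, ncol(P))) {
    raw <- P[[j]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num))
    if (length(bad) > 0) {
      abort(sprintf("%s: missing or non-numeric cell at row %d, column '%s'",
                    path, bad[1], names(P)[j]))
    }
    P[[j]] <- num
  }
  if (!is.null(genotypes)) {
    g_ids <- rownames(genotypes)
    extra <- setdiff(P$sample_id, g_ids)
    missing <- setdiff(g_ids, P$sample_id)
    if (length(extra) > 0 || length(missing) > 0) {
      abort(sprintf(
        "sample sets disagree; only in phenotypes: %s; only in genotypes: %s",
        paste(head(extra, 5), collapse = ", ") %|blank|% "none",
        paste(head(missing, 5), collapse = ", ") %|blank|% "none"))
    }
    P <- P[match(g_ids, P$sample_id), , drop = FALSE]
  }
  tibble::as_tibble(P)
}

`%|blank|%` <- function(a, b) if (nzchar(a)) a else b

#' Write a phenotype table
#' @param P Tibble with `sample_id` and numeric phenotype columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(P, path) {
  readr::write_csv(P, path, progress = FALSE)
  invisible(path)
}

# --- run configuration -------------------------------------------------------

#' Read a run configuration (JSON or YAML)
#'
#' A run configuration drives the command-line interface.  It must contain
#' exactly one of `simulate` (a simulation design) or `inputs` (paths to a
#' genotype matrix and phenotype table, checked for existence at load time),
#' plus optional `dbo`, `pipeline` and `models` sections, `out_dir` and
#' `seed`.
#'
#' @param path Config path (`.json`, `.yaml` or `.yml`).
#' @return A validated list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config not found: %s", path))
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_run_config(cfg, dirname(path))
}

validate_run_config <- function(cfg, base_dir = ".") {
  has_sim <- !is.null(cfg$simulate)
  has_inp <- !is.null(cfg$inputs)
  if (has_sim == has_inp) {
    abort("config must contain exactly one of 'simulate' or 'inputs'")
  }
  if (has_inp) {
    for (field in c("genotypes", "phenotypes")) {
      p <- cfg$inputs[[field]]
      if (is.null(p)) abort(sprintf("config inputs: missing '%s' path", field))
      if (!file.exists(p) && !file.exists(file.path(base_dir, p))) {
        abort(sprintf("config inputs: path does not exist: %s", p))
      }
      if (!file.exists(p)) cfg$inputs[[field]] <- file.path(base_dir, p)
    }
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$out_dir <- cfg$out_dir %||% "pansense_out"
  cfg$dbo <- modifyList(list(pop_size = 50, max_iter = 100), cfg$dbo %||% list())
  cfg$pipeline <- modifyList(
    list(cv_folds = 10, fold_seed = 2024, lambda = 1,
         min_features_range = c(100, 300), max_components = NULL),
    cfg$pipeline %||% list())
  cfg$models <- cfg$models %||% model_names()
  structure(cfg, class = "run_config")
}

#' Write a run configuration
#' @param cfg A `run_config` (or plain list).
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  cfg <- unclass(cfg)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null")
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

# --- fitted pipeline serialization ------------------------------------------

#' Serialize a fitted pipeline to a directory of text files
#'
#' Writes `pipeline.json` (parameters, masks as feature id lists,
#' standardization constants, ridge fit, format version) plus CSVs for the
#' loading matrix and component scores.  [read_fitted_pipeline()] restores
#' the object losslessly.
#'
#' @param fp A `fitted_pipeline`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fitted_pipeline <- function(fp, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    format_version = "1",
    params = unclass(fp$params),
    feature_ids = fp$feature_ids,
    vt_ids = names(fp$vt_mask)[fp$vt_mask],
    ufs_ids = names(fp$ufs_mask)[fp$ufs_mask],
    rfecv_ids = fp$selected_ids,
    feature_center = fp$feature_center,
    feature_scale = fp$feature_scale,
    pca_center = fp$pca_center,
    explained_variance = fp$explained_variance,
    ridge_intercept = fp$ridge_intercept,
    ridge_coefficients = fp$ridge_coefficients,
    y = fp$y
  )
  jsonlite::write_json(meta, file.path(dir, "pipeline.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_csv(tibble::as_tibble(fp$loading_matrix, rownames = "feature_id"),
                   file.path(dir, "loadings.csv"), progress = FALSE)
  readr::write_csv(tibble::as_tibble(fp$component_scores, rownames = "sample_id"),
                   file.path(dir, "scores.csv"), progress = FALSE)
  readr::write_csv(fp$rfecv_path, file.path(dir, "rfecv_path.csv"),
                   progress = FALSE)
  invisible(dir)
}

#' Restore a fitted pipeline written by [write_fitted_pipeline()]
#' @param dir Directory containing `pipeline.json`.
#' @return A `fitted_pipeline`.
#' @export
read_fitted_pipeline <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "pipeline.json"),
                              simplifyVector = TRUE)
  load_tbl <- readr::read_csv(file.path(dir, "loadings.csv"),
                              show_col_types = FALSE, progress = FALSE)
  L <- as.matrix(load_tbl[, -1])
  rownames(L) <- load_tbl$feature_id
  sc_tbl <- readr::read_csv(file.path(dir, "scores.csv"),
                            show_col_types = FALSE, progress = FALSE)
  S <- as.matrix(sc_tbl[, -1])
  rownames(S) <- sc_tbl$sample_id
  path <- readr::read_csv(file.path(dir, "rfecv_path.csv"),
                          show_col_types = FALSE, progress = FALSE)
  ids <- meta$feature_ids
  as_mask <- function(kept) setNames(ids %in% kept, ids)
  structure(
    list(params = do.call(pipeline_params, meta$params[
           c("variance_threshold", "percentile", "rfecv_step",
             "min_features", "scoring", "n_components")]),
         feature_ids = ids,
         vt_mask = as_mask(meta$vt_ids),
         ufs_mask = as_mask(meta$ufs_ids),
         rfecv_mask = as_mask(meta$rfecv_ids),
         selected_ids = meta$rfecv_ids,
         feature_center = setNames(meta$feature_center, meta$rfecv_ids),
         feature_scale = setNames(meta$feature_scale, meta$rfecv_ids),
         pca_center = setNames(meta$pca_center, meta$rfecv_ids),
         loading_matrix = L,
         component_scores = S,
         explained_variance = meta$explained_variance,
         ridge_intercept = meta$ridge_intercept,
         ridge_coefficients = meta$ridge_coefficients,
         rfecv_path = tibble::as_tibble(path),
         y = meta$y),
    class = "fitted_pipeline"
  )
}
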