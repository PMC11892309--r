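#' Fit a PCA model on blood expression
#'
#' Samples are observations and genes are features. Each gene is centered by
#' its mean and (by default) scaled by its standard deviation; the rotation is
#' the top-`K` right singular vectors of the standardized samples x genes
#' matrix, ordered by decreasing singular value. The sign of each component is
#' fixed deterministically: its largest-magnitude loading is positive.
#' Zero-variance genes are dropped with a warning and recorded in the model.
#'
#' @param blood An [expr_mat()] with unit `"log2cpm"` or `"normalized"`.
#' @param K Number of components to keep (default 20). Must not exceed the
#'   numerical rank of the standardized matrix.
#' @param scale. Standardize genes to unit variance (default `TRUE`); if
#'   `FALSE` genes are only centered.
#' @return An object of class `pca_model` with fields `gene_ids`,
#'   `gene_means`, `gene_sds`, `rotation` (genes x K), `sdev`, `K`, `scale.`,
#'   `n_samples`, `dropped_genes`.
#' @export
fit_pca <- function(blood, K = 20, scale. = TRUE) {
  check_unit(blood, c("log2cpm", "normalized"))
  v <- em_values(blood)
  n <- ncol(v)
  if (K < 1) abort("K must be >= 1.")
  if (n < K + 2) abort(sprintf("Need at least K + 2 = %d samples, got %d.", K + 2, n))
  sds <- apply(v, 1L, sd)
  dropped <- rownames(v)[sds == 0]
  if (length(dropped)) {
    warn(sprintf("Dropping %d zero-variance gene(s) before PCA.", length(dropped)))
    v <- v[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  means <- rowMeans(v)
  if (!scale.) sds <- rep(1, length(means))
  x <- t((v - means) / sds)                      # samples x genes, standardized
  sv <- svd(x, nu = 0, nv = min(dim(x)))
  rank_x <- sum(sv$d > max(sv$d) * 1e-8 * max(dim(x)))
  if (K > rank_x) {
    abort(sprintf("K = %d exceeds the numerical rank (%d) of the standardized matrix.",
                  K, rank_x))
  }
  rotation <- sv$v[, seq_len(K), drop = FALSE]
  # deterministic sign: largest-magnitude loading of each component positive
  for (k in seq_len(K)) {
    if (rotation[which.max(abs(rotation[, k])), k] < 0) {
      rotation[, k] <- -rotation[, k]
    }
  }
  dimnames(rotation) <- list(rownames(v), paste0("PC", seq_len(K)))
  structure(list(
    gene_ids = rownames(v),
    gene_means = setNames(means, rownames(v)),
    gene_sds = setNames(sds, rownames(v)),
    rotation = rotation,
    sdev = sv$d[seq_len(K)] / sqrt(n - 1),
    K = K,
    scale. = scale.,
    n_samples = n,
    dropped_genes = dropped
  ), class = "pca_model")
}

#' Project blood samples onto a fitted PCA model
#'
#' New samples are standardized with the model's stored per-gene means and
#' SDs (never the new data's own statistics), then multiplied by the rotation.
#' Genes absent from the new data contribute 0 after standardization, i.e.
#' they are treated as sitting at the training mean; if fewer than half of the
#' model's genes are present, projection fails.
#'
#' @param model A `pca_model` from [fit_pca()].
#' @param blood An [expr_mat()] sharing gene identifiers with the model.
#' @return A samples x K numeric matrix of component scores.
#' @export
project_pca <- function(model, blood) {
  v <- em_values(blood)
  present <- intersect(model$gene_ids, rownames(v))
  coverage <- length(present) / length(model$gene_ids)
  if (coverage < 0.5) {
    abort(sprintf("Gene coverage %.1f%% is below the 50%% floor (%d of %d model genes present).",
                  100 * coverage, length(present), length(model$gene_ids)))
  }
  x <- matrix(0, nrow = ncol(v), ncol = length(model$gene_ids),
              dimnames = list(colnames(v), model$gene_ids))
  x[, present] <- t((v[present, , drop = FALSE] - model$gene_means[present]) /
                      model$gene_sds[present])
  x %*% model$rotation
}

#' Train per-gene linear models of target-tissue expression on PC scores
#'
#' For each target-tissue (lung) gene, an ordinary least-squares regression of
#' its expression on the K component scores plus an intercept. Genes with zero
#' variance are skipped and recorded.
#'
#' @param scores Samples x K score matrix from [project_pca()].
#' @param lung An [expr_mat()] whose samples match the score rows, in order.
#' @return A list with `coef` (genes x (K+1) coefficient matrix, intercept
#'   first) and `skipped` (tibble of gene_id, reason).
#' @export
train_gene_models <- function(scores, lung) {
  v <- em_values(lung)
  if (ncol(v) != nrow(scores)) {
    abort("Number of lung samples must equal the number of score rows.")
  }
  K <- ncol(scores)
  if (ncol(v) < K + 2) abort(sprintf("Need at least K + 2 = %d samples.", K + 2))
  design <- cbind("(Intercept)" = 1, scores)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    abort("Rank-deficient design: score columns are collinear.")
  }
  sds <- apply(v, 1L, sd)
  skipped <- tibble::tibble(gene_id = rownames(v)[sds == 0],
                            reason = rep("zero variance", sum(sds == 0)))
  y <- t(v[sds > 0, , drop = FALSE])
  coef <- t(qr.coef(qr_d, y))
  colnames(coef) <- colnames(design)
  list(coef = coef, skipped = skipped)
}

#' Train a complete imputation bundle from paired blood and lung samples
#'
#' Composes [fit_pca()] on blood, [project_pca()] of the training samples, and
#' [train_gene_models()] on the paired lung matrix. Blood and lung must cover
#' the same subjects; lung columns are reordered to match blood.
#'
#' @inheritParams fit_pca
#' @param lung An [expr_mat()] paired with `blood` by sample identifier.
#' @return An object of class `crosstx_bundle`: fields `pca`, `coef`,
#'   `skipped`, `K`, `training_n`, `created`, `format_version`.
#' @export
train_bundle <- function(blood, lung, K = 20, scale. = TRUE) {
  validate_expr_mat(lung)
  bs <- em_samples(blood)
  ls <- em_samples(lung)
  if (!setequal(bs, ls)) {
    mism <- c(setdiff(bs, ls), setdiff(ls, bs))
    abort(sprintf("Blood and lung samples are not paired; unmatched: %s.",
                  paste(head(mism, 5L), collapse = ", ")))
  }
  lung_v <- em_values(lung)[, bs, drop = FALSE]
  lung <- rewrap(lung_v, lung)
  pca <- fit_pca(blood, K = K, scale. = scale.)
  scores <- project_pca(pca, blood)
  gm <- train_gene_models(scores, lung)
  structure(list(
    pca = pca,
    coef = gm$coef,
    skipped = gm$skipped,
    K = K,
    training_n = length(bs),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    format_version = "1.0"
  ), class = "crosstx_bundle")
}

#' Impute target-tissue expression from blood
#'
#' @param bundle A `crosstx_bundle` from [train_bundle()] or [load_bundle()].
#' @param blood An [expr_mat()] of blood expression for new samples (gene
#'   coverage of the bundle's PCA genes must be at least 50%).
#' @return An [expr_mat()] with unit `"imputed"`: rows are the bundle's
#'   modeled target-tissue genes, columns the input samples.
#' @export
impute <- function(bundle, blood) {
  scores <- project_pca(bundle$pca, blood)
  fitted <- bundle$coef %*% t(cbind(1, scores))
  colnames(fitted) <- rownames(scores)
  expr_mat(fitted, unit = "imputed")
}

#' @export
print.crosstx_bundle <- function(x, ...) {
  cat(sprintf("<crosstx_bundle> K = %d PCs, %d gene models, trained on %d subjects (format %s)\n",
              x$K, nrow(x$coef), x$training_n, x$format_version))
  invisible(x)
}

#' Save / load an imputation bundle
#'
#' The bundle is written as inspectable, language-neutral text: a JSON
#' metadata sidecar (`meta.json`, carrying the format version) plus
#' tab-delimited tables for the PCA gene statistics, rotation and per-gene
#' regression coefficients. Loading verifies the format version.
#'
#' @param bundle A `crosstx_bundle`.
#' @param dir Directory to write to (created if needed).
#' @return `save_bundle()` returns `dir` invisibly; `load_bundle()` returns a
#'   `crosstx_bundle`.
#' @export
save_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- list(
    format_version = bundle$format_version,
    K = bundle$K,
    training_n = bundle$training_n,
    created = bundle$created,
    scale. = bundle$pca$scale.,
    n_samples = bundle$pca$n_samples,
    dropped_genes = bundle$pca$dropped_genes
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_tsv(tibble::tibble(gene_id = bundle$pca$gene_ids,
                                  mean = unname(bundle$pca$gene_means),
                                  sd = unname(bundle$pca$gene_sds)),
                   file.path(dir, "pca_gene_stats.tsv"), progress = FALSE)
  rot <- tibble::as_tibble(bundle$pca$rotation)
  rot <- dplyr::bind_cols(tibble::tibble(gene_id = bundle$pca$gene_ids), rot)
  readr::write_tsv(rot, file.path(dir, "pca_rotation.tsv"), progress = FALSE)
  readr::write_tsv(tibble::tibble(sdev = bundle$pca$sdev),
                   file.path(dir, "pca_sdev.tsv"), progress = FALSE)
  cf <- tibble::as_tibble(bundle$coef)
  cf <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(bundle$coef)), cf)
  readr::write_tsv(cf, file.path(dir, "gene_models.tsv"), progress = FALSE)
  readr::write_tsv(bundle$skipped, file.path(dir, "skipped_genes.tsv"),
                   progress = FALSE)
  invisible(dir)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) abort(sprintf("No bundle found at '%s'.", dir))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$format_version, "1.0")) {
    abort(sprintf("Unsupported bundle format_version '%s' (expected '1.0').",
                  meta$format_version %||% "<missing>"))
  }
  stats <- readr::read_tsv(file.path(dir, "pca_gene_stats.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  rot <- readr::read_tsv(file.path(dir, "pca_rotation.tsv"),
                         show_col_types = FALSE, progress = FALSE)
  sdev <- readr::read_tsv(file.path(dir, "pca_sdev.tsv"),
                          show_col_types = FALSE, progress = FALSE)
  cf <- readr::read_tsv(file.path(dir, "gene_models.tsv"),
                        show_col_types = FALSE, progress = FALSE)
  skipped <- readr::read_tsv(file.path(dir, "skipped_genes.tsv"),
                             show_col_types = FALSE, progress = FALSE,
                             col_types = readr::cols(gene_id = "c", reason = "c"))
  rotation <- as.matrix(rot[, -1L, drop = FALSE])
  rownames(rotation) <- rot$gene_id
  if (ncol(rotation) != meta$K || nrow(stats) != nrow(rotation)) {
    abort("Bundle files are inconsistent with meta.json (truncated or corrupted).")
  }
  coef <- as.matrix(cf[, -1L, drop = FALSE])
  rownames(coef) <- cf$gene_id
  if (ncol(coef) != meta$K + 1L) {
    abort("Bundle gene-model table is inconsistent with meta.json.")
  }
  pca <- structure(list(
    gene_ids = stats$gene_id,
    gene_means = setNames(stats$mean, stats$gene_id),
    gene_sds = setNames(stats$sd, stats$gene_id),
    rotation = rotation,
    sdev = sdev$sdev,
    K = meta$K,
    scale. = meta$scale.,
    n_samples = meta$n_samples,
    dropped_genes = as.character(unlist(meta$dropped_genes))
  ), class = "pca_model")
  structure(list(
    pca = pca, coef = coef, skipped = skipped, K = meta$K,
    training_n = meta$training_n, created = meta$created,
    format_version = meta$format_version
  ), class = "crosstx_bundle")
}
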