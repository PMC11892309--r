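#' Tidy an imputation bundle into a long coefficient table
#'
#' @param x A `crosstx_bundle`.
#' @param ... Unused.
#' @return A tibble with columns `gene_id`, `term`, `estimate` (one row per
#'   regression coefficient, intercept included).
#' @method tidy crosstx_bundle
#' @export
tidy.crosstx_bundle <- function(x, ...) {
  cf <- tibble::as_tibble(x$coef)
  cf$gene_id <- rownames(x$coef)
  tidyr::pivot_longer(cf, -"gene_id", names_to = "term", values_to = "estimate")
}

#' @rdname tidy.crosstx_bundle
#' @return `glance()` returns a one-row summary tibble.
#' @method glance crosstx_bundle
#' @export
glance.crosstx_bundle <- function(x, ...) {
  tibble::tibble(
    K = x$K,
    training_n = x$training_n,
    n_gene_models = nrow(x$coef),
    n_skipped = nrow(x$skipped),
    n_pca_genes = length(x$pca$gene_ids),
    format_version = x$format_version
  )
}

#' @method tidy pca_model
#' @export
tidy.pca_model <- function(x, ...) {
  rot <- tibble::as_tibble(x$rotation)
  rot$gene_id <- x$gene_ids
  tidyr::pivot_longer(rot, -"gene_id", names_to = "component",
                      values_to = "loading")
}

#' @method glance pca_model
#' @export
glance.pca_model <- function(x, ...) {
  tibble::tibble(K = x$K, n_genes = length(x$gene_ids),
                 n_samples = x$n_samples,
                 n_dropped = length(x$dropped_genes),
                 var_explained = sum(x$sdev^2) /
                   (if (x$scale.) length(x$gene_ids) else NA_real_))
}

#' @method glance crosstx_cv
#' @export
glance.crosstx_cv <- function(x, ...) {
  sel <- x$selected
  tibble::tibble(
    n_genes = nrow(x),
    n_selected = sum(sel, na.rm = TRUE),
    mean_cv_accuracy = mean(x$mean_fold_r[sel], na.rm = TRUE),
    median_cv_accuracy = median(x$mean_fold_r[sel], na.rm = TRUE),
    k = attr(x, "k"), K = attr(x, "K"), n = attr(x, "n"),
    seed = attr(x, "seed")
  )
}

#' @method glance crosstx_replication
#' @export
glance.crosstx_replication <- function(x, ...) {
  tibble::tibble(
    n_evaluated = nrow(x),
    n_replicated = sum(x$replicated, na.rm = TRUE),
    pct_replicated = 100 * sum(x$replicated, na.rm = TRUE) / nrow(x),
    mean_validation_accuracy = mean(x$r_rep, na.rm = TRUE),
    n_excluded = attr(x, "n_excluded")
  )
}

#' @method glance crosstx_dge
#' @export
glance.crosstx_dge <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_significant = sum(x$q <= 0.05, na.rm = TRUE),
    n_case = attr(x, "n_case"),
    n_control = attr(x, "n_control"),
    df = attr(x, "df")
  )
}

#' Plot methods for analysis results
#'
#' `autoplot()` on a cross-validation result draws the distribution of pooled
#' out-of-fold correlations split by selection status; on a replication result
#' a training-vs-replication accuracy scatter with the decision thresholds; on
#' a differential-expression result a volcano plot.
#'
#' @param object A `crosstx_cv`, `crosstx_replication` or `crosstx_dge`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot crosstx_cv
#' @export
autoplot.crosstx_cv <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- df[!is.na(df$pooled_r), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pooled_r, fill = .data$selected)) +
    ggplot2::geom_histogram(bins = 60, alpha = 0.8, position = "identity") +
    ggplot2::labs(x = "pooled out-of-fold Pearson r", y = "genes",
                  fill = "selected",
                  title = sprintf("Cross-validated imputation accuracy (K = %s, %s-fold)",
                                  attr(object, "K"), attr(object, "k"))) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.crosstx_cv
#' @method autoplot crosstx_replication
#' @export
autoplot.crosstx_replication <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r_train, y = .data$r_rep,
                                   colour = .data$replicated)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_abline(linetype = "dashed") +
    ggplot2::geom_hline(yintercept = attr(object, "r_min"), linetype = "dotted") +
    ggplot2::labs(x = "training pooled r", y = "replication r",
                  title = "Replication of imputation accuracy") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.crosstx_cv
#' @method autoplot crosstx_dge
#' @export
autoplot.crosstx_dge <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$sig <- !is.na(df$q) & df$q <= 0.05
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(.data$p),
                                   colour = .data$sig)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (case - control)",
                  y = "-log10 p", colour = "q <= 0.05",
                  title = "Differential expression") +
    ggplot2::theme_minimal()
}
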