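#' Exclude samples above an age ceiling
#'
#' Retains samples with `age <= max_age`; strictly older samples are excluded
#' (so at the default ceiling of 70, a 70-year-old is kept and a 70.5- or
#' 71-year-old is dropped). Typically used to match a replication cohort's age
#' range to the training cohort's.
#'
#' @param meta A metadata tibble (see [read_sample_metadata()]).
#' @param max_age Age ceiling in years (default 70).
#' @return The retained metadata rows.
#' @export
filter_age <- function(meta, max_age = 70) {
  if (!"age" %in% names(meta)) abort("Metadata must contain an `age` column.")
  missing_age <- is.na(meta$age)
  if (any(missing_age)) {
    abort(sprintf("Missing age for sample(s): %s.",
                  paste(head(meta$sample_id[missing_age], 5L), collapse = ", ")))
  }
  dplyr::filter(meta, .data$age <= max_age)
}

#' Label COPD cases and controls from spirometry
#'
#' A sample is a case when its FEV1/FVC ratio is strictly below
#' `ratio_threshold` (post-spirometry airflow obstruction), otherwise a
#' control. Samples with a missing ratio are labeled `"unknown"` with a
#' warning and should be excluded from differential expression.
#'
#' @param meta A metadata tibble with a `fev1_fvc` column.
#' @param ratio_threshold Case threshold on FEV1/FVC (default 0.7, strict).
#' @return `meta` with a `status` column (`"case"`, `"control"`, `"unknown"`).
#' @export
copd_case_control <- function(meta, ratio_threshold = 0.7) {
  if (!"fev1_fvc" %in% names(meta)) abort("Metadata must contain `fev1_fvc`.")
  r <- meta$fev1_fvc
  if (all(is.na(r))) abort("All FEV1/FVC ratios are missing; no cases definable.")
  if (anyNA(r)) {
    warn(sprintf("%d sample(s) with missing FEV1/FVC labeled 'unknown'.",
                 sum(is.na(r))))
  }
  dplyr::mutate(meta, status = dplyr::case_when(
    is.na(r) ~ "unknown",
    r < ratio_threshold ~ "case",
    TRUE ~ "control"
  ))
}

#' Covariate-adjusted per-gene differential expression
#'
#' For each gene, an ordinary least-squares fit of expression on a
#' case/control indicator plus optional covariates. The reported `log2fc` is
#' the status coefficient (case minus control) — on log2-scale expression this
#' is the adjusted log2 fold change — with a two-sided t-test on the residual
#' degrees of freedom and Benjamini-Hochberg adjustment across genes. No
#' variance moderation is applied: each gene uses its own residual variance.
#'
#' @param expr An [expr_mat()] of (typically log2-scale or imputed)
#'   expression.
#' @param status Per-sample labels, `"case"`/`"control"` (in sample order), or
#'   a metadata tibble carrying `sample_id` and `status` columns.
#' @param covariates Optional per-sample data frame of covariates (e.g. sex,
#'   age and the four leukocyte percentages), rows in sample order.
#' @return A tibble of class `crosstx_dge` with columns `gene_id`, `log2fc`,
#'   `t_stat`, `p`, `q`.
#' @export
fit_dge <- function(expr, status, covariates = NULL) {
  validate_expr_mat(expr)
  v <- em_values(expr)
  if (is.data.frame(status)) {
    idx <- match(em_samples(expr), status$sample_id)
    if (anyNA(idx)) abort("Every expression sample needs a metadata row.")
    status <- status$status[idx]
  }
  if (length(status) != ncol(v)) abort("`status` must have one label per sample.")
  keep <- status %in% c("case", "control")
  if (any(!keep)) {
    warn(sprintf("Dropping %d sample(s) with status outside case/control.",
                 sum(!keep)))
    v <- v[, keep, drop = FALSE]
    status <- status[keep]
    if (!is.null(covariates)) covariates <- covariates[keep, , drop = FALSE]
  }
  if (sum(status == "case") < 2 || sum(status == "control") < 2) {
    abort("Need at least 2 samples in each group.")
  }
  design <- cbind("(Intercept)" = 1, status_case = as.numeric(status == "case"))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (anyNA(covariates)) abort("Covariates must not contain missing values.")
    cmat <- model.matrix(~ ., data = covariates)[, -1L, drop = FALSE]
    design <- cbind(design, cmat)
  }
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    dropped <- colnames(design)[qr_d$pivot[(qr_d$rank + 1):ncol(design)]]
    abort(sprintf("Design is not full rank; collinear term(s): %s.",
                  paste(dropped, collapse = ", ")))
  }
  df <- ncol(v) - ncol(design)
  if (df < 1) abort("No residual degrees of freedom.")
  coef <- t(qr.coef(qr_d, t(v)))                   # genes x terms
  resid <- t(qr.resid(qr_d, t(v)))
  sigma2 <- rowSums(resid^2) / df
  xtx_inv <- chol2inv(qr.R(qr_d))        # inverse in pivoted column order
  pos <- which(qr_d$pivot == 2L)
  se <- sqrt(sigma2 * xtx_inv[pos, pos])
  log2fc <- coef[, "status_case"]
  t_stat <- ifelse(se > 0, log2fc / se, ifelse(log2fc == 0, 0, Inf * sign(log2fc)))
  p <- 2 * pt(-abs(t_stat), df = df)
  res <- tibble::tibble(
    gene_id = rownames(v),
    log2fc = unname(log2fc),
    t_stat = unname(t_stat),
    p = unname(p),
    q = bh_fdr(unname(p))
  )
  tibble::new_tibble(res, n_case = sum(status == "case"),
                     n_control = sum(status == "control"), df = df,
                     class = "crosstx_dge")
}

#' Log2-fold-change concordance against a reference table
#'
#' Pearson correlation of two sets of per-gene log2 fold changes over their
#' shared genes. With `gene_filter = "reference_significant"` (default) the
#' comparison is restricted to genes significant in the reference table
#' (`q <= q_max`); `"all_shared"` uses every shared gene.
#'
#' @param a A `crosstx_dge` result (or any table with `gene_id` and `log2fc`).
#' @param reference A table with columns `gene_id`, `log2fc` and (for the
#'   default filter) `q`.
#' @param gene_filter `"reference_significant"` or `"all_shared"`.
#' @param q_max Significance cutoff applied to the reference (default 0.05).
#' @return A one-row tibble with `r`, `p`, `n_genes`.
#' @export
logfc_concordance <- function(a, reference,
                              gene_filter = c("reference_significant", "all_shared"),
                              q_max = 0.05) {
  gene_filter <- match.arg(gene_filter)
  a <- tibble::as_tibble(a)
  reference <- tibble::as_tibble(reference)
  if (gene_filter == "reference_significant") {
    if (!"q" %in% names(reference)) {
      abort("The reference table needs a `q` column for the reference_significant filter.")
    }
    reference <- dplyr::filter(reference, .data$q <= q_max)
  }
  shared <- dplyr::inner_join(
    dplyr::select(a, "gene_id", lfc_a = "log2fc"),
    dplyr::select(reference, "gene_id", lfc_ref = "log2fc"),
    by = "gene_id"
  )
  if (nrow(shared) < 10L) {
    abort(sprintf("Only %d shared genes after filtering; need at least 10.",
                  nrow(shared)))
  }
  acc <- per_gene_accuracy(shared$lfc_a, shared$lfc_ref)
  tibble::tibble(r = acc$r, p = acc$p, n_genes = nrow(shared))
}
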