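#' Fisher-z comparison of two Pearson correlations
#'
#' Two-sided z-test for the difference between two independent correlations:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with the p-value
#' from the standard normal. Vectorized over all four arguments.
#'
#' @param r1,r2 Correlations with absolute value strictly below 1.
#' @param n1,n2 Sample sizes, each greater than 3.
#' @return A tibble with columns `z` and `p`.
#' @export
#'
#' @examples
#' fisher_z_compare(0.5, 100, 0.3, 100)
fisher_z_compare <- function(r1, n1, r2, n2) {
  if (any(abs(c(r1, r2)) >= 1)) {
    abort("|r| must be < 1 (the z transform is infinite at 1).")
  }
  if (any(c(n1, n2) <= 3)) abort("Sample sizes must exceed 3.")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  tibble::tibble(z = z, p = 2 * pnorm(-abs(z)))
}

#' Evaluate replication of cross-validated imputation accuracy
#'
#' Restricted to genes selected by cross-validation, imputes the replication
#' cohort's target-tissue expression from its blood profiles, correlates
#' imputed against observed per gene, and compares the replication correlation
#' with the training (pooled out-of-fold) correlation by [fisher_z_compare()].
#' A gene replicates when the two accuracies do not differ significantly
#' (uncorrected `p > p_min`, strict) and the replication correlation is at
#' least `r_min` (inclusive). No multiple-testing correction is applied to the
#' replication p-values.
#'
#' Genes absent from the replication target-tissue matrix, or with a constant
#' observed or imputed profile, are excluded and counted in the
#' `n_excluded` attribute.
#'
#' @param cv A `crosstx_cv` from [cross_validate()].
#' @param bundle The `crosstx_bundle` trained on the full training cohort.
#' @param rep_blood,rep_lung Paired replication matrices (same subjects).
#' @param r_min Minimum replication correlation (default 0.1, inclusive).
#' @param p_min Fisher-z p-value floor (default 0.05; replication requires
#'   `p > p_min`).
#' @return A tibble of class `crosstx_replication` with columns `gene_id`,
#'   `r_train`, `n_train`, `r_rep`, `n_rep`, `z`, `p`, `replicated`.
#' @export
evaluate_replication <- function(cv, bundle, rep_blood, rep_lung,
                                 r_min = 0.1, p_min = 0.05) {
  validate_expr_mat(rep_blood); validate_expr_mat(rep_lung)
  subjects <- em_samples(rep_blood)
  if (!setequal(subjects, em_samples(rep_lung))) {
    abort("Replication blood and lung matrices must cover the same subjects.")
  }
  n_rep <- length(subjects)
  if (n_rep <= 3) abort("Replication needs more than 3 subjects.")
  n_train <- attr(cv, "n")
  sel <- select_genes(cv, r2_min = attr(cv, "r2_min") %||% 0.01,
                      q_max = attr(cv, "q_max") %||% 0.05)
  imp <- em_values(impute(bundle, rep_blood))[, subjects, drop = FALSE]
  obs_all <- em_values(rep_lung)[, subjects, drop = FALSE]
  genes <- intersect(sel$gene_id, intersect(rownames(imp), rownames(obs_all)))
  n_excluded <- nrow(sel) - length(genes)
  if (length(genes) == 0L) abort("No selected genes are present in the replication data.")
  r_rep <- row_cor(imp[genes, , drop = FALSE], obs_all[genes, , drop = FALSE])
  r_train <- sel$pooled_r[match(genes, sel$gene_id)]
  usable <- !is.na(r_rep) & abs(r_rep) < 1 & abs(r_train) < 1
  n_excluded <- n_excluded + sum(!usable)
  z <- p <- rep(NA_real_, length(genes))
  if (any(usable)) {
    zt <- fisher_z_compare(r_train[usable], n_train, r_rep[usable], n_rep)
    z[usable] <- zt$z
    p[usable] <- zt$p
  }
  res <- tibble::tibble(
    gene_id = genes,
    r_train = r_train,
    n_train = n_train,
    r_rep = r_rep,
    n_rep = n_rep,
    z = z,
    p = p,
    replicated = is_replicated(p, r_rep, p_min = p_min, r_min = r_min)
  )
  tibble::new_tibble(res, n_excluded = n_excluded, r_min = r_min,
                     p_min = p_min, class = "crosstx_replication")
}

#' Replication decision rule
#'
#' A gene's cross-validated accuracy is deemed replicated when the Fisher-z
#' comparison shows no significant difference (uncorrected `p > p_min`,
#' strict) and the replication correlation reaches `r_min` (inclusive).
#' Missing values yield `FALSE`.
#'
#' @param p Fisher-z two-sided p-value(s).
#' @param r_rep Replication correlation(s).
#' @inheritParams evaluate_replication
#' @return Logical vector.
#' @export
is_replicated <- function(p, r_rep, p_min = 0.05, r_min = 0.1) {
  !is.na(p) & p > p_min & !is.na(r_rep) & r_rep >= r_min
}

#' Direct blood-vs-target-tissue expression concordance
#'
#' For every gene shared between the two paired matrices, the Pearson
#' correlation of its blood values against its target-tissue values across
#' subjects. Genes constant in either tissue are flagged with `NA`
#' correlation.
#'
#' @param blood,lung Paired [expr_mat()] objects (same subjects).
#' @return A tibble with columns `gene_id`, `r`, `n`, `flagged`.
#' @export
blood_lung_concordance <- function(blood, lung) {
  h <- harmonize_genes(blood, lung)
  subjects <- em_samples(h$a)
  if (!setequal(subjects, em_samples(h$b))) {
    abort("Blood and lung matrices must cover the same subjects.")
  }
  a <- em_values(h$a)
  b <- em_values(h$b)[, subjects, drop = FALSE]
  r <- row_cor(a, b)
  tibble::tibble(gene_id = rownames(a), r = r, n = length(subjects),
                 flagged = is.na(r))
}
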