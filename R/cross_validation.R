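#' Randomly assign subjects to cross-validation folds
#'
#' Balanced assignment (fold sizes differ by at most 1), deterministic given
#' the seed. Assignment is at the subject level, so paired blood/lung samples
#' from one subject always land in the same fold.
#'
#' @param subject_ids Character vector of subject identifiers.
#' @param k Number of folds (default 5).
#' @param seed Integer seed (required; there is no hidden default).
#' @return A tibble with columns `subject_id` and `fold`.
#' @export
assign_folds <- function(subject_ids, k = 5, seed) {
  if (missing(seed)) abort("`seed` is required for reproducible fold assignment.")
  n <- length(subject_ids)
  if (k < 2) abort("k must be >= 2.")
  if (k > n) abort(sprintf("k = %d exceeds the number of subjects (%d).", k, n))
  labels <- rep(seq_len(k), length.out = n)
  fold <- withr::with_seed(seed, sample(labels))
  tibble::tibble(subject_id = as.character(subject_ids), fold = fold)
}

#' Per-gene prediction accuracy
#'
#' Pearson correlation of observed vs predicted values, its square, and a
#' two-sided p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom.
#'
#' @param observed,predicted Numeric vectors of equal length (at least 4),
#'   neither constant.
#' @return A one-row tibble with columns `r`, `r2`, `p`, `n`.
#' @export
per_gene_accuracy <- function(observed, predicted) {
  n <- length(observed)
  if (length(predicted) != n) abort("Vectors must have equal length.")
  if (n < 4) abort("Need at least 4 paired values.")
  if (sd(observed) == 0 || sd(predicted) == 0) {
    abort("Correlation is undefined for a constant vector.")
  }
  r <- cor(observed, predicted)
  tibble::tibble(r = r, r2 = r^2, p = cor_pvalue(r, n), n = n)
}

# two-sided p for a Pearson correlation via the t transform; saturates at |r|=1
cor_pvalue <- function(r, n) {
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r)
  rr <- pmin(1, pmax(-1, r[ok]))
  t_abs <- rep(Inf, length(rr))
  inside <- abs(rr) < 1
  t_abs[inside] <- abs(rr[inside]) * sqrt((n - 2) / (1 - rr[inside]^2))
  p[ok] <- 2 * pt(-t_abs, df = n - 2)
  p
}

#' Per-gene k-fold cross-validation of the imputation model
#'
#' For each fold, the PCA and all per-gene models are refit on the training
#' folds only (no leakage) and the held-out subjects are predicted. Each gene
#' is scored by its per-fold Pearson correlation (averaged over folds, and
#' squared then averaged for the R-squared accuracy measure) and by the pooled
#' correlation over the concatenated out-of-fold predictions, whose two-sided
#' p-value feeds Benjamini-Hochberg adjustment across genes. A gene is
#' selected when `mean_fold_r2 >= r2_min`, `q <= q_max` and (by default) the
#' pooled correlation is positive.
#'
#' @inheritParams train_bundle
#' @param k Number of folds (default 5).
#' @param seed Integer seed for fold assignment (required).
#' @param r2_min Minimum mean fold R-squared for selection (default 0.01).
#' @param q_max Maximum BH-adjusted p for selection (default 0.05).
#' @param require_positive Also require `pooled_r > 0` (default `TRUE`); this
#'   guards against selecting systematically anti-correlated predictions,
#'   which squared correlation alone would admit.
#' @return A tibble of class `crosstx_cv` with columns `gene_id`,
#'   `mean_fold_r`, `mean_fold_r2`, `pooled_r`, `pooled_p`, `q`, `selected`,
#'   and attributes `k`, `seed`, `n`, `K`, `r2_min`, `q_max`.
#' @export
cross_validate <- function(blood, lung, K = 20, k = 5, seed,
                           r2_min = 0.01, q_max = 0.05,
                           require_positive = TRUE, scale. = TRUE) {
  if (missing(seed)) abort("`seed` is required.")
  validate_expr_mat(blood); validate_expr_mat(lung)
  subjects <- em_samples(blood)
  if (!setequal(subjects, em_samples(lung))) {
    abort("Blood and lung matrices must cover the same subjects.")
  }
  n <- length(subjects)
  min_train <- n - ceiling(n / k)
  if (min_train < K + 2) {
    abort(sprintf("Smallest training split (%d subjects) cannot support K = %d components; use a smaller K.",
                  min_train, K))
  }
  folds <- assign_folds(subjects, k = k, seed = seed)
  lung_v <- em_values(lung)[, subjects, drop = FALSE]
  blood_v <- em_values(blood)
  pred <- matrix(NA_real_, nrow(lung_v), n, dimnames = dimnames(lung_v))
  fold_r <- matrix(NA_real_, nrow(lung_v), k,
                   dimnames = list(rownames(lung_v), NULL))
  for (f in seq_len(k)) {
    test_ids <- folds$subject_id[folds$fold == f]
    train_ids <- setdiff(subjects, test_ids)
    b_train <- rewrap(blood_v[, train_ids, drop = FALSE], blood)
    l_train <- rewrap(lung_v[, train_ids, drop = FALSE], lung)
    bundle <- train_bundle(b_train, l_train, K = K, scale. = scale.)
    b_test <- rewrap(blood_v[, test_ids, drop = FALSE], blood)
    imp <- em_values(impute(bundle, b_test))
    pred[rownames(imp), test_ids] <- imp
    obs <- lung_v[rownames(imp), test_ids, drop = FALSE]
    fold_r[rownames(imp), f] <- row_cor(obs, imp)
  }
  valid <- rowSums(!is.na(pred)) == n & apply(lung_v, 1L, sd) > 0
  pooled_r <- rep(NA_real_, nrow(lung_v))
  pooled_r[valid] <- row_cor(lung_v[valid, , drop = FALSE],
                             pred[valid, , drop = FALSE])
  pooled_p <- cor_pvalue(pooled_r, n)
  q <- rep(NA_real_, length(pooled_p))
  ok <- !is.na(pooled_p)
  q[ok] <- bh_fdr(pooled_p[ok])
  res <- tibble::tibble(
    gene_id = rownames(lung_v),
    mean_fold_r = unname(rowMeans(fold_r, na.rm = TRUE)),
    mean_fold_r2 = unname(rowMeans(fold_r^2, na.rm = TRUE)),
    pooled_r = pooled_r,
    pooled_p = pooled_p,
    q = q
  )
  res$mean_fold_r[is.nan(res$mean_fold_r)] <- NA_real_
  res$mean_fold_r2[is.nan(res$mean_fold_r2)] <- NA_real_
  res$selected <- !is.na(res$q) & !is.na(res$mean_fold_r2) &
    res$mean_fold_r2 >= r2_min & res$q <= q_max &
    (!require_positive | res$pooled_r > 0)
  tibble::new_tibble(res, k = k, seed = seed, n = n, K = K,
                     r2_min = r2_min, q_max = q_max,
                     class = "crosstx_cv")
}

# rowwise Pearson correlation between two matrices of identical shape
row_cor <- function(a, b) {
  a <- a - rowMeans(a)
  b <- b - rowMeans(b)
  den <- sqrt(rowSums(a^2) * rowSums(b^2))
  out <- pmin(1, pmax(-1, rowSums(a * b) / den))
  out[den == 0] <- NA_real_
  unname(out)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values: `q_(i) = min over j >= i of min(1, m p_(j) / j)`
#' on the sorted p-values, returned in the input order.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\] (no missing values).
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    abort("p-values must lie in [0, 1] with no missing values.")
  }
  p.adjust(pvals, method = "BH")
}

#' Select reliably imputed genes from a cross-validation result
#'
#' A gene is selected when its fold-averaged squared correlation is at least
#' `r2_min`, its BH-adjusted p-value is at most `q_max`, and (optionally) its
#' pooled out-of-fold correlation is positive. Both thresholds are inclusive.
#'
#' @param cv A `crosstx_cv` tibble from [cross_validate()].
#' @inheritParams cross_validate
#' @return The selected rows of `cv`.
#' @export
select_genes <- function(cv, r2_min = 0.01, q_max = 0.05,
                         require_positive = TRUE) {
  dplyr::filter(tibble::as_tibble(cv),
                !is.na(.data$mean_fold_r2), !is.na(.data$q),
                .data$mean_fold_r2 >= r2_min, .data$q <= q_max,
                !require_positive | .data$pooled_r > 0)
}

#' Sweep the number of principal components
#'
#' Runs [cross_validate()] for each requested component count and summarizes
#' the number of selected genes and their mean accuracy; when an independent
#' paired replication dataset is supplied, each bundle is additionally
#' refit on the full training data and evaluated with
#' [evaluate_replication()], adding replicated counts and mean validation
#' accuracy per K.
#'
#' @inheritParams cross_validate
#' @param K_list Integer vector of component counts, e.g. `c(5, 10, 20, 40)`.
#' @param rep_blood,rep_lung Optional paired replication matrices.
#' @return A tibble with one row per K: `n_pcs`, `n_selected`,
#'   `mean_cv_accuracy`, and with replication data `n_imputed_rep`,
#'   `mean_validation_accuracy`, `n_replicated`, `pct_replicated`.
#' @export
pc_sweep <- function(blood, lung, K_list = c(5, 10, 20, 40), k = 5, seed,
                     rep_blood = NULL, rep_lung = NULL,
                     r2_min = 0.01, q_max = 0.05, scale. = TRUE) {
  if (missing(seed)) abort("`seed` is required.")
  purrr::map_dfr(K_list, function(K) {
    cv <- cross_validate(blood, lung, K = K, k = k, seed = seed,
                         r2_min = r2_min, q_max = q_max, scale. = scale.)
    sel <- select_genes(cv, r2_min = r2_min, q_max = q_max)
    out <- tibble::tibble(
      n_pcs = K,
      n_selected = nrow(sel),
      mean_cv_accuracy = mean(sel$mean_fold_r)
    )
    if (!is.null(rep_blood) && !is.null(rep_lung)) {
      bundle <- train_bundle(blood, lung, K = K, scale. = scale.)
      rep <- evaluate_replication(cv, bundle, rep_blood, rep_lung)
      out$n_imputed_rep <- nrow(rep)
      out$mean_validation_accuracy <- mean(rep$r_rep, na.rm = TRUE)
      out$n_replicated <- sum(rep$replicated, na.rm = TRUE)
      out$pct_replicated <- 100 * out$n_replicated / out$n_imputed_rep
    }
    out
  })
}
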