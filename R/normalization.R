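#' Counts per million
#'
#' Scales each sample's counts by its library size (the full column sum,
#' computed before any gene filtering) times 1e6, so every output column sums
#' to one million.
#'
#' @param m An [expr_mat()] with unit `"counts"`.
#' @return An [expr_mat()] with unit `"cpm"`.
#' @export
counts_to_cpm <- function(m) {
  check_unit(m, "counts")
  v <- em_values(m)
  lib <- colSums(v)
  if (any(lib <= 0)) {
    abort(sprintf("Zero library size in sample(s): %s.",
                  paste(colnames(v)[lib <= 0], collapse = ", ")))
  }
  rewrap(sweep(v, 2L, lib, "/") * 1e6, m, unit = "cpm")
}

#' Remove genes with low expression across the cohort
#'
#' A gene is removed when its CPM is at or below `cpm_threshold` in at least
#' `min_samples` samples. Gene order is otherwise preserved. The defaults
#' implement the common bulk RNA-seq rule of dropping genes with CPM <= 1 in
#' 100 or more participants.
#'
#' @param m An [expr_mat()] with unit `"cpm"`.
#' @param cpm_threshold CPM value at or below which a sample counts as
#'   non-expressing (default 1).
#' @param min_samples Number of non-expressing samples that triggers removal
#'   (default 100).
#' @return A filtered [expr_mat()] with unit `"cpm"`.
#' @export
filter_low_expression <- function(m, cpm_threshold = 1, min_samples = 100) {
  check_unit(m, "cpm")
  v <- em_values(m)
  if (min_samples > ncol(v)) {
    warn(sprintf("min_samples (%d) exceeds the number of samples (%d); no genes removed.",
                 min_samples, ncol(v)))
    return(m)
  }
  low <- rowSums(v <= cpm_threshold)
  rewrap(v[low < min_samples, , drop = FALSE], m)
}

#' Log2 transform with pseudocount
#'
#' @param m An [expr_mat()] with unit `"cpm"`.
#' @param pseudocount Positive offset added before taking log2 (default 1, so
#'   zero CPM maps to zero).
#' @return An [expr_mat()] with unit `"log2cpm"`.
#' @export
log2_transform <- function(m, pseudocount = 1) {
  check_unit(m, "cpm")
  if (pseudocount <= 0) abort("pseudocount must be > 0.")
  rewrap(log2(em_values(m) + pseudocount), m, unit = "log2cpm")
}

#' Quantile normalization
#'
#' Forces every sample to share one empirical distribution: the per-rank mean
#' of the sorted columns. Tied values within a column receive the mean of the
#' target values over their tied ranks, so the transform is deterministic and
#' rank order within each column is preserved up to ties.
#'
#' @param m An [expr_mat()] with at least two samples.
#' @return An [expr_mat()] with unit `"normalized"`.
#' @export
quantile_normalize <- function(m) {
  v <- em_values(m)
  if (ncol(v) < 2L) abort("Quantile normalization needs at least 2 samples.")
  target <- rowMeans(apply(v, 2L, sort, method = "radix"))
  cs <- c(0, cumsum(target))
  out <- apply(v, 2L, function(x) {
    rmin <- rank(x, ties.method = "min")
    rmax <- rank(x, ties.method = "max")
    (cs[rmax + 1L] - cs[rmin]) / (rmax - rmin + 1L)
  })
  dimnames(out) <- dimnames(v)
  rewrap(out, m, unit = "normalized")
}

#' Trimmed mean of M-values scaling factors
#'
#' Between-sample scaling factors from the Robinson-Oshlack TMM estimator: a
#' reference sample is chosen as the one whose upper-quartile of library-size-
#' scaled counts is closest to the mean upper-quartile; each sample's factor is
#' 2 to the precision-weighted mean of per-gene log2 expression ratios
#' (M-values) against the reference, after two-sided trimming of the most
#' extreme `trim_m` of M-values and `trim_a` of average log expression
#' (A-values), with inverse approximate-binomial-variance weights. Genes with a
#' zero count in either the sample or the reference are excluded. Factors are
#' rescaled to have geometric mean 1.
#'
#' @param m An [expr_mat()] with unit `"counts"` and at least 2 samples.
#' @param trim_m Two-sided trim fraction on M-values (default 0.30).
#' @param trim_a Two-sided trim fraction on A-values (default 0.05).
#' @return A tibble with columns `sample_id` and `tmm_factor`.
#' @export
tmm_factors <- function(m, trim_m = 0.30, trim_a = 0.05) {
  check_unit(m, "counts")
  v <- em_values(m)
  if (ncol(v) < 2L) abort("TMM needs at least 2 samples.")
  lib <- colSums(v)
  if (any(lib <= 0)) {
    abort(sprintf("Sample(s) with all-zero counts: %s.",
                  paste(colnames(v)[lib <= 0], collapse = ", ")))
  }
  x <- v[rowSums(v > 0) > 0L, , drop = FALSE]
  uq <- vapply(seq_len(ncol(x)),
               function(j) quantile(x[, j], probs = 0.75, names = FALSE),
               numeric(1)) / lib
  if (median(uq) < 1e-20) {
    ref <- which.max(colSums(sqrt(x)))
  } else {
    ref <- which.min(abs(uq - mean(uq)))
  }
  f <- vapply(seq_len(ncol(x)), function(j) {
    tmm_pair(x[, j], x[, ref], lib[j], lib[ref], trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  tibble::tibble(sample_id = colnames(v), tmm_factor = f)
}

# One sample's TMM factor against the reference (Robinson & Oshlack 2010).
tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  p_obs <- obs / n_obs
  p_ref <- ref / n_ref
  keep <- obs > 0 & ref > 0
  m_val <- log2(p_obs[keep] / p_ref[keep])
  a_val <- (log2(p_obs[keep]) + log2(p_ref[keep])) / 2
  w <- (n_obs - obs[keep]) / n_obs / obs[keep] +
       (n_ref - ref[keep]) / n_ref / ref[keep]
  if (length(m_val) == 0L) return(1)
  if (max(abs(m_val)) < 1e-6) return(1)
  n <- length(m_val)
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  rm_ <- rank(m_val)
  ra_ <- rank(a_val)
  use <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
  f <- sum(m_val[use] / w[use], na.rm = TRUE) / sum(1 / w[use], na.rm = TRUE)
  if (is.na(f)) f <- 0
  2^f
}

#' Location/scale batch adjustment
#'
#' Per gene, each batch's values are standardized (batch mean subtracted,
#' batch SD divided out) and rescaled to the gene's pooled mean and SD, so
#' batch means and spreads are equalized while within-batch ranks are
#' preserved. Genes with zero variance within any batch are mean-centered per
#' batch only (shifted to the pooled mean). This is a deliberately simple
#' location/scale standardization, not an empirical-Bayes method: no
#' shrinkage across genes is applied.
#'
#' @param m An [expr_mat()].
#' @param batch Per-sample batch labels (length = number of samples, in sample
#'   order). Every batch must contain at least 2 samples.
#' @return An [expr_mat()] with unit `"normalized"`.
#' @export
adjust_batches <- function(m, batch) {
  v <- em_values(m)
  batch <- as.character(batch)
  if (length(batch) != ncol(v)) {
    abort("`batch` must have one label per sample.")
  }
  sizes <- table(batch)
  if (any(sizes < 2L)) {
    abort(sprintf("Singleton batch(es): %s.",
                  paste(names(sizes)[sizes < 2L], collapse = ", ")))
  }
  pooled_mean <- rowMeans(v)
  pooled_sd <- apply(v, 1L, sd)
  out <- v
  idx <- split(seq_len(ncol(v)), batch)
  b_mean <- vapply(idx, function(i) rowMeans(v[, i, drop = FALSE]),
                   numeric(nrow(v)))
  b_sd <- vapply(idx, function(i) apply(v[, i, drop = FALSE], 1L, sd),
                 numeric(nrow(v)))
  if (nrow(v) == 1L) { b_mean <- rbind(b_mean); b_sd <- rbind(b_sd) }
  # genes with a degenerate batch (or pooled) SD fall back to mean-centering
  scale_ok <- rowSums(b_sd == 0) == 0L & pooled_sd > 0
  for (k in seq_along(idx)) {
    i <- idx[[k]]
    centred <- v[, i, drop = FALSE] - b_mean[, k]
    if (any(scale_ok)) {
      out[scale_ok, i] <- (centred / b_sd[, k] * pooled_sd +
                             pooled_mean)[scale_ok, , drop = FALSE]
    }
    if (any(!scale_ok)) {
      out[!scale_ok, i] <- (centred + pooled_mean)[!scale_ok, , drop = FALSE]
    }
  }
  rewrap(out, m, unit = "normalized")
}

check_unit <- function(m, expected) {
  validate_expr_mat(m)
  if (!em_unit(m) %in% expected) {
    abort(sprintf("Expected unit %s but got '%s'.",
                  paste(sprintf("'%s'", expected), collapse = " or "),
                  em_unit(m)))
  }
  invisible(m)
}
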