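#' Reference model-comparison summary
#'
#' Loads the reference summary of blood-to-lung imputation models at 5, 10,
#' 20 and 40 principal components (number of transcripts imputed in the
#' external replication cohort, mean cross-validation and validation
#' accuracies, and replicated-transcript counts with the percentages as
#' originally printed). Used by the worked example of replicated-fraction
#' arithmetic.
#'
#' @return A tibble with columns `n_pcs`, `n_imputed`, `mean_cv_accuracy`,
#'   `mean_validation_accuracy`, `n_replicated`, `pct_replicated_printed`.
#' @export
pc_model_summary <- function() {
  readr::read_tsv(system.file("extdata", "pc_model_summary.tsv",
                              package = "crosstx"),
                  show_col_types = FALSE, progress = FALSE)
}

#' Replicated fraction as a percentage
#'
#' `100 * n_replicated / n_imputed`, vectorized; the percentage of reliably
#' imputed transcripts whose prediction accuracy replicated externally.
#'
#' @param n_replicated,n_imputed Non-negative counts with
#'   `n_replicated <= n_imputed` and `n_imputed > 0`.
#' @return Numeric vector of percentages.
#' @export
#'
#' @examples
#' replicated_fraction(2713, 7971)
replicated_fraction <- function(n_replicated, n_imputed) {
  if (any(n_imputed <= 0)) abort("n_imputed must be positive.")
  if (any(n_replicated < 0 | n_replicated > n_imputed)) {
    abort("n_replicated must lie in [0, n_imputed].")
  }
  100 * n_replicated / n_imputed
}
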