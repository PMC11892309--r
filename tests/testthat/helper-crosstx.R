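# shared fixtures, built in code

make_mat <- function(values, genes = NULL, samples = NULL, unit = "counts") {
  values <- as.matrix(values)
  genes <- genes %||% sprintf("g%d", seq_len(nrow(values)))
  samples <- samples %||% sprintf("s%d", seq_len(ncol(values)))
  expr_mat(values, gene_ids = genes, sample_ids = samples, unit = unit)
}

rand_counts <- function(n_genes, n_samples, seed, lambda = 50) {
  withr::with_seed(seed, {
    v <- matrix(stats::rpois(n_genes * n_samples, lambda), n_genes, n_samples)
    make_mat(v, unit = "counts")
  })
}

rand_norm_mat <- function(n_genes, n_samples, seed, unit = "normalized") {
  withr::with_seed(seed, {
    make_mat(matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples),
             unit = unit)
  })
}

`%||%` <- rlang::`%||%`

row_cor_test_helper <- function(a, b) {
  sapply(seq_len(nrow(a)), function(i) stats::cor(a[i, ], b[i, ]))
}

# brute-force Benjamini-Hochberg step-up, straight from the definition:
# q_(i) = min_{j >= i} min(1, m p_(j) / j) on sorted p, mapped back
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  p_sorted <- p[ord]
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p_sorted[i:m] / (i:m)))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}
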