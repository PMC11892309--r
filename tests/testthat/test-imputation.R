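test_that("PCA reproduces fit-time scores and matches an eigendecomposition oracle", {
  m <- rand_norm_mat(4, 5, seed = 7)              # 4 genes x 5 samples
  pca <- fit_pca(m, K = 3)
  # round trip: projecting the training samples gives the fit-time scores
  x <- scale(t(em_values(m)))
  scores_direct <- x %*% pca$rotation
  expect_equal(unname(project_pca(pca, m)), unname(scores_direct),
               tolerance = 1e-8)
  # component variances equal the eigenvalues of the standardized covariance
  ev <- eigen(cov(x), symmetric = TRUE)$values
  expect_equal(pca$sdev^2, ev[1:3], tolerance = 1e-8)
  # orthonormal rotation
  expect_equal(crossprod(pca$rotation), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  # deterministic sign: largest-magnitude loading positive
  for (k in 1:3) {
    expect_gt(pca$rotation[which.max(abs(pca$rotation[, k])), k], 0)
  }
})

test_that("PCA guards its preconditions", {
  m <- rand_norm_mat(10, 6, seed = 8)
  expect_error(fit_pca(m, K = 6), "rank|samples")
  expect_identical(eval(formals(fit_pca)$K), 20)
  v <- em_values(m)
  v[1, ] <- 3                                      # zero-variance gene
  expect_warning(p <- fit_pca(make_mat(v, unit = "normalized"), K = 2),
                 "zero-variance")
  expect_identical(p$dropped_genes, "g1")
  expect_false("g1" %in% p$gene_ids)
})

test_that("projection uses stored training statistics", {
  m <- rand_norm_mat(30, 40, seed = 9)
  pca <- fit_pca(m, K = 4)
  # a sample at the training gene means projects to the origin
  mean_sample <- make_mat(cbind(pca$gene_means), genes = pca$gene_ids,
                          samples = "new", unit = "normalized")
  expect_equal(unname(project_pca(pca, mean_sample)), matrix(0, 1, 4),
               tolerance = 1e-10)
  # dropping one gene shifts scores by minus its standardized value x loading row
  one <- make_mat(em_values(m)[, 1, drop = FALSE], genes = em_genes(m),
                  samples = "s1", unit = "normalized")
  full <- project_pca(pca, one)
  drop_g <- pca$gene_ids[5]
  partial <- project_pca(pca, make_mat(em_values(one)[-5, , drop = FALSE],
                                       genes = em_genes(one)[-5],
                                       samples = "s1", unit = "normalized"))
  zval <- (em_values(one)[drop_g, 1] - pca$gene_means[drop_g]) / pca$gene_sds[drop_g]
  expect_equal(unname(full - partial), unname(zval * pca$rotation[drop_g, , drop = FALSE]),
               tolerance = 1e-10)
  # coverage floor
  few <- make_mat(em_values(m)[1:10, 1, drop = FALSE], genes = em_genes(m)[1:10],
                  samples = "s1", unit = "normalized")
  expect_error(project_pca(pca, few), "coverage")
})

test_that("gene models recover exact linear targets and the normal equations", {
  blood <- rand_norm_mat(60, 30, seed = 10)
  pca <- fit_pca(blood, K = 3)
  scores <- project_pca(pca, blood)
  # lung gene constructed as 1 + 2 * PC1, zero noise
  lung_v <- rbind(1 + 2 * scores[, 1], deparse.level = 0)
  rownames(lung_v) <- "target"
  gm <- train_gene_models(scores, make_mat(lung_v, genes = "target",
                                           samples = rownames(scores),
                                           unit = "normalized"))
  expect_equal(unname(gm$coef["target", ]), c(1, 2, 0, 0), tolerance = 1e-8)
  # 50 random genes: coefficients equal (X'X)^-1 X'Y from an independent oracle
  lung <- withr::with_seed(1, {
    make_mat(matrix(rnorm(50 * 30), 50, 30), samples = rownames(scores),
             unit = "normalized")
  })
  gm2 <- train_gene_models(scores, lung)
  x <- cbind(1, scores)
  beta_oracle <- t(solve(t(x) %*% x, t(x) %*% t(em_values(lung))))
  expect_lt(max(abs(unname(gm2$coef) - unname(beta_oracle))), 1e-8)
  # constant lung gene skipped with a record
  lung_c <- make_mat(rbind(rep(2, 30)), genes = "flat",
                     samples = rownames(scores), unit = "normalized")
  gm3 <- train_gene_models(scores, lung_c)
  expect_identical(gm3$skipped$gene_id, "flat")
  expect_identical(gm3$skipped$reason, "zero variance")
  # duplicated score columns are rank-deficient
  expect_error(train_gene_models(cbind(scores, scores[, 1]), lung),
               "collinear|Rank")
})

test_that("bundles compose PCA and gene models; truncation property holds", {
  sim <- simulate_paired(60, n_blood_genes = 80, n_lung_genes = 20,
                         n_factors = 4, shared_fractions = 0.5, seed = 12)
  b5 <- train_bundle(sim$blood, sim$lung, K = 5)
  b10 <- train_bundle(sim$blood, sim$lung, K = 10)
  expect_identical(b5$K, 5)
  expect_identical(nrow(b5$coef), 20L)
  expect_equal(b5$pca$rotation, b10$pca$rotation[, 1:5], tolerance = 1e-10)
  # unpaired samples are rejected with the mismatches listed
  drop1 <- make_mat(em_values(sim$lung)[, -1], genes = em_genes(sim$lung),
                    samples = em_samples(sim$lung)[-1], unit = "normalized")
  expect_error(train_bundle(sim$blood, drop1, K = 5), "S0001")
})

test_that("noise-free lung genes are reproduced exactly in-sample", {
  sim <- simulate_paired(100, n_blood_genes = 150, n_lung_genes = 30,
                         n_factors = 5, shared_fractions = 1, noise_sd = 0,
                         seed = 13)
  bundle <- train_bundle(sim$blood, sim$lung, K = 5)
  imp <- em_values(impute(bundle, sim$blood))
  obs <- em_values(sim$lung)[rownames(imp), ]
  r <- sapply(seq_len(nrow(imp)), function(g) cor(imp[g, ], obs[g, ]))
  expect_true(all(r >= 1 - 1e-6))
})

test_that("imputation is the advertised linear map", {
  # hand-built K = 1 bundle: y = 1 + 2 * score
  pca <- structure(list(gene_ids = "bg", gene_means = c(bg = 0),
                        gene_sds = c(bg = 1),
                        rotation = matrix(1, 1, 1, dimnames = list("bg", "PC1")),
                        sdev = 1, K = 1, scale. = TRUE, n_samples = 10,
                        dropped_genes = character(0)), class = "pca_model")
  bundle <- structure(list(pca = pca,
                           coef = matrix(c(1, 2), 1, 2,
                                         dimnames = list("lg", c("(Intercept)", "PC1"))),
                           skipped = tibble::tibble(gene_id = character(0),
                                                    reason = character(0)),
                           K = 1, training_n = 10, created = "t",
                           format_version = "1.0"), class = "crosstx_bundle")
  blood <- make_mat(matrix(0.5, 1, 1), genes = "bg", samples = "s1",
                    unit = "normalized")
  expect_equal(em_values(impute(bundle, blood))["lg", "s1"], 2.0)

  # imputing the training matrix equals in-sample fitted values, and matches
  # a brute-force per-sample dot-product oracle
  sim <- simulate_paired(100, n_blood_genes = 100, n_lung_genes = 25,
                         n_factors = 5, seed = 14)
  b <- train_bundle(sim$blood, sim$lung, K = 8)
  scores <- project_pca(b$pca, sim$blood)
  imp <- em_values(impute(b, sim$blood))
  for (g in sample(rownames(imp), 5)) {
    for (s in sample(colnames(imp), 4)) {
      oracle <- b$coef[g, 1] + sum(b$coef[g, -1] * scores[s, ])
      expect_equal(imp[g, s], oracle, tolerance = 1e-10)
    }
  }
  fitted <- b$coef %*% t(cbind(1, scores))
  expect_equal(unname(imp), unname(fitted), tolerance = 1e-12)
})

test_that("imputation is linear in standardization-consistent inputs", {
  sim <- simulate_paired(50, n_blood_genes = 60, n_lung_genes = 10,
                         n_factors = 3, seed = 15)
  b <- train_bundle(sim$blood, sim$lung, K = 3)
  v <- em_values(sim$blood)
  x <- v[, 1]; y <- v[, 2]; a <- 0.3
  mix <- make_mat(cbind(x, y, a * x + (1 - a) * y), genes = em_genes(sim$blood),
                  samples = c("x", "y", "mix"), unit = "normalized")
  imp <- em_values(impute(b, mix))
  expect_equal(unname(imp[, "mix"]),
               unname(a * imp[, "x"] + (1 - a) * imp[, "y"]),
               tolerance = 1e-8)
})

test_that("bundles survive a save/load round trip and refuse corrupt input", {
  sim <- simulate_paired(40, n_blood_genes = 50, n_lung_genes = 12,
                         n_factors = 3, seed = 16)
  b <- train_bundle(sim$blood, sim$lung, K = 3)
  dir <- withr::local_tempdir()
  save_bundle(b, dir)
  b2 <- load_bundle(dir)
  expect_equal(em_values(impute(b2, sim$blood)),
               em_values(impute(b, sim$blood)), tolerance = 1e-12)
  expect_identical(b2$format_version, "1.0")
  # truncated rotation table -> explicit error
  rot <- readLines(file.path(dir, "pca_rotation.tsv"))
  writeLines(rot[1:5], file.path(dir, "pca_rotation.tsv"))
  expect_error(load_bundle(dir), "inconsistent|corrupt")
  # version mismatch -> explicit error
  dir2 <- withr::local_tempdir()
  save_bundle(b, dir2)
  meta <- jsonlite::read_json(file.path(dir2, "meta.json"))
  meta$format_version <- "9.9"
  jsonlite::write_json(meta, file.path(dir2, "meta.json"), auto_unbox = TRUE)
  expect_error(load_bundle(dir2), "format_version")
})
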