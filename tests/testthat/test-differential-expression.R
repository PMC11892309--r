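meta_fixture <- function(n = 8, seed = 50) {
  withr::with_seed(seed, tibble::tibble(
    sample_id = sprintf("s%d", 1:n),
    subject_id = sprintf("p%d", 1:n),
    age = round(runif(n, 40, 75), 1),
    sex = sample(c("male", "female"), n, TRUE),
    fev1_fvc = round(runif(n, 0.4, 0.9), 2)
  ))
}

test_that("the age filter keeps 70 and excludes anyone strictly older", {
  meta <- meta_fixture()
  meta$age <- c(69, 70, 70.5, 71, 50, 60, 65, 68)
  kept <- filter_age(meta)
  expect_identical(kept$sample_id, meta$sample_id[c(1, 2, 5:8)])
  expect_identical(filter_age(meta, max_age = 100), meta)  # all retained
  meta$age[2] <- NA
  expect_error(filter_age(meta), "s2")
})

test_that("COPD status comes from a strict FEV1/FVC < 0.7 rule", {
  meta <- meta_fixture()
  meta$fev1_fvc <- c(0.69, 0.70, 0.71, 0.5, NA, 0.699, 0.8, 0.9)
  expect_warning(lab <- copd_case_control(meta), "unknown")
  expect_identical(lab$status,
                   c("case", "control", "control", "case", "unknown",
                     "case", "control", "control"))
  meta$fev1_fvc <- NA_real_
  expect_error(copd_case_control(meta), "no cases")
})

test_that("with no covariates the status coefficient is the group mean difference", {
  expr <- make_mat(rbind(c(1, 2, 3, 3, 4, 5),
                         c(2, 2, 2, 2, 2, 2.0001),
                         c(10, 11, 9, 5, 4, 6)), unit = "normalized")
  status <- rep(c("control", "case"), each = 3)
  res <- fit_dge(expr, status)
  diffs <- rowMeans(em_values(expr)[, 4:6]) - rowMeans(em_values(expr)[, 1:3])
  expect_equal(res$log2fc, unname(diffs))
  expect_equal(res$log2fc[1], 2)
  # symmetric case: identical group values give exactly zero
  sym <- make_mat(rbind(c(1, 5, 9, 1, 5, 9)), unit = "normalized")
  expect_equal(fit_dge(sym, status)$log2fc, 0)
})

test_that("fit_dge agrees with lm() and respects Frisch-Waugh-Lovell", {
  n <- 40
  sim <- withr::with_seed(51, {
    list(v = matrix(rnorm(20 * n), 20, n),
         status = sample(rep(c("case", "control"), n / 2)),
         age = runif(n, 40, 70),
         pct = rnorm(n, 60, 5))
  })
  expr <- make_mat(sim$v, unit = "normalized")
  covars <- data.frame(age = sim$age, pct_neut = sim$pct)
  res <- fit_dge(expr, sim$status, covars)
  for (g in c(1, 7, 20)) {
    fit <- lm(sim$v[g, ] ~ I(sim$status == "case") + sim$age + sim$pct)
    sm <- summary(fit)$coefficients[2, ]
    expect_equal(res$log2fc[g], unname(sm["Estimate"]), tolerance = 1e-10)
    expect_equal(res$t_stat[g], unname(sm["t value"]), tolerance = 1e-8)
    expect_equal(res$p[g], unname(sm["Pr(>|t|)"]), tolerance = 1e-8)
  }
  # a covariate orthogonal to status leaves the coefficient unchanged
  status_num <- as.numeric(sim$status == "case")
  ortho <- residuals(lm(sim$age ~ status_num))
  res_plain <- fit_dge(expr, sim$status)
  res_ortho <- fit_dge(expr, sim$status, data.frame(o = ortho))
  expect_equal(res_ortho$log2fc, res_plain$log2fc, tolerance = 1e-10)
  # collinear covariates are named
  expect_error(fit_dge(expr, sim$status,
                       data.frame(a = sim$age, b = 2 * sim$age)),
               "collinear")
  expect_error(fit_dge(expr, c("case", rep("control", n - 1))), "each group")
})

test_that("null p-values are approximately uniform", {
  # f = 0 gives independent null genes, so the KS statistic has its nominal
  # sampling distribution rather than the inflated one of factor-correlated genes
  sim <- simulate_case_control(100, 100, n_blood_genes = 50,
                               n_lung_genes = 2000, n_factors = 5,
                               shared_fractions = 0, seed = 52)
  res <- fit_dge(sim$lung, sim$meta$status,
                 sim$meta[, c("sex", "age", "pct_neut", "pct_lymph",
                              "pct_mono", "pct_eos")])
  ks <- suppressWarnings(ks.test(res$p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
  expect_lte(mean(res$q <= 0.05), 0.10)
})

test_that("log2FC concordance behaves as a correlation over shared genes", {
  d <- tibble::tibble(gene_id = sprintf("g%d", 1:30),
                      log2fc = withr::with_seed(53, rnorm(30)),
                      q = rep(c(0.01, 0.5), 15))
  expect_equal(logfc_concordance(d, d)$r, 1)
  neg <- dplyr::mutate(d, log2fc = -log2fc)
  expect_equal(logfc_concordance(d, neg, gene_filter = "all_shared")$r, -1)
  # reference_significant keeps only reference genes at q <= 0.05
  cc <- logfc_concordance(d, d, gene_filter = "reference_significant")
  expect_identical(cc$n_genes, 15L)
  # order invariance and symmetry for all_shared
  shuf <- d[withr::with_seed(54, sample(30)), ]
  expect_equal(logfc_concordance(d, shuf, gene_filter = "all_shared")$r, 1)
  a <- d; b <- dplyr::mutate(shuf, log2fc = log2fc + rep(c(1, -1), 15))
  expect_equal(logfc_concordance(a, b, gene_filter = "all_shared")$r,
               logfc_concordance(b, a, gene_filter = "all_shared")$r)
  expect_error(logfc_concordance(d[1:5, ], d[1:5, ], gene_filter = "all_shared"),
               "at least 10")
})

test_that("imputed-lung DE recovers shared-factor effects but not lung-private ones", {
  # at most n_factors effect genes keeps the factor-shift system exactly
  # solvable, so the embedded lung effect is exactly the requested one
  effects <- tibble::tibble(gene_id = sprintf("G%05d", 1:5),
                            true_log2fc = rep(1, 5))
  run_route <- function(route, seed) {
    sim <- simulate_case_control(300, 300, n_blood_genes = 300,
                                 n_lung_genes = 100, n_factors = 6,
                                 shared_fractions = 0.4,
                                 effect_genes = effects,
                                 effect_route = route, seed = seed)
    # train on controls only, then deploy on the whole cohort: mirrors the
    # healthy-reference-training / disease-cohort-deployment protocol and
    # keeps disease effects out of the training fit
    ctrl <- sim$meta$sample_id[sim$meta$status == "control"]
    take <- function(m, ids) expr_mat(em_values(m)[, ids],
                                      unit = em_unit(m))
    bundle <- train_bundle(take(sim$blood, ctrl), take(sim$lung, ctrl), K = 6)
    imp <- impute(bundle, sim$blood)
    list(obs = fit_dge(sim$lung, sim$meta$status),
         imp = fit_dge(imp, sim$meta$status),
         blood = fit_dge(sim$blood, sim$meta$status),
         truth = sim$truth)
  }
  priv <- run_route("lung_private", seed = 55)
  expect_lt(abs(mean(priv$imp$log2fc[priv$imp$gene_id %in% effects$gene_id])),
            0.05)
  expect_gt(mean(priv$obs$log2fc[priv$obs$gene_id %in% effects$gene_id]), 0.8)
  shared <- run_route("shared_factor", seed = 56)
  obs_eff <- shared$obs$log2fc[shared$obs$gene_id %in% effects$gene_id]
  expect_lt(abs(mean(obs_eff) - 1), 0.1)
  # imputed-lung DE concordance with the truth beats blood DE concordance
  ref <- dplyr::mutate(shared$truth$lung, log2fc = true_log2fc, q = 0)
  r_imp <- logfc_concordance(shared$imp, ref, gene_filter = "all_shared")$r
  r_blood <- logfc_concordance(shared$blood, ref, gene_filter = "all_shared")$r
  expect_gt(r_imp, 0)
  expect_gt(r_imp, r_blood)
})
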