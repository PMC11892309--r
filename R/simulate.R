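#' Simulate paired two-tissue expression with shared latent structure
#'
#' Subjects carry `n_factors` standard-normal latent factors shared by both
#' tissues. Each blood gene is a loading-weighted combination of the factors
#' plus Gaussian noise, standardized so its population variance is 1. Each
#' target-tissue ("lung") gene draws exactly a fraction `f` of its unit
#' variance from the shared factors and `1 - f` from independent noise, so `f`
#' is the gene's imputability ceiling: no predictor built from blood can
#' exceed a population correlation of `sqrt(f)` with it. Loadings are drawn
#' once per simulation from a standard normal and normalized to unit length,
#' so the mixing is generic and no gene is privileged.
#'
#' Blood and lung genes share one identifier namespace (`G00001`, ...), i.e.
#' gene `G00007` in blood and in lung is the same gene measured in two
#' tissues, with independent loadings in each.
#'
#' @param n_subjects Number of paired subjects.
#' @param n_blood_genes,n_lung_genes Gene counts per tissue.
#' @param n_factors Number of shared latent factors.
#' @param shared_fractions Per-lung-gene shared-variance fraction `f` in
#'   \[0, 1\]; a scalar is recycled, or supply a vector of length
#'   `n_lung_genes`.
#' @param noise_sd Blood noise standard deviation relative to unit factor
#'   signal (default 1, i.e. half of each blood gene's variance is factor
#'   signal).
#' @param seed Integer seed; identical parameters and seed give bit-identical
#'   output.
#' @return A list with `blood` and `lung` ([expr_mat()] objects, unit
#'   `"normalized"`) and `truth` (class `sim_truth`): per-lung-gene
#'   `shared_fraction` and `true_log2fc`, the realized latent factor matrix
#'   (`factors`), the per-tissue loadings, and the generative parameters.
#' @export
simulate_paired <- function(n_subjects, n_blood_genes = 500, n_lung_genes = 200,
                            n_factors = 10, shared_fractions = 0.3,
                            noise_sd = 1, seed) {
  if (missing(seed)) abort("`seed` is required.")
  f <- check_shared_fractions(shared_fractions, n_lung_genes)
  if (n_subjects < n_factors + 2) {
    abort("Need n_subjects >= n_factors + 2.")
  }
  withr::with_seed(seed, {
    parts <- sim_draw(n_subjects, n_blood_genes, n_lung_genes, n_factors)
    build_paired(parts, f, noise_sd, seed,
                 true_log2fc = rep(0, n_lung_genes))
  })
}

check_shared_fractions <- function(f, n_lung_genes) {
  if (length(f) == 1L) f <- rep(f, n_lung_genes)
  if (length(f) != n_lung_genes) {
    abort("shared_fractions must be a scalar or one value per lung gene.")
  }
  if (any(f < 0 | f > 1)) abort("shared_fractions must lie in [0, 1].")
  f
}

# draw everything random: latent factors, loadings, noise
sim_draw <- function(n, pb, pl, q) {
  list(
    z = matrix(rnorm(n * q), n, q),
    blood_loadings = apply(matrix(rnorm(q * pb), q, pb), 2L,
                           function(x) x / sqrt(sum(x^2))),
    lung_loadings = apply(matrix(rnorm(q * pl), q, pl), 2L,
                          function(x) x / sqrt(sum(x^2))),
    blood_noise = matrix(rnorm(pb * n), pb, n),
    lung_noise = matrix(rnorm(pl * n), pl, n),
    n = n, pb = pb, pl = pl, q = q
  )
}

# deterministic assembly given the drawn parts (so case shifts can reuse it)
build_paired <- function(parts, f, noise_sd, seed, true_log2fc,
                         z = parts$z) {
  if (length(parts$q) && ncol(z) != parts$q) abort("factor dimension mismatch")
  sample_ids <- sprintf("S%04d", seq_len(parts$n))
  blood_ids <- sprintf("G%05d", seq_len(parts$pb))
  lung_ids <- sprintf("G%05d", seq_len(parts$pl))
  blood_v <- (t(z %*% parts$blood_loadings) + noise_sd * parts$blood_noise) /
    sqrt(1 + noise_sd^2)
  lung_signal <- t(z %*% parts$lung_loadings)
  lung_v <- sqrt(f) * lung_signal + sqrt(1 - f) * parts$lung_noise
  dimnames(blood_v) <- list(blood_ids, sample_ids)
  dimnames(lung_v) <- list(lung_ids, sample_ids)
  truth <- structure(list(
    lung = tibble::tibble(gene_id = lung_ids, shared_fraction = f,
                          true_log2fc = true_log2fc),
    factors = structure(z, dimnames = list(sample_ids, NULL)),
    blood_loadings = parts$blood_loadings,
    lung_loadings = parts$lung_loadings,
    n_factors = parts$q,
    noise_sd = noise_sd,
    seed = seed
  ), class = "sim_truth")
  list(blood = expr_mat(blood_v, unit = "normalized"),
       lung = expr_mat(lung_v, unit = "normalized"),
       truth = truth)
}

#' Simulate a negative-binomial RNA-seq count matrix
#'
#' Gene means are drawn log-normal; counts are negative binomial around
#' `gene_mean x library multiplier`, with per-sample library multipliers drawn
#' uniformly from `lib_size_range`. Exercises the counting-scale operations
#' (CPM, filtering, TMM) with known library-size structure.
#'
#' @param n_genes,n_samples Matrix dimensions.
#' @param mean_log_expr List with `meanlog` and `sdlog` of the log-normal gene
#'   means (defaults 3 and 1.5 on the natural-log scale, giving a realistic
#'   spread of per-gene depth).
#' @param dispersion Negative-binomial dispersion (> 0); variance is
#'   `mu + dispersion * mu^2`.
#' @param lib_size_range Length-2 range of uniform library multipliers.
#' @param seed Integer seed.
#' @return An [expr_mat()] with unit `"counts"`.
#' @export
simulate_counts <- function(n_genes, n_samples,
                            mean_log_expr = list(meanlog = 3, sdlog = 1.5),
                            dispersion = 0.1,
                            lib_size_range = c(0.5, 1.5), seed) {
  if (missing(seed)) abort("`seed` is required.")
  if (dispersion <= 0) abort("dispersion must be > 0.")
  withr::with_seed(seed, {
    mu_g <- rlnorm(n_genes, mean_log_expr$meanlog, mean_log_expr$sdlog)
    libm <- runif(n_samples, lib_size_range[1L], lib_size_range[2L])
    mu <- outer(mu_g, libm)
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                     n_genes, n_samples)
    dimnames(counts) <- list(sprintf("G%05d", seq_len(n_genes)),
                             sprintf("S%04d", seq_len(n_samples)))
    expr_mat(counts, unit = "counts")
  })
}

#' Simulate a case-control cohort with embedded target-tissue effects
#'
#' Generates a paired cohort as in [simulate_paired()] and shifts case
#' subjects by known per-gene effects:
#'
#' * `effect_route = "shared_factor"`: the latent factors of case subjects are
#'   shifted by the minimum-norm vector that reproduces the requested
#'   target-tissue log2 fold changes through the factor loadings. The shift
#'   therefore leaves a mixed, attenuated, sign-scrambled trace in blood — and
#'   imputation, which reads blood, can recover the lung effect. Because the
#'   loadings are dense, genes outside `effect_genes` acquire small spillover
#'   effects; the realized effect of every lung gene is recorded as the truth.
#' * `effect_route = "lung_private"`: only the target-tissue residuals of the
#'   effect genes are shifted. Blood carries no trace, so imputation cannot
#'   recover the effect.
#'
#' Metadata (age, sex, batch, leukocyte percentages, FEV1/FVC consistent with
#' status) is drawn independently of expression, so covariates are
#' unconfounded by default.
#'
#' @inheritParams simulate_paired
#' @param n_cases,n_controls Group sizes.
#' @param effect_genes A tibble with columns `gene_id` (lung genes, no
#'   duplicates) and `true_log2fc`, or NULL for a null cohort.
#' @param effect_route `"shared_factor"` or `"lung_private"`.
#' @return A list with `blood`, `lung`, `meta` (metadata tibble including
#'   `status`) and `truth` (`sim_truth` with the realized per-gene
#'   `true_log2fc`).
#' @export
simulate_case_control <- function(n_cases, n_controls,
                                  n_blood_genes = 500, n_lung_genes = 200,
                                  n_factors = 10, shared_fractions = 0.3,
                                  noise_sd = 1, effect_genes = NULL,
                                  effect_route = c("shared_factor", "lung_private"),
                                  seed) {
  if (missing(seed)) abort("`seed` is required.")
  effect_route <- match.arg(effect_route)
  n <- n_cases + n_controls
  f <- check_shared_fractions(shared_fractions, n_lung_genes)
  if (n < n_factors + 2) abort("Need n_cases + n_controls >= n_factors + 2.")
  lung_ids <- sprintf("G%05d", seq_len(n_lung_genes))
  lfc <- setNames(rep(0, n_lung_genes), lung_ids)
  if (!is.null(effect_genes) && nrow(effect_genes) > 0L) {
    if (anyDuplicated(effect_genes$gene_id)) {
      abort("Each gene may be assigned an effect route only once.")
    }
    if (!all(effect_genes$gene_id %in% lung_ids)) {
      abort("effect_genes must be a subset of the simulated lung genes.")
    }
    lfc[effect_genes$gene_id] <- effect_genes$true_log2fc
  }
  withr::with_seed(seed, {
    parts <- sim_draw(n, n_blood_genes, n_lung_genes, n_factors)
    status <- sample(rep(c("case", "control"), c(n_cases, n_controls)))
    is_case <- status == "case"
    true_lfc <- lfc
    z <- parts$z
    if (effect_route == "shared_factor" && any(lfc != 0)) {
      idx <- which(lfc != 0)
      m_eff <- t(parts$lung_loadings[, idx, drop = FALSE]) * sqrt(f[idx])
      d <- pinv_solve(m_eff, lfc[idx])
      z[is_case, ] <- z[is_case, , drop = FALSE] +
        matrix(d, sum(is_case), length(d), byrow = TRUE)
      # realized effect of every lung gene through the factor shift
      true_lfc <- as.numeric(sqrt(f) * (t(parts$lung_loadings) %*% d))
      names(true_lfc) <- lung_ids
    }
    sim <- build_paired(parts, f, noise_sd, seed,
                        true_log2fc = unname(true_lfc), z = z)
    if (effect_route == "lung_private" && any(lfc != 0)) {
      v <- em_values(sim$lung)
      v[names(lfc)[lfc != 0], is_case] <-
        v[names(lfc)[lfc != 0], is_case, drop = FALSE] + lfc[lfc != 0]
      sim$lung <- rewrap(v, sim$lung)
    }
    meta <- tibble::tibble(
      sample_id = em_samples(sim$blood),
      subject_id = em_samples(sim$blood),
      age = round(runif(n, 45, 70), 1),
      sex = sample(c("male", "female"), n, replace = TRUE),
      batch = sample(c("batch1", "batch2"), n, replace = TRUE),
      disease_status = status,
      status = status,
      fev1_fvc = ifelse(is_case, runif(n, 0.40, 0.699), runif(n, 0.70, 0.92)),
      pct_neut = pmin(pmax(rnorm(n, 60, 8), 0), 100),
      pct_lymph = pmin(pmax(rnorm(n, 30, 7), 0), 100),
      pct_mono = pmin(pmax(rnorm(n, 7, 2), 0), 100),
      pct_eos = pmin(pmax(rnorm(n, 2.5, 1.2), 0), 100)
    )
    list(blood = sim$blood, lung = sim$lung, meta = meta, truth = sim$truth)
  })
}

# minimum-norm solution of A x = b via the singular value decomposition
pinv_solve <- function(a, b) {
  sv <- svd(a)
  tol <- max(dim(a)) * max(sv$d) * .Machine$double.eps
  pos <- sv$d > tol
  as.numeric(sv$v[, pos, drop = FALSE] %*%
               ((t(sv$u[, pos, drop = FALSE]) %*% b) / sv$d[pos]))
}
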