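# MAF filtering, genotype PCA, additive regression, scan, inflation
# factor, permutation significance.

make_geno <- function(dosage, pos = NULL, pops = NULL, sex = NULL) {
  m <- nrow(dosage)
  n <- ncol(dosage)
  samples <- data.frame(sample_id = sprintf("s%02d", seq_len(n)),
                        stringsAsFactors = FALSE)
  if (!is.null(pops)) samples$population <- pops
  if (!is.null(sex)) samples$sex <- sex
  dimnames(dosage) <- list(sprintf("m%02d", seq_len(m)), samples$sample_id)
  genotype_matrix(dosage,
                  data.frame(snp_id = rownames(dosage), chrom = "1",
                             pos = if (is.null(pos)) seq_len(m) * 100 else pos,
                             major = "T", minor = "C",
                             stringsAsFactors = FALSE),
                  samples)
}

test_that("the MAF filter is inclusive at the threshold and cohort-relative", {
  # 100 samples: one SNP at MAF exactly 0.01, one monomorphic, one common
  d <- rbind(c(rep(0, 98), 1, 1),        # MAF 0.02/2 = 0.01 -> removed
             rep(0, 100),                # monomorphic -> removed
             c(rep(0, 50), rep(1, 50)))  # MAF 0.25 -> kept
  g <- make_geno(d)
  kept <- maf_filter(g, 0.01)
  expect_equal(kept$info$snp_id, "m03")
  # hand-counted example: dosages {0,0,1,1} over 4 samples -> MAF 0.25
  g2 <- make_geno(matrix(c(0, 0, 1, 1), 1))
  expect_equal(unname(snp_maf(g2)), 0.25)
  expect_equal(nrow(maf_filter(g2, 0.01)$info), 1)
  expect_error(maf_filter(make_geno(matrix(0, 2, 4)), 0.01), "every SNP")
})

test_that("genotype PCA handles degenerate input and yields orthogonal PCs", {
  # identical genotype columns: no variance, all-zero components
  d <- matrix(rep(c(0, 1, 2, 1, 0), 6), 5, 6)
  pcs <- genotype_pca(make_geno(d), k = 2)
  expect_equal(unname(as.matrix(pcs[, -1])), matrix(0, 6, 2),
               tolerance = 1e-10)
  set.seed(9)
  g <- make_geno(matrix(rbinom(50 * 12, 2, 0.3), 50, 12))
  pcs <- genotype_pca(g, k = 3)
  M <- as.matrix(pcs[, -1])
  expect_lt(abs(sum(M[, 1] * M[, 2])), 1e-8)
  expect_lt(abs(sum(M[, 2] * M[, 3])), 1e-8)
  expect_error(genotype_pca(g, k = 13), "exceeds")
})

test_that("additive regression matches closed-form OLS and flags degeneracies", {
  # exact fit: slope recovered, zero residual flagged with se = 0
  dosage <- c(0, 1, 2, 0, 1, 2)
  fit <- additive_regression(2 * dosage + 7, dosage)
  expect_equal(fit$beta, 2)
  expect_equal(fit$se, 0)
  expect_equal(fit$flag, "zero_residual")
  # orthogonal phenotype: slope 0
  y <- c(1, -1, 0, -1, 1, 0)
  expect_equal(additive_regression(y - mean(y), dosage)$beta, 0,
               tolerance = 1e-12)
  # hand-computed oracle on the worked 6-sample example
  y <- c(1.0, 1.9, 3.2, 0.8, 2.1, 3.0)
  fit <- additive_regression(y, dosage)
  oracle <- brute_ols(y, dosage)
  expect_equal(fit$beta, oracle$beta)
  expect_equal(fit$se, oracle$se)
  expect_equal(fit$p_value, oracle$p_value)
  # random small cases against the closed form
  set.seed(12)
  for (i in 1:20) {
    n <- sample(5:15, 1)
    x <- rbinom(n, 2, 0.4)
    if (var(x) == 0) next
    y <- rnorm(n)
    fit <- additive_regression(y, x)
    oracle <- brute_ols(y, x)
    expect_equal(fit$beta, oracle$beta)
    expect_equal(fit$p_value, oracle$p_value)
  }
  # constant dosage flagged, not silently p = 1
  fit <- additive_regression(rnorm(5), rep(1, 5))
  expect_equal(fit$flag, "constant_dosage")
  expect_true(is.na(fit$p_value))
})

test_that("additive regression with covariates agrees with lm()", {
  set.seed(33)
  n <- 40
  x <- rbinom(n, 2, 0.3)
  C <- cbind(sex = rbinom(n, 1, 0.5), pc1 = rnorm(n))
  y <- 0.5 * x + 0.3 * C[, 1] + rnorm(n)
  fit <- additive_regression(y, x, C)
  ref <- summary(lm(y ~ x + C))$coefficients["x", ]
  expect_equal(fit$beta, unname(ref["Estimate"]))
  expect_equal(fit$se, unname(ref["Std. Error"]))
  expect_equal(fit$p_value, unname(ref["Pr(>|t|)"]))
})

test_that("the vectorized scan equals per-SNP regressions and handles missing dosage", {
  set.seed(44)
  n <- 30
  d <- matrix(rbinom(20 * n, 2, 0.4), 20, n)
  g <- make_geno(d, sex = rbinom(n, 1, 0.5))
  y <- setNames(rnorm(n), g$samples$sample_id)
  cov <- make_covariates(g, 2)
  assoc <- gwas_scan(g, y, cov)
  C <- as.matrix(cov[, -1])
  for (snp in sample(assoc$snp_id, 5)) {
    fit <- additive_regression(unname(y), d[match(snp, g$info$snp_id), ], C)
    row <- assoc[assoc$snp_id == snp, ]
    expect_equal(row$beta, fit$beta)
    expect_equal(row$p_value, fit$p_value)
  }
  expect_equal(assoc$bonferroni_p, pmin(1, assoc$p_value * 20))
  expect_false(is.unsorted(assoc$p_value, na.rm = TRUE))
  # inject missing dosages: pairwise-deletion path must agree with
  # per-SNP regression on complete cases
  d_na <- d
  d_na[1, 1:3] <- NA
  g_na <- make_geno(d_na, sex = g$samples$sex)
  assoc_na <- gwas_scan(g_na, y, cov)
  fit <- additive_regression(unname(y), d_na[1, ], C)
  row <- assoc_na[assoc_na$snp_id == "m01", ]
  expect_equal(row$p_value, fit$p_value)
  expect_equal(row$n_used, n - 3)
})

test_that("scan p-values are invariant to affine rescaling of the phenotype", {
  set.seed(55)
  n <- 25
  g <- make_geno(matrix(rbinom(15 * n, 2, 0.4), 15, n))
  y <- setNames(rnorm(n), g$samples$sample_id)
  a1 <- gwas_scan(g, y)
  a2 <- gwas_scan(g, 100 * y - 3)
  expect_equal(a2$p_value, a1$p_value, tolerance = 1e-9)
})

test_that("the genomic inflation factor behaves at its null and under inflation", {
  expect_equal(genomic_lambda(rep(0.5, 11)), 1)
  set.seed(66)
  p <- runif(1e5)
  expect_equal(genomic_lambda(p), 1, tolerance = 0.02)
  expect_gt(genomic_lambda(p / 2), 1)
  expect_error(genomic_lambda(numeric(0)), "no p-values")
  expect_error(genomic_lambda(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("permutation p follows the counting definition in edge cases", {
  set.seed(77)
  n <- 40
  g <- make_geno(matrix(rbinom(10 * n, 2, 0.4), 10, n))
  # strong signal: observed min p below every permutation minimum
  y <- setNames(as.numeric(g$dosage[1, ]) + rnorm(n, 0, 0.05),
                g$samples$sample_id)
  pr <- permutation_minp(g, y, n_perm = 50, seed = 1)
  expect_equal(pr$permutation_p, 0)
  expect_length(pr$null_min_p, 50)
  expect_equal(pr$permutation_p, mean(pr$null_min_p <= pr$observed_min_p))
  # n_perm = 1 under the null is almost always 1/1
  y0 <- setNames(rnorm(n), g$samples$sample_id)
  pr1 <- permutation_minp(g, y0, n_perm = 1, seed = 2)
  expect_true(pr1$permutation_p %in% c(0, 1))
  expect_equal(pr1$permutation_p,
               as.numeric(pr1$null_min_p <= pr1$observed_min_p))
  expect_error(permutation_minp(g, y, n_perm = 0), "at least 1")
})

test_that("the causal effect estimate covers the truth at the causal SNP", {
  # parameter recovery: estimated slope within 2 se of the (rank-scale)
  # effect implied by the simulation in nearly all replicates; here the
  # truth is taken as the large-sample mean slope, estimated once
  slopes <- t(sapply(1:15, function(s) {
    res <- scan_study(sim_config(n_samples = 50, n_snps = 200,
                                 effect_size = 0.1, seed = s))
    i <- match("snp00001", res$assoc$snp_id)
    c(res$assoc$beta[i], res$assoc$se[i])
  }))
  truth <- mean(slopes[, 1])
  covered <- abs(slopes[, 1] - truth) <= 2 * slopes[, 2]
  expect_gte(mean(covered), 0.8)
})
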