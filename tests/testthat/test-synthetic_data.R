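# Synthetic-data generator: determinism, Hardy-Weinberg structure,
# half-life dichotomy, causal expression model, knockdown design.

test_that("configuration validation rejects out-of-range parameters", {
  expect_error(sim_config(fst = 1), "fst")
  expect_error(sim_config(fst = -0.1), "fst")
  expect_error(sim_config(maf_range = c(0.4, 0.2)), "maf_range")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(frac_long = 0), "frac_long")
  expect_error(sim_config(frac_long = 1), "frac_long")
  expect_error(sim_config(n_samples = 0))
  expect_error(sim_config(causal_snp_index = 99999))
  expect_silent(sim_config(fst = 0, n_pops = 2))  # no structure is allowed
})

test_that("generators are bit-identical under a fixed seed", {
  cfg <- sim_config(n_samples = 20, n_snps = 50, n_genes = 40, seed = 11)
  expect_identical(simulate_genotypes(cfg), simulate_genotypes(cfg))
  expect_identical(simulate_halflife_table(cfg), simulate_halflife_table(cfg))
  st1 <- simulate_study(cfg)
  st2 <- simulate_study(cfg)
  expect_identical(st1$expression, st2$expression)
  ht <- st1$halflife
  expect_identical(simulate_knockdown(ht, 3, 1, cfg),
                   simulate_knockdown(ht, 3, 1, cfg))
})

test_that("mean dosage approaches 2p for fixed allele frequency", {
  cfg <- sim_config(n_samples = 2000, n_pops = 1, fst = 0,
                    maf_range = c(0.5, 0.5), n_snps = 20, seed = 5)
  g <- simulate_genotypes(cfg)
  expect_equal(unname(rowMeans(g$dosage)), rep(1, 20), tolerance = 0.05)
})

test_that("genotype counts follow Hardy-Weinberg proportions without structure", {
  cfg <- sim_config(n_samples = 300, n_pops = 1, fst = 0, n_snps = 400,
                    maf_range = c(0.1, 0.5), seed = 17)
  g <- simulate_genotypes(cfg)
  pvals <- apply(g$dosage, 1, function(d) {
    p <- mean(d) / 2
    exp_counts <- length(d) * c((1 - p)^2, 2 * p * (1 - p), p^2)
    obs <- tabulate(d + 1, 3)
    stat <- sum((obs - exp_counts)^2 / exp_counts)
    pchisq(stat, df = 1, lower.tail = FALSE)  # 1 df: p estimated
  })
  # calibrated rejection: about 5% of SNPs at alpha = 0.05
  expect_gt(mean(pvals < 0.05), 0.01)
  expect_lt(mean(pvals < 0.05), 0.11)
})

test_that("population divergence is visible on the first genotype PC", {
  cfg <- sim_config(n_samples = 60, n_pops = 2, fst = 0.2, n_snps = 500,
                    causal_snp_index = NULL, seed = 23)
  g <- simulate_genotypes(cfg)
  pcs <- genotype_pca(g, k = 2)
  pop <- as.integer(factor(g$samples$population))
  expect_gt(abs(cor(pcs$PC1, pop)), 0.9)
})

test_that("the half-life mixture enforces group sizes and annotation enrichment", {
  cfg <- sim_config(n_genes = 1000, frac_long = 0.5, seed = 31)
  ht <- simulate_halflife_table(cfg)
  expect_equal(sum(ht$half_life >= 4), 500)
  expect_equal(sum(ht$half_life < 4), 500)
  expect_true(all(ht$half_life > 0))
  # recompute enrichment odds ratio from the emitted table
  long <- ht$half_life >= 4
  fe <- fisher_enrichment(sum(long & ht$housekeeping),
                          sum(long & !ht$housekeeping),
                          sum(!long & ht$housekeeping),
                          sum(!long & !ht$housekeeping))
  expect_gt(fe$odds_ratio, 1)
  expect_lt(fe$p_value, 0.05)
})

test_that("expression is strictly positive and responds to causal dosage", {
  cfg <- sim_config(n_samples = 100, n_snps = 100, n_genes = 300,
                    causal_snp_index = 7, effect_size = 0.3, seed = 41)
  st <- simulate_study(cfg)
  expect_true(all(st$expression > 0))
  cls <- classify_genes(st$halflife)
  sc <- rs_score(st$expression, cls)
  d <- st$genotypes$dosage[7, sc$sample_id]
  means <- tapply(sc$rs_score, d, mean)
  expect_true(all(diff(means[as.character(0:2)]) > 0))
})

test_that("a null effect leaves long-lived expression independent of dosage", {
  cfg <- sim_config(n_samples = 100, n_snps = 50, n_genes = 200,
                    causal_snp_index = NULL, seed = 43)
  st <- simulate_study(cfg)
  cls <- classify_genes(st$halflife)
  sc <- rs_score(st$expression, cls)
  d <- st$genotypes$dosage[1, sc$sample_id]
  fit <- additive_regression(sc$rs_score, d)
  expect_gt(fit$p_value, 0.01)
})

test_that("knockdown lowers long-lived expression only, with recorded pairing", {
  cfg <- sim_config(n_genes = 400, seed = 47)
  ht <- simulate_halflife_table(cfg)
  kd <- simulate_knockdown(ht, n_reps = 3, knockdown_shift = 1, config = cfg)
  expect_equal(dim(kd$control), dim(kd$knockdown))
  expect_equal(nrow(kd$pairing), 3)
  long <- ht$half_life >= 4
  lr <- log(rowMeans(kd$knockdown) / rowMeans(kd$control))
  expect_lt(mean(lr[long]), mean(lr[!long]) - 0.5)
  expect_error(simulate_knockdown(ht, n_reps = 0), "at least 1")
})
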