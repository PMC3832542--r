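# Gene classification and the per-sample stability score.

test_that("half-life classification applies the inclusive 4 h boundary", {
  ht <- data.frame(gene_id = c("a", "b", "c"),
                   half_life = c(4.0, 3.99, 10))
  cls <- classify_genes(ht, "half_life_threshold", threshold = 4)
  expect_equal(cls$group[cls$gene_id == "a"], "long")
  expect_equal(cls$group[cls$gene_id == "b"], "short")
  expect_equal(cls$group[cls$gene_id == "c"], "long")
})

test_that("decay-rate classification splits at the mean with low decay = long", {
  ht <- data.frame(gene_id = paste0("g", 1:4),
                   relative_decay_rate = c(-1, -0.5, 0.2, 1.3))
  cls <- classify_genes(ht, "decay_rate_mean")
  expect_equal(cls$group, c("long", "long", "short", "short"))
  flipped <- classify_genes(ht, "decay_rate_mean", long_is_low_decay = FALSE)
  expect_equal(flipped$group, c("short", "short", "long", "long"))
})

test_that("classification rejects degenerate tables and drops missing values", {
  expect_error(classify_genes(data.frame(gene_id = "a", half_life = 9),
                              "half_life_threshold"),
               "one group")
  ht <- data.frame(gene_id = c("a", "b", "c"),
                   half_life = c(8, NA, 1))
  expect_message(cls <- classify_genes(ht, "half_life_threshold"), "1 genes")
  expect_equal(nrow(cls), 2)
})

test_that("housekeeping and coding schemes use their flags directly", {
  ht <- data.frame(gene_id = paste0("g", 1:4),
                   housekeeping = c(TRUE, FALSE, TRUE, FALSE),
                   biotype = c("coding", "coding", "non-coding", "non-coding"))
  expect_equal(classify_genes(ht, "housekeeping")$group,
               c("long", "short", "long", "short"))
  expect_equal(classify_genes(ht, "coding")$group,
               c("long", "long", "short", "short"))
})

test_that("expression ranks ascend with expression and average over ties", {
  expect_equal(rank_expression(c(5, 3, 2, 1)), c(4, 3, 2, 1))
  expect_equal(rank_expression(c(2, 2, 1)), c(2.5, 2.5, 1))
  expect_equal(rank_expression(rep(7, 5)), rep(3, 5))
  expect_error(rank_expression(numeric(0)), "empty")
  expect_error(rank_expression(c(1, NA)), "finite")
})

test_that("the worked 4-gene example scores exactly 2", {
  w <- worked_example()
  expect_equal(rs_score(w$expr, w$cls)$rs_score, 2.0)
})

test_that("scores equal the brute-force sort-and-average oracle", {
  set.seed(101)
  for (i in 1:50) {
    n_genes <- sample(4:50, 1)
    n_samples <- sample(1:10, 1)
    f <- random_classified_matrix(n_genes, n_samples)
    got <- rs_score(f$expr, f$cls)$rs_score
    expect_equal(got, brute_rs_score(f$expr, f$long_ids, f$short_ids))
  }
})

test_that("score magnitude is bounded by N/2, attained iff groups separate", {
  # exhaustive over orderings of 3 long + 3 short genes
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 6), ]
  f <- random_classified_matrix(6, 1, n_long = 3)
  for (i in seq_len(nrow(perms))) {
    expr <- matrix(perms[i, ], ncol = 1,
                   dimnames = list(f$cls$gene_id, "s1"))
    sc <- rs_score(expr, f$cls)$rs_score
    expect_lte(abs(sc), 3)
    separated <- min(expr[f$long_ids, 1]) > max(expr[f$short_ids, 1]) ||
      max(expr[f$long_ids, 1]) < min(expr[f$short_ids, 1])
    expect_equal(abs(sc) == 3, separated)
  }
})

test_that("scores are invariant to strictly increasing transformations", {
  set.seed(202)
  f <- random_classified_matrix(30, 5)
  base <- rs_score(f$expr, f$cls)$rs_score
  expect_equal(rs_score(exp(f$expr), f$cls)$rs_score, base)
  expect_equal(rs_score(f$expr^3 + 2 * f$expr, f$cls)$rs_score, base)
})

test_that("raising long-lived expression in one sample never lowers its score", {
  set.seed(303)
  for (i in 1:20) {
    f <- random_classified_matrix(25, 1)
    base <- rs_score(f$expr, f$cls)$rs_score
    shifted <- f$expr
    shifted[f$long_ids, 1] <- exp(log(shifted[f$long_ids, 1]) + runif(1, 0, 2))
    expect_gte(rs_score(shifted, f$cls)$rs_score, base)
  }
})

test_that("scoring errors name the missing group", {
  w <- worked_example()
  expr_short_only <- w$expr[3:4, , drop = FALSE]
  expect_error(rs_score(expr_short_only, w$cls), "long")
  expr_long_only <- w$expr[1:2, , drop = FALSE]
  expect_error(rs_score(expr_long_only, w$cls), "short")
})

test_that("score agreement reproduces hand-computed Spearman correlations", {
  a <- data.frame(sample_id = paste0("s", 1:4), rs_score = c(1, 2, 3, 4))
  b <- data.frame(sample_id = paste0("s", 1:4), rs_score = c(1, 2, 4, 3))
  expect_equal(score_agreement(a, a), 1)
  neg <- a
  neg$rs_score <- -a$rs_score
  expect_equal(score_agreement(a, neg), -1)
  expect_equal(score_agreement(a, b), 0.8)  # 1 - 6*2/(4*15)
  expect_error(score_agreement(a[1:2, ], b), "3 shared")
})
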