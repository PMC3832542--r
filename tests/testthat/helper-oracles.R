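# Independent oracles used across tests. These deliberately avoid the
# package's own code paths (and base rank()) so they can serve as
# brute-force references.

# average rank of each element, by direct counting
brute_rank <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, numeric(1))
}

# stability score by explicit sort-and-average per sample
brute_rs_score <- function(expr, long_ids, short_ids) {
  ids <- c(long_ids, short_ids)
  vapply(seq_len(ncol(expr)), function(j) {
    r <- brute_rank(expr[ids, j])
    names(r) <- ids
    mean(r[long_ids]) - mean(r[short_ids])
  }, numeric(1))
}

# closed-form simple OLS slope test (no covariates)
brute_ols <- function(y, x) {
  n <- length(y)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  alpha <- mean(y) - beta * mean(x)
  rss <- sum((y - alpha - beta * x)^2)
  se <- sqrt(rss / (n - 2) / sum((x - mean(x))^2))
  t_stat <- beta / se
  list(beta = beta, se = se, t_stat = t_stat,
       p_value = 2 * pt(abs(t_stat), n - 2, lower.tail = FALSE))
}

# Benjamini-Hochberg step-up by the literal construction
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# one-way ANOVA F from between/within sums of squares
brute_anova_F <- function(values, groups) {
  groups <- factor(groups)
  grand <- mean(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  dfb <- nlevels(groups) - 1
  dfw <- length(values) - nlevels(groups)
  (ssb / dfb) / (ssw / dfw)
}

# small classified expression fixture: genes g1..g4, worked example column
worked_example <- function() {
  expr <- matrix(c(5, 3, 2, 1), ncol = 1,
                 dimnames = list(c("g1", "g2", "g3", "g4"), "s1"))
  cls <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                    group = c("long", "long", "short", "short"),
                    scheme = "half_life_threshold", stringsAsFactors = FALSE)
  class(cls) <- c("gene_classification", "data.frame")
  list(expr = expr, cls = cls)
}

random_classified_matrix <- function(n_genes, n_samples, n_long = NULL) {
  if (is.null(n_long)) n_long <- sample(1:(n_genes - 1), 1)
  expr <- matrix(rexp(n_genes * n_samples), n_genes, n_samples,
                 dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                 sprintf("s%03d", seq_len(n_samples))))
  cls <- data.frame(gene_id = rownames(expr),
                    group = c(rep("long", n_long),
                              rep("short", n_genes - n_long)),
                    scheme = "half_life_threshold", stringsAsFactors = FALSE)
  class(cls) <- c("gene_classification", "data.frame")
  list(expr = expr, cls = cls,
       long_ids = rownames(expr)[seq_len(n_long)],
       short_ids = rownames(expr)[-seq_len(n_long)])
}

# run the standard analysis chain on a simulated study
scan_study <- function(config, n_pcs = 5) {
  st <- simulate_study(config)
  cls <- classify_genes(st$halflife)
  scores <- rs_score(st$expression, cls)
  g <- maf_filter(st$genotypes)
  cov <- make_covariates(g, n_pcs)
  list(study = st, cls = cls, scores = scores, genotypes = g,
       covariates = cov, assoc = gwas_scan(g, scores, cov))
}
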