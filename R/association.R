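# Genome-wide association of the stability score: MAF filter, genotype PCA
# (Patterson normalization), additive OLS per SNP, genomic inflation factor,
# and min-p permutation significance.

#' Filter SNPs by minor allele frequency
#'
#' MAF is computed from non-missing dosages within the current cohort
#' (folded frequency), so the filter is analysis-cohort-relative. SNPs with
#' MAF less than or equal to the threshold are excluded — i.e. a SNP at
#' exactly the threshold is removed, and monomorphic SNPs always are.
#'
#' @param genotypes a [genotype_matrix()].
#' @param threshold frequency in \[0, 0.5); default 0.01.
#' @return the filtered `genotype_matrix`.
#' @export
maf_filter <- function(genotypes, threshold = 0.01) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (!(threshold >= 0 && threshold < 0.5)) stop("threshold must lie in [0, 0.5)")
  maf <- snp_maf(genotypes)
  keep <- !is.na(maf) & maf > threshold
  if (!any(keep)) stop("MAF filter removed every SNP")
  subset_genotypes(genotypes, snps = which(keep))
}

#' Principal components of the genotype matrix
#'
#' Each SNP row is mean-centered and scaled by `sqrt(p(1-p))` with
#' `p = (1 + sum of dosages) / (2 + 2n)`, the posterior allele-frequency
#' estimate of the Patterson/Eigensoft normalization; missing dosages are
#' mean-imputed before scaling. The top-k sample coordinates are returned in
#' decreasing eigenvalue order. The sign of each component is arbitrary.
#'
#' @param genotypes a [genotype_matrix()].
#' @param k number of components (>= 1, at most min(samples, SNPs), and
#'   fewer than the number of samples).
#' @return data.frame with `sample_id` and columns `PC1..PCk`; eigenvalues
#'   are attached as attribute `"eigenvalues"`.
#' @export
genotype_pca <- function(genotypes, k = 5) {
  stopifnot(inherits(genotypes, "genotype_matrix"), k >= 1)
  X <- genotypes$dosage
  m <- nrow(X)
  n <- ncol(X)
  if (k > min(n, m)) stop("k exceeds min(number of samples, number of SNPs)")
  if (n < k + 1) stop("need at least k + 1 samples")

  nn <- rowSums(!is.na(X))
  p_hat <- (1 + rowSums(X, na.rm = TRUE)) / (2 + 2 * nn)
  mu <- rowMeans(X, na.rm = TRUE)
  if (anyNA(X)) {
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 1]]
  }
  Xn <- (X - mu) / sqrt(p_hat * (1 - p_hat))

  sv <- svd(t(Xn), nu = k, nv = 0)
  scores <- sv$u * rep(sv$d[seq_len(k)], each = n)
  colnames(scores) <- paste0("PC", seq_len(k))
  out <- data.frame(sample_id = genotypes$samples$sample_id, scores,
                    stringsAsFactors = FALSE)
  attr(out, "eigenvalues") <- sv$d[seq_len(k)]^2 / max(1, n - 1)
  out
}

#' Build the default covariate set (sex plus genotype PCs)
#'
#' @param genotypes a [genotype_matrix()] whose `samples` carry a `sex`
#'   column coded 0/1.
#' @param n_pcs number of genotype principal components to include (0 for
#'   sex only).
#' @return data.frame with `sample_id`, `sex` and `PC1..PCk`.
#' @export
make_covariates <- function(genotypes, n_pcs = 5) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  samp <- genotypes$samples
  if (is.null(samp$sex)) stop("genotype samples carry no 'sex' column")
  out <- data.frame(sample_id = samp$sample_id, sex = samp$sex,
                    stringsAsFactors = FALSE)
  if (n_pcs > 0) {
    pcs <- genotype_pca(genotypes, k = n_pcs)
    out <- cbind(out, pcs[, -1, drop = FALSE])
  }
  out
}

# covariate data.frame -> numeric model matrix (no intercept), aligned to ids
.covariate_matrix <- function(covariates, sample_ids) {
  if (is.null(covariates)) {
    return(matrix(numeric(0), nrow = length(sample_ids), ncol = 0))
  }
  stopifnot(is.data.frame(covariates), "sample_id" %in% names(covariates))
  idx <- match(sample_ids, covariates$sample_id)
  if (anyNA(idx)) stop("covariates missing for some samples")
  C <- as.matrix(covariates[idx, setdiff(names(covariates), "sample_id"),
                            drop = FALSE])
  storage.mode(C) <- "double"
  C
}

.phenotype_vector <- function(phenotype) {
  if (inherits(phenotype, "rs_score") ||
      (is.data.frame(phenotype) && all(c("sample_id", "rs_score") %in% names(phenotype)))) {
    stats::setNames(phenotype$rs_score, phenotype$sample_id)
  } else if (is.numeric(phenotype)) {
    phenotype
  } else {
    stop("phenotype must be an rs_score data.frame or a (named) numeric vector")
  }
}

#' Additive single-SNP regression
#'
#' Ordinary least squares of the phenotype on minor-allele dosage with an
#' intercept and optional covariates; the returned test concerns the dosage
#' coefficient, with a two-sided p-value from the t distribution on
#' residual degrees of freedom. Samples with missing dosage are dropped
#' pairwise. Degenerate fits are flagged rather than given silent p-values:
#' `"constant_dosage"` when dosage has no variance after missing-data
#' removal (p undefined), `"zero_residual"` for an exact fit (se = 0).
#'
#' @param phenotype numeric vector of per-sample scores.
#' @param dosage numeric vector of dosages in \{0, 1, 2\} (NA allowed),
#'   aligned with `phenotype`.
#' @param covariates optional numeric matrix (or data.frame of numeric
#'   columns) of covariates aligned with `phenotype`, without intercept.
#' @return list with `beta`, `se`, `t_stat`, `p_value`, `n_used`, `flag`
#'   (`NA` when the fit is regular).
#' @export
additive_regression <- function(phenotype, dosage, covariates = NULL) {
  stopifnot(length(phenotype) == length(dosage))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == length(phenotype))
  }
  keep <- !is.na(dosage) & !is.na(phenotype)
  y <- phenotype[keep]
  x <- dosage[keep]
  n <- length(y)
  C <- if (is.null(covariates)) NULL else covariates[keep, , drop = FALSE]

  if (n == 0 || stats::var(x) == 0) {
    return(list(beta = NA_real_, se = NA_real_, t_stat = NA_real_,
                p_value = NA_real_, n_used = n, flag = "constant_dosage"))
  }
  X <- cbind(`(Intercept)` = 1, dosage = x, C)
  qr_fit <- qr(X)
  df <- n - qr_fit$rank
  if (df < 1) stop("fewer than 1 residual degree of freedom")
  XtXinv <- tryCatch(solve(crossprod(X)), error = function(e) NULL)
  if (is.null(XtXinv) || qr_fit$rank < ncol(X)) {
    return(list(beta = NA_real_, se = NA_real_, t_stat = NA_real_,
                p_value = NA_real_, n_used = n, flag = "collinear"))
  }
  coefs <- qr.coef(qr_fit, y)
  res <- y - X %*% coefs
  rss <- sum(res^2)
  XtXinv_dd <- XtXinv[2, 2]
  beta <- unname(coefs["dosage"])
  if (rss < .Machine$double.eps * max(1, sum(y^2))) {
    return(list(beta = beta, se = 0, t_stat = NA_real_, p_value = NA_real_,
                n_used = n, flag = "zero_residual"))
  }
  sigma2 <- rss / df
  se <- sqrt(sigma2 * XtXinv_dd)
  t_stat <- beta / se
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  list(beta = beta, se = se, t_stat = t_stat, p_value = p, n_used = n,
       flag = NA_character_)
}

# Vectorized scan core: residualize phenotype and dosages on the covariate
# space (Frisch-Waugh), then per-SNP slope tests. G must have no missing
# values. Returns per-SNP beta/se/t/p plus the residual pieces needed to
# rescore permuted phenotypes cheaply.
.scan_core <- function(G, y, C) {
  n <- length(y)
  Cfull <- cbind(1, C)
  qrC <- qr(Cfull)
  Q <- qr.Q(qrC)
  df <- n - qrC$rank - 1L
  if (df < 1) stop("fewer than 1 residual degree of freedom")
  yr <- drop(y - Q %*% crossprod(Q, y))
  Gr <- G - (G %*% Q) %*% t(Q)
  xx <- rowSums(Gr^2)
  xy <- drop(Gr %*% yr)
  yy <- sum(yr^2)
  const <- xx < n * .Machine$double.eps
  beta <- ifelse(const, NA_real_, xy / xx)
  rss <- pmax(yy - beta * xy, 0)
  sigma2 <- rss / df
  se <- sqrt(sigma2 / xx)
  t_stat <- beta / se
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  p[const] <- NA_real_
  list(beta = beta, se = se, t_stat = t_stat, p_value = p,
       df = df, Q = Q, Gr = Gr, xx = xx, const = const, n = n)
}

#' Genome-wide association scan of a quantitative stability phenotype
#'
#' Runs one additive regression per SNP (intercept + dosage + covariates),
#' reporting effect size, standard error, t statistic, two-sided p-value
#' and Bonferroni-adjusted p-value with m equal to the number of SNPs in
#' this scan. Rows are sorted by p-value ascending. Genotypes should
#' already be MAF-filtered for the analysis cohort.
#'
#' @param genotypes a [genotype_matrix()].
#' @param phenotype an `rs_score` data.frame or named numeric vector.
#' @param covariates optional data.frame with `sample_id` plus numeric
#'   covariate columns (e.g. from [make_covariates()]).
#' @return data.frame of class `association_table` with columns `snp_id`,
#'   `chrom`, `pos`, `maf`, `beta`, `se`, `t_stat`, `p_value`, `n_used`,
#'   `bonferroni_p`, `flag`.
#' @export
gwas_scan <- function(genotypes, phenotype, covariates = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  y_named <- .phenotype_vector(phenotype)
  if (is.null(names(y_named))) stop("phenotype must carry sample identifiers")
  shared <- intersect(colnames(genotypes$dosage), names(y_named))
  if (length(shared) == 0) stop("no overlapping samples between genotypes and phenotype")
  g <- subset_genotypes(genotypes, samples = shared)
  y <- unname(y_named[shared])
  C <- .covariate_matrix(covariates, shared)
  G <- g$dosage
  storage.mode(G) <- "double"
  m <- nrow(G)
  maf <- snp_maf(g)

  if (!anyNA(G)) {
    core <- .scan_core(G, y, C)
    res <- data.frame(
      snp_id = g$info$snp_id, chrom = g$info$chrom, pos = g$info$pos,
      maf = maf, beta = core$beta, se = core$se, t_stat = core$t_stat,
      p_value = core$p_value, n_used = core$n,
      flag = ifelse(core$const, "constant_dosage", NA_character_),
      stringsAsFactors = FALSE
    )
  } else {
    fits <- lapply(seq_len(m), function(j) {
      additive_regression(y, G[j, ], if (ncol(C)) C else NULL)
    })
    res <- data.frame(
      snp_id = g$info$snp_id, chrom = g$info$chrom, pos = g$info$pos,
      maf = maf,
      beta = vapply(fits, `[[`, numeric(1), "beta"),
      se = vapply(fits, `[[`, numeric(1), "se"),
      t_stat = vapply(fits, `[[`, numeric(1), "t_stat"),
      p_value = vapply(fits, `[[`, numeric(1), "p_value"),
      n_used = vapply(fits, `[[`, numeric(1), "n_used"),
      flag = vapply(fits, `[[`, character(1), "flag"),
      stringsAsFactors = FALSE
    )
  }
  res$bonferroni_p <- pmin(1, res$p_value * m)
  res <- res[order(res$p_value), ]
  rownames(res) <- NULL
  attr(res, "n_snps_tested") <- m
  class(res) <- c("association_table", "data.frame")
  res
}

#' Genomic inflation factor
#'
#' lambda = median of the 1-df chi-square statistics implied by the
#' p-values, divided by the null median 0.4549364. Values near 1 indicate
#' no systematic inflation; lambda above about 1.05 is the conventional
#' warning sign of population stratification.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return lambda (scalar).
#' @export
genomic_lambda <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (length(p_values) == 0) stop("no p-values supplied")
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must lie in (0, 1]")
  chisq <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Permutation-based genome-wide significance (min-p null)
#'
#' Shuffles the phenotype values across samples (covariates stay attached
#' to their samples), re-runs the scan, and records the lowest p-value of
#' each permuted scan. The permutation p-value is the proportion of
#' permutation minima less than or equal to the observed minimum p-value;
#' the estimator admits an exact zero, reported as `< 1/n_perm` in
#' human-readable summaries while the raw count is kept.
#'
#' @param genotypes a MAF-filtered [genotype_matrix()] without missing
#'   dosages (the batched permutation path requires complete dosages).
#' @param phenotype an `rs_score` data.frame or named numeric vector.
#' @param covariates optional covariate data.frame as in [gwas_scan()].
#' @param n_perm number of permutations (>= 1; 1000 in a full analysis).
#' @param seed integer seed for the shuffles.
#' @return object of class `permutation_result`: list with
#'   `observed_min_p`, `null_min_p` (length `n_perm`), `permutation_p`,
#'   `n_perm`, `seed`.
#' @export
permutation_minp <- function(genotypes, phenotype, covariates = NULL,
                             n_perm = 1000, seed = 1) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  stopifnot(inherits(genotypes, "genotype_matrix"))
  y_named <- .phenotype_vector(phenotype)
  shared <- intersect(colnames(genotypes$dosage), names(y_named))
  if (length(shared) == 0) stop("no overlapping samples between genotypes and phenotype")
  g <- subset_genotypes(genotypes, samples = shared)
  if (anyNA(g$dosage)) {
    stop("permutation_minp requires complete dosages; impute or drop missing SNPs first")
  }
  y <- unname(y_named[shared])
  C <- .covariate_matrix(covariates, shared)
  G <- g$dosage
  storage.mode(G) <- "double"
  n <- length(y)

  core <- .scan_core(G, y, C)
  observed_min_p <- min(core$p_value, na.rm = TRUE)

  set.seed(seed)
  Y <- vapply(seq_len(n_perm), function(b) y[sample.int(n)], numeric(n))
  Yr <- Y - core$Q %*% crossprod(core$Q, Y)
  XY <- core$Gr %*% Yr                        # m x n_perm
  yy <- colSums(Yr^2)
  ok <- !core$const
  r2 <- sweep(XY[ok, , drop = FALSE]^2 / core$xx[ok], 2, yy, "/")
  r2max <- apply(r2, 2, max)
  r2max <- pmin(r2max, 1 - .Machine$double.eps)
  tmax <- sqrt(core$df * r2max / (1 - r2max))
  null_min_p <- 2 * stats::pt(tmax, core$df, lower.tail = FALSE)

  res <- list(observed_min_p = observed_min_p,
              null_min_p = null_min_p,
              permutation_p = mean(null_min_p <= observed_min_p),
              n_perm = as.integer(n_perm), seed = as.integer(seed))
  class(res) <- "permutation_result"
  res
}

#' @export
print.permutation_result <- function(x, ...) {
  p_str <- if (x$permutation_p == 0) {
    sprintf("< %g (0 of %d permutation minima at or below the observed)",
            1 / x$n_perm, x$n_perm)
  } else {
    format(x$permutation_p)
  }
  cat(sprintf("min-p permutation test: observed min p = %g\n", x$observed_min_p))
  cat(sprintf("  permutation p = %s [n_perm = %d, seed = %d]\n",
              p_str, x$n_perm, x$seed))
  invisible(x)
}
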