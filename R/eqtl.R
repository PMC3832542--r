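# cis/trans eQTL mapping by Spearman rank correlation with BH FDR control,
# and 2x2 Fisher enrichment for associated-gene sets.

#' Spearman association between dosage and expression
#'
#' Tie-corrected Spearman rho (Pearson correlation of average ranks) with a
#' two-sided p-value from the t approximation on n - 2 degrees of freedom.
#'
#' @param dosage per-sample dosages in \{0, 1, 2\}.
#' @param expression per-sample expression values, aligned with `dosage`.
#' @return list with `rho`, `p_value`, `n`, and `flag`
#'   (`"constant_input"` with undefined rho when either vector is constant).
#' @export
spearman_assoc <- function(dosage, expression) {
  stopifnot(length(dosage) == length(expression))
  keep <- !is.na(dosage) & !is.na(expression)
  x <- dosage[keep]
  y <- expression[keep]
  n <- length(x)
  if (n < 4) stop("need at least 4 shared samples")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                flag = "constant_input"))
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- .spearman_p(rho, n)
  list(rho = rho, p_value = p, n = n, flag = NA_character_)
}

.spearman_p <- function(rho, n) {
  r2 <- pmin(rho^2, 1)
  t_stat <- abs(rho) * sqrt((n - 2) / pmax(1 - r2, 0))
  2 * stats::pt(t_stat, n - 2, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: sorted ascending, `q_i = p_i * m / i`, made
#' monotone from the largest down, capped at 1, returned in input order.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return adjusted p-values (same length and order).
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) stop("no p-values supplied")
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Trans-eQTL scan of one SNP against an expression matrix
#'
#' Runs [spearman_assoc()] of the SNP's dosage against every gene, adjusts
#' the p-values by [bh_fdr()] over all genes tested, and flags rows below
#' the FDR threshold as associated. The sign of rho is retained so the
#' subset of genes positively correlated with minor-allele dosage is
#' recoverable.
#'
#' @param dosage named per-sample dosage vector for the SNP.
#' @param expr genes x samples expression matrix.
#' @param fdr_threshold FDR cutoff for the associated flag; default 0.1.
#' @return data.frame of class `eqtl_table`: `gene_id`, `rho`, `p_value`,
#'   `fdr`, `associated`, `in_cis` (all `FALSE` here).
#' @export
trans_eqtl_scan <- function(dosage, expr, fdr_threshold = 0.1) {
  if (!is.matrix(expr) || nrow(expr) == 0) stop("empty expression matrix")
  shared <- intersect(names(dosage), colnames(expr))
  if (length(shared) < 4) stop("need at least 4 shared samples")
  d <- dosage[shared]
  if (stats::var(d) == 0) stop("dosage is constant in the shared samples")
  E <- expr[, shared, drop = FALSE]
  n <- length(shared)

  rd <- rank(d)
  R <- t(apply(E, 1, rank))
  rho <- drop(stats::cor(t(R), rd))
  p <- .spearman_p(rho, n)
  constant <- apply(E, 1, stats::var) == 0
  rho[constant] <- NA_real_
  p[constant] <- NA_real_
  fdr <- rep(NA_real_, length(p))
  fdr[!constant] <- bh_fdr(p[!constant])

  out <- data.frame(gene_id = rownames(E), rho = rho, p_value = p, fdr = fdr,
                    associated = !is.na(fdr) & fdr < fdr_threshold,
                    in_cis = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("eqtl_table", "data.frame")
  out
}

#' cis-eQTL scan within a window centered on a SNP
#'
#' A gene is in cis iff it lies on the SNP's chromosome with
#' `|tss_pos - snp_pos| <= window/2` (boundary inclusive; the default 1 Mb
#' window thus spans +/- 500 kb). Each cis gene is tested with
#' [spearman_assoc()]; the minimum-p gene is reported as the candidate cis
#' target via the `"candidate"` attribute.
#'
#' @param snp a one-row data.frame or list with `chrom` and `pos`.
#' @param dosage named per-sample dosage vector for the SNP.
#' @param expr genes x samples expression matrix.
#' @param annot gene annotation data.frame with `gene_id`, `chrom`,
#'   `tss_pos`.
#' @param window window size in bases, default 1e6.
#' @return `eqtl_table` restricted to cis genes (`in_cis = TRUE`), with FDR
#'   over the cis set; empty (with a warning) when no gene falls in the
#'   window.
#' @export
cis_window_scan <- function(snp, dosage, expr, annot, window = 1e6) {
  stopifnot(all(c("gene_id", "chrom", "tss_pos") %in% names(annot)))
  in_cis <- annot$chrom == as.character(snp$chrom) &
    abs(annot$tss_pos - as.numeric(snp$pos)) <= window / 2
  cis_genes <- intersect(annot$gene_id[in_cis], rownames(expr))
  if (length(cis_genes) == 0) {
    warning("no genes in the cis window")
    out <- data.frame(gene_id = character(0), rho = numeric(0),
                      p_value = numeric(0), fdr = numeric(0),
                      associated = logical(0), in_cis = logical(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("eqtl_table", "data.frame")
    return(out)
  }
  out <- trans_eqtl_scan(dosage, expr[cis_genes, , drop = FALSE])
  out$in_cis <- TRUE
  cand <- out$gene_id[which.min(out$p_value)]
  attr(out, "candidate") <- if (length(cand)) cand else NA_character_
  class(out) <- c("eqtl_table", "data.frame")
  out
}

#' Fisher exact enrichment test on a 2x2 table
#'
#' Conditional (hypergeometric) two-sided exact test with the sample odds
#' ratio `ad / bc`. The table rows are (in set, not in set) and columns
#' (with property, without), i.e. `a` = associated genes with the property.
#'
#' @param a,b,c,d non-negative counts of the 2x2 table, row-wise.
#' @return list with `odds_ratio` (`Inf` flagged when `bc = 0` and
#'   `ad > 0`) and `p_value`.
#' @export
fisher_enrichment <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (sum(counts) == 0) stop("all-zero table")
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(tab)$p.value
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else {
    (a * d) / (b * c)
  }
  list(odds_ratio = or, p_value = p)
}
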