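# Knockdown comparisons: paired and two-sample tests on stability scores,
# group-wise expression-shift tests, and score-by-genotype ANOVA.

#' Paired t test on replicate stability scores
#'
#' Two-sided paired t test on treated minus control score differences.
#' Zero-variance differences are flagged (p undefined) rather than given a
#' p-value.
#'
#' @param scores data.frame with one row per replicate and columns
#'   `control_score` and `treated_score` (a `replicate_id` column is
#'   carried along if present).
#' @return list with `mean_difference`, `t_stat`, `p_value`, `df`, `flag`.
#' @export
paired_score_test <- function(scores) {
  stopifnot(all(c("control_score", "treated_score") %in% names(scores)))
  d <- scores$treated_score - scores$control_score
  if (length(d) < 2) stop("need at least 2 replicates")
  if (stats::sd(d) == 0) {
    return(list(mean_difference = mean(d), t_stat = NA_real_,
                p_value = NA_real_, df = length(d) - 1L,
                flag = "zero_variance"))
  }
  fit <- stats::t.test(d)
  list(mean_difference = mean(d), t_stat = unname(fit$statistic),
       p_value = fit$p.value, df = unname(fit$parameter),
       flag = NA_character_)
}

#' Two-sample t test on stability scores
#'
#' Two-sided t test comparing score replicates between two conditions,
#' pooled variance by default.
#'
#' @param a,b numeric vectors of score replicates (each of length >= 2).
#' @param var_equal pool the variance (default `TRUE`).
#' @return list with `mean_difference` (a - b), `t_stat`, `p_value`, `df`,
#'   `flag` (`"zero_variance"` when both groups are constant).
#' @export
two_sample_score_test <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs at least 2 values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(list(mean_difference = mean(a) - mean(b), t_stat = NA_real_,
                p_value = NA_real_, df = NA_real_, flag = "zero_variance"))
  }
  fit <- stats::t.test(a, b, var.equal = var_equal)
  list(mean_difference = mean(a) - mean(b), t_stat = unname(fit$statistic),
       p_value = fit$p.value, df = unname(fit$parameter),
       flag = NA_character_)
}

#' Wilcoxon rank-sum test of group-wise expression shift
#'
#' Computes per-gene log-ratios (natural log) of treated over control
#' expression and compares the log-ratio distributions of long- versus
#' short-lived genes with a two-sided Wilcoxon rank-sum test (exact when
#' both groups have fewer than 20 genes and there are no ties, normal
#' approximation with continuity correction otherwise). The direction
#' reports which group shifted down.
#'
#' @param treated,control named per-gene expression vectors for one matched
#'   replicate pair (strictly positive, matched gene sets).
#' @param cls a [classify_genes()] result.
#' @return list with `p_value`, `statistic` (rank-sum W), `direction`
#'   (`"long_down"`, `"short_down"` or `"none"`), `n_long`, `n_short`,
#'   `flag` (`"degenerate"` when all log-ratios are identical).
#' @export
group_shift_test <- function(treated, control, cls) {
  genes <- intersect(names(treated), names(control))
  if (length(genes) == 0) stop("no matched genes between treated and control")
  lr <- log(treated[genes] / control[genes])
  long_ids <- intersect(genes, cls$gene_id[cls$group == "long"])
  short_ids <- intersect(genes, cls$gene_id[cls$group == "short"])
  if (length(long_ids) < 2 || length(short_ids) < 2) {
    stop("each group needs at least 2 genes")
  }
  x <- lr[long_ids]
  y <- lr[short_ids]
  if (stats::var(c(x, y)) == 0) {
    return(list(p_value = NA_real_, statistic = NA_real_, direction = "none",
                n_long = length(x), n_short = length(y), flag = "degenerate"))
  }
  exact <- length(x) < 20 && length(y) < 20 && !anyDuplicated(c(x, y))
  fit <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  direction <- if (stats::median(x) < stats::median(y)) "long_down"
  else if (stats::median(x) > stats::median(y)) "short_down"
  else "none"
  list(p_value = fit$p.value, statistic = unname(fit$statistic),
       direction = direction, n_long = length(x), n_short = length(y),
       flag = NA_character_)
}

#' One-way ANOVA of a score or expression across genotype classes
#'
#' Fixed-effects one-way ANOVA of the values across the genotype classes
#' (dosage groups 0/1/2) present in the data. With two classes the F
#' statistic equals the square of the equal-variance two-sample t
#' statistic.
#'
#' @param values per-sample score or expression values.
#' @param dosage per-sample dosages in \{0, 1, 2\}, aligned with `values`.
#' @return list with `F_stat`, `p_value`, `df_between`, `df_within`.
#' @export
anova_by_genotype <- function(values, dosage) {
  stopifnot(length(values) == length(dosage))
  keep <- !is.na(values) & !is.na(dosage)
  values <- values[keep]
  g <- factor(dosage[keep])
  if (nlevels(g) < 2) stop("need at least 2 genotype classes")
  fit <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(F_stat = unname(fit$statistic), p_value = fit$p.value,
       df_between = unname(fit$parameter[1]),
       df_within = unname(fit$parameter[2]))
}

#' Stability scores for a paired knockdown experiment
#'
#' Convenience wrapper: computes per-replicate scores for matched control
#' and knockdown expression matrices and assembles the paired score set
#' used by [paired_score_test()].
#'
#' @param control,knockdown genes x replicates expression matrices.
#' @param cls a [classify_genes()] result.
#' @param pairing data.frame with `treated_sample` and `control_sample`
#'   columns (and optionally `replicate_id`); default pairs columns in
#'   order.
#' @return data.frame with `replicate_id`, `control_score`,
#'   `treated_score`.
#' @export
knockdown_scores <- function(control, knockdown, cls, pairing = NULL) {
  if (is.null(pairing)) {
    stopifnot(ncol(control) == ncol(knockdown))
    pairing <- data.frame(replicate_id = sprintf("rep%d", seq_len(ncol(control))),
                          treated_sample = colnames(knockdown),
                          control_sample = colnames(control),
                          stringsAsFactors = FALSE)
  }
  if (is.null(pairing$replicate_id)) {
    pairing$replicate_id <- sprintf("rep%d", seq_len(nrow(pairing)))
  }
  sc <- rs_score(control, cls)
  sk <- rs_score(knockdown, cls)
  data.frame(
    replicate_id = pairing$replicate_id,
    control_score = sc$rs_score[match(pairing$control_sample, sc$sample_id)],
    treated_score = sk$rs_score[match(pairing$treated_sample, sk$sample_id)],
    stringsAsFactors = FALSE
  )
}
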