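# RNA stability score: classify genes into long-/short-lived groups and
# score each sample by the difference in mean expression rank between them.

#' Classify genes into long- and short-lived groups
#'
#' Supported schemes:
#' \describe{
#'   \item{`half_life_threshold`}{long-lived iff `half_life >= threshold`
#'     (default 4 hours; the boundary is inclusive).}
#'   \item{`decay_rate_mean`}{long-lived iff the relative decay rate is below
#'     the mean across genes — lower decay means longer life. Set
#'     `long_is_low_decay = FALSE` to invert the sign convention.}
#'   \item{`housekeeping`}{long-lived := housekeeping flag set; transcripts
#'     of housekeeping genes tend to be stable, so this gives a half-life-free
#'     grouping.}
#'   \item{`coding`}{long-lived := protein-coding biotype; non-coding RNAs
#'     tend to be short-lived.}
#' }
#' Genes with a missing value in the relevant column are dropped with a
#' message stating the count.
#'
#' @param halflife a data.frame with `gene_id` and, depending on the scheme,
#'   `half_life` (hours), `relative_decay_rate`, `housekeeping` (logical) or
#'   `biotype` (`"coding"`/`"non-coding"`).
#' @param scheme classification scheme, see above.
#' @param threshold half-life threshold in hours for `half_life_threshold`.
#' @param long_is_low_decay sign convention for `decay_rate_mean`.
#' @return a data.frame of class `gene_classification` with columns
#'   `gene_id`, `group` (`"long"`/`"short"`) and `scheme`.
#' @export
classify_genes <- function(halflife,
                           scheme = c("half_life_threshold", "decay_rate_mean",
                                      "housekeeping", "coding"),
                           threshold = 4, long_is_low_decay = TRUE) {
  scheme <- match.arg(scheme)
  col <- switch(scheme,
    half_life_threshold = "half_life",
    decay_rate_mean = "relative_decay_rate",
    housekeeping = "housekeeping",
    coding = "biotype"
  )
  if (!col %in% names(halflife)) {
    stop(sprintf("scheme '%s' requires column '%s'", scheme, col))
  }
  if (anyDuplicated(halflife$gene_id)) stop("gene_ids must be unique")
  v <- halflife[[col]]
  keep <- !is.na(v)
  if (any(!keep)) {
    message(sprintf("classify_genes: dropped %d genes with missing '%s'",
                    sum(!keep), col))
  }
  v <- v[keep]
  ids <- halflife$gene_id[keep]
  long <- switch(scheme,
    half_life_threshold = {
      if (any(v <= 0)) stop("half-lives must be positive")
      v >= threshold
    },
    decay_rate_mean = {
      if (long_is_low_decay) v < mean(v) else v > mean(v)
    },
    housekeeping = as.logical(v),
    coding = v == "coding"
  )
  if (all(long) || !any(long)) {
    stop("all genes fall into one group; the stability score is undefined")
  }
  out <- data.frame(gene_id = ids,
                    group = ifelse(long, "long", "short"),
                    scheme = scheme, stringsAsFactors = FALSE)
  class(out) <- c("gene_classification", "data.frame")
  out
}

#' Rank a sample's expression values
#'
#' Ranks ascending with expression (higher expression, higher rank); ties
#' receive the average of their rank span.
#'
#' @param values finite numeric vector of one sample's expression levels.
#' @return numeric vector of ranks in 1..N.
#' @export
rank_expression <- function(values) {
  if (length(values) == 0) stop("cannot rank an empty expression vector")
  if (!all(is.finite(values))) stop("expression values must be finite")
  rank(values, ties.method = "average")
}

#' Per-sample RNA stability score
#'
#' For each sample, genes present in both the expression matrix and the
#' classification are ranked by expression (average ties), and the score is
#' the difference in mean rank between the long-lived and the short-lived
#' group: `mean(rank | long) - mean(rank | short)`. Only classified genes
#' participate in the ranking, which makes `|score| <= N/2` exact for N
#' classified genes. Higher scores mean stable transcripts are relatively
#' more highly expressed, i.e. more effective RNA stabilization in that
#' sample.
#'
#' @param expr genes x samples matrix of non-negative expression values with
#'   unique gene rownames and sample colnames.
#' @param cls a [classify_genes()] result.
#' @return a data.frame of class `rs_score` with columns `sample_id`,
#'   `rs_score`, `n_long`, `n_short`.
#' @export
rs_score <- function(expr, cls) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  if (anyDuplicated(rownames(expr))) {
    stop("duplicate gene identifiers in the expression matrix; collapse probes first")
  }
  if (any(!is.finite(expr)) || any(expr < 0)) {
    stop("expression values must be finite and non-negative")
  }
  long_ids <- intersect(rownames(expr), cls$gene_id[cls$group == "long"])
  short_ids <- intersect(rownames(expr), cls$gene_id[cls$group == "short"])
  if (length(long_ids) == 0) stop("no long-lived genes present in the expression matrix")
  if (length(short_ids) == 0) stop("no short-lived genes present in the expression matrix")

  sub <- expr[c(long_ids, short_ids), , drop = FALSE]
  is_long <- c(rep(TRUE, length(long_ids)), rep(FALSE, length(short_ids)))
  ranks <- apply(sub, 2, rank, ties.method = "average")
  score <- colMeans(ranks[is_long, , drop = FALSE]) -
    colMeans(ranks[!is_long, , drop = FALSE])
  out <- data.frame(sample_id = colnames(expr), rs_score = unname(score),
                    n_long = length(long_ids), n_short = length(short_ids),
                    stringsAsFactors = FALSE)
  class(out) <- c("rs_score", "data.frame")
  out
}

#' Agreement between two stability-score vectors
#'
#' Spearman rank correlation of two per-sample score vectors over their
#' shared samples, e.g. scores computed from half-life tables of different
#' cell types, or from alternative grouping schemes.
#'
#' @param a,b `rs_score` data.frames (or any data.frames with `sample_id`
#'   and `rs_score` columns).
#' @return Spearman rho over the shared samples (at least 3 required).
#' @export
score_agreement <- function(a, b) {
  shared <- intersect(a$sample_id, b$sample_id)
  if (length(shared) < 3) stop("need at least 3 shared samples")
  stats::cor(a$rs_score[match(shared, a$sample_id)],
             b$rs_score[match(shared, b$sample_id)],
             method = "spearman")
}
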