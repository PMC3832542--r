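# Genotype container and allele-frequency utilities.

#' Construct a genotype matrix object
#'
#' Container for SNPs x samples minor-allele dosages plus per-SNP and
#' per-sample metadata.
#'
#' @param dosage integer/numeric matrix of allele dosages in \{0, 1, 2\} (or
#'   `NA` for missing), SNPs in rows, samples in columns, with dimnames.
#' @param info data.frame with one row per SNP: `snp_id`, `chrom`, `pos`
#'   (1-based), `major`, `minor` allele labels. Optional column
#'   `counted_allele` records which allele the dosage counts.
#' @param samples data.frame with one row per sample: `sample_id`, and
#'   optionally `population` and `sex` (0/1).
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, info, samples) {
  stopifnot(is.matrix(dosage), nrow(dosage) == nrow(info),
            ncol(dosage) == nrow(samples))
  if (anyDuplicated(info$snp_id)) stop("snp_ids must be unique")
  if (anyDuplicated(samples$sample_id)) stop("sample_ids must be unique")
  if (any(info$pos <= 0)) stop("positions must be positive (1-based)")
  ok <- dosage %in% c(0, 1, 2) | is.na(dosage)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or missing")
  rownames(dosage) <- info$snp_id
  colnames(dosage) <- samples$sample_id
  structure(list(dosage = dosage, info = info, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d SNPs x %d samples", nrow(x$dosage),
              ncol(x$dosage)))
  if (!is.null(x$samples$population)) {
    cat(sprintf(" (%d populations)", length(unique(x$samples$population))))
  }
  cat("\n")
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param x a `genotype_matrix`.
#' @param snps,samples index vectors (logical, integer or character) applied
#'   to SNP rows and sample columns; `NULL` keeps all.
#' @return the subsetted `genotype_matrix`.
#' @export
subset_genotypes <- function(x, snps = NULL, samples = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (is.null(snps)) snps <- seq_len(nrow(x$dosage))
  if (is.null(samples)) samples <- seq_len(ncol(x$dosage))
  if (is.character(snps)) snps <- match(snps, x$info$snp_id)
  if (is.character(samples)) samples <- match(samples, x$samples$sample_id)
  genotype_matrix(x$dosage[snps, samples, drop = FALSE],
                  x$info[snps, , drop = FALSE],
                  x$samples[samples, , drop = FALSE])
}

#' Per-SNP minor allele frequency
#'
#' Folded allele frequency `min(f, 1 - f)` computed from non-missing dosages
#' in the current sample set, so the filter is cohort-relative.
#'
#' @param genotypes a `genotype_matrix`.
#' @return numeric vector of MAFs, one per SNP (NaN when all dosages are
#'   missing).
#' @export
snp_maf <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  f <- rowMeans(genotypes$dosage, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

#' Orient dosages to count the cohort minor allele
#'
#' SNPs whose counted-allele frequency exceeds 0.5 in the current cohort are
#' flipped (`dosage <- 2 - dosage`) and their major/minor labels swapped, so
#' that dosage always counts the cohort minor allele. The allele counted
#' after orientation is recorded in `info$counted_allele`.
#'
#' @param genotypes a `genotype_matrix`.
#' @return the re-oriented `genotype_matrix`.
#' @export
orient_minor <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  f <- rowMeans(genotypes$dosage, na.rm = TRUE) / 2
  flip <- !is.na(f) & f > 0.5
  if (any(flip)) {
    genotypes$dosage[flip, ] <- 2 - genotypes$dosage[flip, , drop = FALSE]
    tmp <- genotypes$info$major[flip]
    genotypes$info$major[flip] <- genotypes$info$minor[flip]
    genotypes$info$minor[flip] <- tmp
  }
  genotypes$info$counted_allele <- genotypes$info$minor
  genotypes
}
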