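# Readers and writers for the pipeline's TSV/VCF dialects, plus the
# end-to-end pipeline driver.

.read_tsv <- function(path, ...) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("%s: ragged row at line %d (%d fields, expected %d)",
                 path, bad, nf[bad], nf[1]))
  }
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE, ...)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers. Duplicate gene rows (e.g. multiple probes per gene) are
#' collapsed by their mean with a message; negative or non-numeric values
#' are rejected with their location.
#'
#' @param path TSV file path.
#' @return genes x samples numeric matrix.
#' @export
read_expression <- function(path) {
  df <- .read_tsv(path)
  if (ncol(df) < 2) stop(sprintf("%s: need a gene_id column plus sample columns", path))
  for (j in 2:ncol(df)) {
    if (!is.numeric(df[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[j]]))))[1]
      stop(sprintf("%s: non-numeric value in column '%s', data row %d",
                   path, names(df)[j], bad))
    }
  }
  genes <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (any(mat < 0, na.rm = TRUE)) {
    bad <- which(mat < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("%s: negative expression value at gene '%s', sample '%s'",
                 path, genes[bad[1]], colnames(mat)[bad[2]]))
  }
  if (anyDuplicated(genes)) {
    n_dup <- sum(duplicated(genes))
    message(sprintf("read_expression: collapsed %d duplicate gene rows by mean", n_dup))
    mat <- rowsum(mat, genes) / as.vector(table(genes))  # both sorted by gene
    mat <- mat[unique(genes), , drop = FALSE]
  } else {
    rownames(mat) <- genes
  }
  mat
}

#' Write an expression matrix to TSV
#'
#' @param expr genes x samples matrix with dimnames.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' Read a gene half-life / decay-rate table from TSV
#'
#' The header determines the measure: a `half_life_h` column yields a
#' half-life table (hours), a `relative_decay_rate` column a decay-rate
#' table. Annotation columns (`biotype`, `housekeeping`, `are_target`,
#' `chrom`, `tss_pos`) are carried through when present.
#'
#' @param path TSV file path.
#' @return data.frame of class `halflife_table`.
#' @export
read_halflife <- function(path) {
  df <- .read_tsv(path)
  if (!"gene_id" %in% names(df)) stop(sprintf("%s: missing 'gene_id' column", path))
  has_hl <- "half_life_h" %in% names(df)
  has_dr <- "relative_decay_rate" %in% names(df)
  if (has_hl == has_dr) {
    stop(sprintf("%s: need exactly one of 'half_life_h' or 'relative_decay_rate'", path))
  }
  if (has_hl) {
    names(df)[names(df) == "half_life_h"] <- "half_life"
    if (any(df$half_life <= 0, na.rm = TRUE)) {
      stop(sprintf("%s: half-lives must be positive", path))
    }
  }
  if (anyDuplicated(df$gene_id)) stop(sprintf("%s: duplicate gene_ids", path))
  if ("housekeeping" %in% names(df)) df$housekeeping <- as.logical(df$housekeeping)
  if ("are_target" %in% names(df)) df$are_target <- as.logical(df$are_target)
  if ("chrom" %in% names(df)) df$chrom <- as.character(df$chrom)
  class(df) <- c("halflife_table", "data.frame")
  df
}

#' Write a half-life table to TSV
#'
#' @param halflife a half-life (or decay-rate) table.
#' @param path output path.
#' @export
write_halflife <- function(halflife, path) {
  df <- as.data.frame(halflife)
  if ("half_life" %in% names(df)) {
    names(df)[names(df) == "half_life"] <- "half_life_h"
  }
  .write_tsv(df, path)
}

#' Read a gene annotation table from TSV
#'
#' Columns: `gene_id`, `chrom`, `tss_pos`, `biotype`, `housekeeping`,
#' `are_target`.
#'
#' @param path TSV file path.
#' @return annotation data.frame.
#' @export
read_annotation <- function(path) {
  df <- .read_tsv(path)
  need <- c("gene_id", "chrom", "tss_pos")
  if (!all(need %in% names(df))) {
    stop(sprintf("%s: missing columns: %s", path,
                 paste(setdiff(need, names(df)), collapse = ", ")))
  }
  if (anyDuplicated(df$gene_id)) stop(sprintf("%s: duplicate gene_ids", path))
  if (any(df$tss_pos <= 0)) stop(sprintf("%s: positions must be positive", path))
  df$chrom <- as.character(df$chrom)
  if ("housekeeping" %in% names(df)) df$housekeeping <- as.logical(df$housekeeping)
  if ("are_target" %in% names(df)) df$are_target <- as.logical(df$are_target)
  df
}

#' Write a gene annotation table to TSV
#'
#' @param annot annotation data.frame (e.g. a half-life table's annotation
#'   columns).
#' @param path output path.
#' @export
write_annotation <- function(annot, path) {
  cols <- intersect(c("gene_id", "chrom", "tss_pos", "biotype",
                      "housekeeping", "are_target"), names(annot))
  .write_tsv(as.data.frame(annot)[, cols], path)
}

#' Read genotypes from VCF or TSV
#'
#' VCF (4.x, GT field): biallelic sites are converted to dosages of the
#' cohort minor allele — the ALT-allele count is flipped at sites where the
#' ALT frequency exceeds 0.5, so the dosage is always cohort-relative, and
#' the counted allele is recorded. Missing genotypes (`./.`) become missing
#' dosages; non-biallelic sites are skipped with a message.
#'
#' TSV dialect: columns `snp_id chrom pos ref alt` followed by one dosage
#' column per sample; dosages are taken as stored (the TSV dialect is this
#' package's native, already-oriented format).
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "vcf") .read_genotypes_vcf(path) else .read_genotypes_tsv(path)
}

.read_genotypes_vcf <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  biallelic <- vcfR::is.biallelic(vcf)
  if (any(!biallelic)) {
    message(sprintf("read_genotypes: skipped %d non-biallelic sites", sum(!biallelic)))
    vcf <- vcf[biallelic, ]
  }
  fix <- vcfR::getFIX(vcf)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  d <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  called <- a1 %in% c("0", "1") & a2 %in% c("0", "1")
  d[called] <- (a1[called] == "1") + (a2[called] == "1")
  snp_id <- fix[, "ID"]
  no_id <- is.na(snp_id) | snp_id == "."
  snp_id[no_id] <- paste0(fix[no_id, "CHROM"], ":", fix[no_id, "POS"])
  g <- genotype_matrix(
    dosage = d,
    info = data.frame(snp_id = snp_id, chrom = as.character(fix[, "CHROM"]),
                      pos = as.integer(fix[, "POS"]),
                      major = fix[, "REF"], minor = fix[, "ALT"],
                      stringsAsFactors = FALSE),
    samples = data.frame(sample_id = colnames(gt), stringsAsFactors = FALSE)
  )
  orient_minor(g)
}

.read_genotypes_tsv <- function(path) {
  df <- .read_tsv(path)
  need <- c("snp_id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(df)[1:5])) {
    stop(sprintf("%s: expected leading columns %s", path, paste(need, collapse = " ")))
  }
  dcols <- setdiff(names(df), need)
  if (length(dcols) == 0) stop(sprintf("%s: no sample dosage columns", path))
  d <- as.matrix(df[, dcols, drop = FALSE])
  storage.mode(d) <- "double"
  bad <- which(!(d %in% c(0, 1, 2) | is.na(d)))
  if (length(bad)) {
    loc <- arrayInd(bad[1], dim(d))
    stop(sprintf("%s: invalid dosage at data row %d, sample '%s'",
                 path, loc[1], dcols[loc[2]]))
  }
  genotype_matrix(
    dosage = d,
    info = data.frame(snp_id = df$snp_id, chrom = as.character(df$chrom),
                      pos = as.integer(df$pos), major = df$ref,
                      minor = df$alt, stringsAsFactors = FALSE),
    samples = data.frame(sample_id = dcols, stringsAsFactors = FALSE)
  )
}

#' Write genotypes to TSV or VCF
#'
#' The TSV dialect stores dosages as-is. The VCF writer first orients
#' dosages to the cohort minor allele, then emits GT fields with REF =
#' major and ALT = minor allele, so a VCF round trip is lossless.
#'
#' @param genotypes a [genotype_matrix()].
#' @param path output path.
#' @param format `"tsv"` or `"vcf"`.
#' @export
write_genotypes <- function(genotypes, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (format == "tsv") {
    df <- data.frame(snp_id = genotypes$info$snp_id,
                     chrom = genotypes$info$chrom,
                     pos = genotypes$info$pos,
                     ref = genotypes$info$major,
                     alt = genotypes$info$minor,
                     genotypes$dosage, check.names = FALSE,
                     stringsAsFactors = FALSE)
    return(.write_tsv(df, path))
  }
  g <- orient_minor(genotypes)
  gt_codes <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(g$dosage), ncol(g$dosage))
  ok <- !is.na(g$dosage)
  gt[ok] <- gt_codes[g$dosage[ok] + 1]
  header <- c("##fileformat=VCFv4.2",
              paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                     paste(g$samples$sample_id, collapse = "\t")))
  body <- paste(g$info$chrom, g$info$pos, g$info$snp_id, g$info$major,
                g$info$minor, ".", ".", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a sample sheet (population and sex labels)
#'
#' Columns: `sample_id`, optional `population`, optional `sex` (0/1; 0 =
#' female, 1 = male).
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_samples <- function(path) {
  df <- .read_tsv(path)
  if (!"sample_id" %in% names(df)) stop(sprintf("%s: missing 'sample_id'", path))
  if ("sex" %in% names(df) && !all(df$sex %in% c(0, 1, NA))) {
    stop(sprintf("%s: sex must be coded 0/1", path))
  }
  df
}

#' Write a sample sheet
#' @param samples data.frame with `sample_id` and optional `population`,
#'   `sex`.
#' @param path output path.
#' @export
write_samples <- function(samples, path) .write_tsv(samples, path)

#' Read a covariate table (`sample_id sex pc1..pck`)
#' @param path TSV file path.
#' @return covariate data.frame.
#' @export
read_covariates <- function(path) {
  df <- .read_tsv(path)
  if (!"sample_id" %in% names(df)) stop(sprintf("%s: missing 'sample_id'", path))
  df
}

#' Write a covariate table
#' @param covariates covariate data.frame.
#' @param path output path.
#' @export
write_covariates <- function(covariates, path) .write_tsv(covariates, path)

#' Write a gene classification to TSV (`gene_id group scheme`)
#' @param cls a [classify_genes()] result.
#' @param path output path.
#' @export
write_classification <- function(cls, path) .write_tsv(as.data.frame(cls), path)

#' Write an association table to TSV
#'
#' Emits `snp_id chrom pos maf beta se t p bonferroni_p` with p-values in
#' scientific notation, plus (optionally) a companion table of
#' `chrom pos neglog10_p` for Manhattan plotting.
#'
#' @param assoc an `association_table` from [gwas_scan()].
#' @param path output path.
#' @param manhattan_path optional path for the plotting companion table.
#' @export
write_association <- function(assoc, path, manhattan_path = NULL) {
  df <- data.frame(snp_id = assoc$snp_id, chrom = assoc$chrom,
                   pos = assoc$pos, maf = assoc$maf,
                   beta = assoc$beta, se = assoc$se, t = assoc$t_stat,
                   p = sprintf("%.6e", assoc$p_value),
                   bonferroni_p = sprintf("%.6e", assoc$bonferroni_p),
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
  if (!is.null(manhattan_path)) {
    .write_tsv(data.frame(chrom = assoc$chrom, pos = assoc$pos,
                          neglog10_p = -log10(assoc$p_value)),
               manhattan_path)
  }
  invisible(path)
}

#' Write an eQTL table to TSV (`snp_id gene_id rho p fdr in_cis`)
#' @param eqtl an `eqtl_table`.
#' @param snp_id identifier of the scanned SNP.
#' @param path output path.
#' @export
write_eqtl <- function(eqtl, snp_id, path) {
  .write_tsv(data.frame(snp_id = rep(snp_id, nrow(eqtl)), gene_id = eqtl$gene_id,
                        rho = eqtl$rho, p = sprintf("%.6e", eqtl$p_value),
                        fdr = sprintf("%.6e", eqtl$fdr),
                        in_cis = eqtl$in_cis, stringsAsFactors = FALSE),
             path)
}

#' Write a simulated study to a directory
#'
#' Emits the bundle consumed by [run_pipeline()]: `genotypes.tsv` (or
#' `.vcf`), `expression.tsv`, `halflife.tsv`, `annotation.tsv` and
#' `samples.tsv`.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @param genotype_format `"tsv"` or `"vcf"`.
#' @return named character vector of the written paths.
#' @export
write_study <- function(study, dir, genotype_format = c("tsv", "vcf")) {
  genotype_format <- match.arg(genotype_format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geno_path <- file.path(dir, paste0("genotypes.", genotype_format))
  write_genotypes(study$genotypes, geno_path, genotype_format)
  write_expression(study$expression, file.path(dir, "expression.tsv"))
  write_halflife(study$halflife, file.path(dir, "halflife.tsv"))
  write_annotation(study$halflife, file.path(dir, "annotation.tsv"))
  write_samples(study$genotypes$samples, file.path(dir, "samples.tsv"))
  c(genotypes = geno_path,
    expression = file.path(dir, "expression.tsv"),
    halflife = file.path(dir, "halflife.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    samples = file.path(dir, "samples.tsv"))
}

#' Pipeline configuration
#'
#' Paths plus the analysis thresholds. Defaults: 4 h half-life threshold,
#' MAF cutoff 0.01, 5 principal components, 1000 permutations, FDR 0.1 and
#' a 1 Mb cis window.
#'
#' @param genotype_file,expression_file,halflife_file input paths.
#' @param annotation_file optional gene annotation path (enables the cis
#'   scan).
#' @param samples_file optional sample sheet path (population/sex labels).
#' @param out_dir output directory for the report bundle.
#' @param scheme,threshold gene classification scheme and half-life
#'   threshold (hours).
#' @param maf_threshold MAF exclusion threshold.
#' @param n_pcs number of genotype PCs used as covariates (0 disables).
#' @param n_perm number of phenotype permutations.
#' @param fdr_threshold FDR cutoff for trans associations.
#' @param cis_window cis window size in bases.
#' @param seed integer seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(genotype_file, expression_file, halflife_file,
                            annotation_file = NULL, samples_file = NULL,
                            out_dir = "rstab_out",
                            scheme = "half_life_threshold", threshold = 4,
                            maf_threshold = 0.01, n_pcs = 5, n_perm = 1000,
                            fdr_threshold = 0.1, cis_window = 1e6, seed = 1) {
  cfg <- list(genotype_file = genotype_file, expression_file = expression_file,
              halflife_file = halflife_file, annotation_file = annotation_file,
              samples_file = samples_file, out_dir = out_dir, scheme = scheme,
              threshold = threshold, maf_threshold = maf_threshold,
              n_pcs = as.integer(n_pcs), n_perm = as.integer(n_perm),
              fdr_threshold = fdr_threshold, cis_window = cis_window,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

# short stable polynomial hash of the configuration for the run log
.config_hash <- function(config) {
  bytes <- utf8ToInt(paste(names(config), sapply(config, function(x)
    paste(format(x), collapse = ",")), collapse = ";"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full stability-score association pipeline
#'
#' Orchestrates score computation, structure correction, the genome-wide
#' scan, permutation significance and eQTL mapping of the top SNP:
#' classify genes, compute per-sample scores, MAF-filter the genotypes,
#' build sex + PC covariates, scan, compute the genomic inflation factor,
#' run the min-p permutation test, and map the top SNP in trans (and in
#' cis when an annotation is supplied). All tables and a run log recording
#' the thresholds, seed and configuration hash are written to
#' `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with `scores`, `association`, `lambda`,
#'   `permutation`, `top_snp`, `trans_eqtl`, `cis_eqtl` and the output
#'   paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  genotypes <- .stage("read_genotypes", read_genotypes(config$genotype_file))
  expr <- .stage("read_expression", read_expression(config$expression_file))
  halflife <- .stage("read_halflife", read_halflife(config$halflife_file))
  annot <- if (!is.null(config$annotation_file)) {
    .stage("read_annotation", read_annotation(config$annotation_file))
  }
  if (!is.null(config$samples_file)) {
    samples <- .stage("read_samples", read_samples(config$samples_file))
    idx <- match(genotypes$samples$sample_id, samples$sample_id)
    for (col in setdiff(names(samples), "sample_id")) {
      genotypes$samples[[col]] <- samples[[col]][idx]
    }
  }

  cls <- .stage("classify_genes",
                classify_genes(halflife, scheme = config$scheme,
                               threshold = config$threshold))
  scores <- .stage("rs_score", rs_score(expr, cls))
  genotypes <- .stage("maf_filter", maf_filter(genotypes, config$maf_threshold))

  covariates <- .stage("covariates", {
    if (!is.null(genotypes$samples$sex) && anyNA(genotypes$samples$sex)) {
      drop_n <- sum(is.na(genotypes$samples$sex))
      message(sprintf("run_pipeline: dropped %d samples with unknown sex", drop_n))
      genotypes <- subset_genotypes(genotypes,
                                    samples = which(!is.na(genotypes$samples$sex)))
    }
    if (is.null(genotypes$samples$sex)) {
      if (config$n_pcs > 0) genotype_pca(genotypes, config$n_pcs) else NULL
    } else {
      make_covariates(genotypes, config$n_pcs)
    }
  })

  assoc <- .stage("gwas_scan", gwas_scan(genotypes, scores, covariates))
  lambda <- .stage("genomic_lambda",
                   genomic_lambda(assoc$p_value[!is.na(assoc$p_value)]))
  perm <- .stage("permutation_minp",
                 permutation_minp(genotypes, scores, covariates,
                                  n_perm = config$n_perm, seed = config$seed))

  top <- assoc[1, ]
  top_dosage <- genotypes$dosage[top$snp_id, ]
  trans <- .stage("trans_eqtl_scan",
                  trans_eqtl_scan(top_dosage, expr, config$fdr_threshold))
  cis <- if (!is.null(annot)) {
    .stage("cis_window_scan",
           cis_window_scan(list(chrom = top$chrom, pos = top$pos),
                           top_dosage, expr, annot, config$cis_window))
  }

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    scores = file.path(config$out_dir, "scores.tsv"),
    association = file.path(config$out_dir, "association.tsv"),
    manhattan = file.path(config$out_dir, "manhattan.tsv"),
    trans_eqtl = file.path(config$out_dir, "eqtl_trans.tsv"),
    log = file.path(config$out_dir, "run_log.txt")
  )
  .write_tsv(as.data.frame(scores), paths["scores"])
  write_association(assoc, paths["association"], paths["manhattan"])
  write_eqtl(trans, top$snp_id, paths["trans_eqtl"])
  if (!is.null(cis)) {
    paths["cis_eqtl"] <- file.path(config$out_dir, "eqtl_cis.tsv")
    write_eqtl(cis, top$snp_id, paths["cis_eqtl"])
  }

  version <- tryCatch(as.character(utils::packageVersion("rstab")),
                      error = function(e) "unknown")
  log_lines <- c(
    sprintf("rstab version: %s", version),
    sprintf("config hash: %s", .config_hash(config)),
    sprintf("seed: %d", config$seed),
    sprintf("scheme: %s (threshold %g h)", config$scheme, config$threshold),
    sprintf("maf_threshold: %g", config$maf_threshold),
    sprintf("n_pcs: %d", config$n_pcs),
    sprintf("n_perm: %d", config$n_perm),
    sprintf("fdr_threshold: %g", config$fdr_threshold),
    sprintf("cis_window: %g", config$cis_window),
    sprintf("snps tested: %d", attr(assoc, "n_snps_tested")),
    sprintf("samples scored: %d", nrow(scores)),
    sprintf("genomic lambda: %.4f", lambda),
    sprintf("top SNP: %s (%s:%d), p = %.3e, Bonferroni p = %.3e",
            top$snp_id, top$chrom, top$pos, top$p_value, top$bonferroni_p),
    sprintf("permutation p: %s",
            if (perm$permutation_p == 0) sprintf("< %g", 1 / perm$n_perm)
            else format(perm$permutation_p))
  )
  writeLines(log_lines, paths["log"])

  invisible(list(scores = scores, association = assoc, lambda = lambda,
                 permutation = perm, top_snp = top, trans_eqtl = trans,
                 cis_eqtl = cis, covariates = covariates, paths = paths))
}
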