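# Readers for the standard input formats.
#
# Containers are light S3 lists in the MatrixEQTL spirit:
#   genotype_matrix:    $dosage  samples x SNPs integer matrix, $snps meta
#   methylation_matrix: $beta    samples x CpGs numeric matrix (0-100), $cpgs meta
# Point features are 1-based; interval tracks 0-based half-open (see coords.R).

new_genotype_matrix <- function(dosage, snps) {
  stopifnot(ncol(dosage) == nrow(snps))
  structure(list(dosage = dosage, snps = snps), class = "genotype_matrix")
}

new_methylation_matrix <- function(beta, cpgs) {
  stopifnot(ncol(beta) == nrow(cpgs))
  structure(list(beta = beta, cpgs = cpgs), class = "methylation_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs, MAF range [%.3f, %.3f]\n",
              nrow(x$dosage), ncol(x$dosage), min(x$snps$maf), max(x$snps$maf)))
  invisible(x)
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat(sprintf("methylation_matrix: %d samples x %d CpGs (beta 0-100)\n",
              nrow(x$beta), ncol(x$beta)))
  invisible(x)
}

snp_maf_from_dosage <- function(dosage) {
  af <- colMeans(dosage) / 2
  pmin(af, 1 - af)
}

#' Read a genotype matrix from VCF or dosage TSV
#'
#' The TSV dialect has header columns `snp_id`, `chrom`, `pos` followed by one
#' column per sample holding additive dosages in \{0, 1, 2\}. VCF input uses
#' hard GT calls; non-biallelic records are skipped (logged), and the dosage
#' is the ALT allele count. MAF is recomputed from the dosages in both paths.
#'
#' @param path Path to the file.
#' @param format `"vcf"`, `"tsv"`, or `"auto"` (by extension).
#' @param impute_mean Replace missing dosages by the SNP mean instead of
#'   erroring (off by default; upstream data are expected to be complete).
#' @return A `genotype_matrix`: `$dosage` (samples x SNPs) and `$snps`
#'   (data.table with `snp_id`, `chrom`, `pos`, `maf`).
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv"),
                           impute_mean = FALSE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (!file.exists(path)) mk_stop("genotype file not found: %s", path)
  if (format == "vcf") read_genotypes_vcf(path, impute_mean) else
    read_genotypes_tsv(path, impute_mean)
}

read_genotypes_vcf <- function(path, impute_mean) {
  vcf <- VariantAnnotation::readVcf(path)
  if (!("GT" %in% names(VariantAnnotation::geno(vcf))))
    mk_stop("VCF has no GT field: %s", path)
  alt <- VariantAnnotation::alt(vcf)
  biallelic <- lengths(alt) == 1L
  n_skip <- sum(!biallelic)
  if (n_skip > 0L) {
    mk_log("skipped %d non-biallelic VCF records", n_skip)
    vcf <- vcf[biallelic]
  }
  gt <- VariantAnnotation::geno(vcf)$GT  # SNPs x samples, strings
  rr <- SummarizedExperiment::rowRanges(vcf)
  snp_id <- names(rr)
  if (anyDuplicated(snp_id)) mk_stop("duplicate snp_id in VCF: %s",
                                     snp_id[duplicated(snp_id)][1L])
  dose <- gt_to_dosage(gt)
  if (anyNA(dose)) {
    if (!impute_mean) {
      bad <- which(rowSums(is.na(dose)) > 0L)[1L]
      mk_stop("missing GT at record %s (use impute_mean = TRUE to allow)",
              snp_id[bad])
    }
    dose <- impute_row_means(dose)
  }
  dosage <- t(dose)
  rownames(dosage) <- colnames(gt)
  colnames(dosage) <- snp_id
  snps <- data.table(snp_id = snp_id,
                     chrom = norm_chrom(GenomicRanges::seqnames(rr)),
                     pos = GenomicRanges::start(rr),
                     maf = snp_maf_from_dosage(dosage))
  new_genotype_matrix(dosage, snps)
}

gt_to_dosage <- function(gt) {
  d <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  lut <- c("0/0" = 0, "0|0" = 0, "0/1" = 1, "1/0" = 1, "0|1" = 1, "1|0" = 1,
           "1/1" = 2, "1|1" = 2)
  known <- gt %in% names(lut)
  d[known] <- lut[gt[known]]
  missing_codes <- gt %in% c("./.", ".|.", ".")
  bad <- !known & !missing_codes
  if (any(bad)) mk_stop("unparseable GT value '%s'", gt[bad][1L])
  d
}

impute_row_means <- function(d) {
  na_rows <- which(rowSums(is.na(d)) > 0L)
  for (i in na_rows) {
    m <- mean(d[i, ], na.rm = TRUE)
    d[i, is.na(d[i, ])] <- m
  }
  mk_log("imputed missing dosages at %d SNPs with the SNP mean", length(na_rows))
  d
}

read_genotypes_tsv <- function(path, impute_mean) {
  dt <- fread(path, sep = "\t", colClasses = list(character = "chrom"))
  need <- c("snp_id", "chrom", "pos")
  if (!all(need %in% names(dt)))
    mk_stop("genotype TSV must start with columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(dt$snp_id))
    mk_stop("duplicate snp_id: %s", dt$snp_id[duplicated(dt$snp_id)][1L])
  samp_cols <- setdiff(names(dt), need)
  if (length(samp_cols) == 0L) mk_stop("genotype TSV has no sample columns")
  dose <- as.matrix(dt[, samp_cols, with = FALSE])
  storage.mode(dose) <- "double"
  ok <- dose %in% c(0, 1, 2) | is.na(dose)
  if (!all(ok)) {
    idx <- which(!matrix(ok, nrow(dose)), arr.ind = TRUE)[1L, ]
    mk_stop("dosage out of range at snp %s, sample %s",
            dt$snp_id[idx[1L]], samp_cols[idx[2L]])
  }
  if (anyNA(dose)) {
    if (!impute_mean) mk_stop("missing dosage at record %s",
                              dt$snp_id[which(rowSums(is.na(dose)) > 0L)[1L]])
    dose <- impute_row_means(dose)
  }
  dosage <- t(dose)
  rownames(dosage) <- samp_cols
  colnames(dosage) <- dt$snp_id
  snps <- data.table(snp_id = dt$snp_id, chrom = norm_chrom(dt$chrom),
                     pos = as.integer(dt$pos),
                     maf = snp_maf_from_dosage(dosage))
  new_genotype_matrix(dosage, snps)
}

#' Read a methylation beta matrix
#'
#' TSV with header `cpg_id`, `chrom`, `pos` (optionally `snp_proximal`)
#' followed by one column per sample. Values are percent methylation on the
#' 0-100 scale; a matrix entirely within \[0, 1\] is assumed to be on the
#' proportion scale and is rescaled by 100 with a logged warning. Per-CpG
#' standard deviation (sample sd, n-1 denominator) is stored in the metadata.
#'
#' @param path Path to the TSV file.
#' @return A `methylation_matrix`: `$beta` (samples x CpGs) and `$cpgs`
#'   (data.table with `cpg_id`, `chrom`, `pos`, `sd`, `snp_proximal`).
#' @export
read_methylation <- function(path) {
  dt <- fread(path, sep = "\t", colClasses = list(character = "chrom"))
  need <- c("cpg_id", "chrom", "pos")
  if (!all(need %in% names(dt)))
    mk_stop("methylation TSV must start with columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(dt$cpg_id))
    mk_stop("duplicate cpg_id: %s", dt$cpg_id[duplicated(dt$cpg_id)][1L])
  prox <- if ("snp_proximal" %in% names(dt)) as.logical(dt$snp_proximal) else
    rep(FALSE, nrow(dt))
  samp_cols <- setdiff(names(dt), c(need, "snp_proximal"))
  if (length(samp_cols) == 0L) mk_stop("methylation TSV has no sample columns")
  vals <- as.matrix(dt[, samp_cols, with = FALSE])
  if (all(vals >= 0 & vals <= 1, na.rm = TRUE) && nrow(vals) > 0L) {
    warning("methylation values all in [0,1]; rescaling to the 0-100 beta scale")
    mk_log("rescaled methylation matrix from [0,1] to [0,100]")
    vals <- vals * 100
  }
  if (any(vals < 0 | vals > 100, na.rm = TRUE))
    mk_stop("methylation value outside [0,100] after rescale")
  beta <- t(vals)
  rownames(beta) <- samp_cols
  colnames(beta) <- dt$cpg_id
  cpgs <- data.table(cpg_id = dt$cpg_id, chrom = norm_chrom(dt$chrom),
                     pos = as.integer(dt$pos),
                     sd = apply(vals, 1L, stats::sd),
                     snp_proximal = prox)
  new_methylation_matrix(beta, cpgs)
}

#' Read GWAS summary statistics
#'
#' @param path TSV with columns `snp_id`, `chrom`, `pos`, `p`, `maf`.
#' @return data.table with those columns; `p` validated in (0, 1].
#' @export
read_gwas <- function(path) {
  dt <- fread(path, sep = "\t", colClasses = list(character = "chrom"))
  need <- c("snp_id", "chrom", "pos", "p", "maf")
  if (!all(need %in% names(dt)))
    mk_stop("GWAS TSV must have columns %s", paste(need, collapse = ", "))
  if (any(dt$p <= 0 | dt$p > 1))
    mk_stop("GWAS p-values must lie in (0, 1]; offending snp %s",
            dt$snp_id[which(dt$p <= 0 | dt$p > 1)[1L]])
  dt[, chrom := norm_chrom(chrom)]
  dt[]
}

#' Read a BED3+ feature track
#'
#' Intervals are kept in the native 0-based half-open convention.
#'
#' @param path BED file (tab-separated, no header).
#' @param name Track name; defaults to the file stem. If `use_name_column`
#'   is TRUE and a 4th column exists, its first value overrides the name.
#' @param use_name_column Take the track name from BED column 4.
#' @return A `feature_track`: `$name` and `$intervals`
#'   (data.table `chrom`, `start`, `end`).
#' @export
read_bed <- function(path, name = NULL, use_name_column = FALSE) {
  if (!file.exists(path)) mk_stop("BED file not found: %s", path)
  stem <- sub("\\.bed$", "", basename(path))
  if (file.size(path) == 0L) {
    return(new_feature_track(name %||% stem,
                             data.table(chrom = character(), start = integer(),
                                        end = integer())))
  }
  dt <- fread(path, sep = "\t", header = FALSE)
  if (ncol(dt) < 3L) mk_stop("BED file needs >= 3 columns: %s", path)
  setnames(dt, 1:3, c("chrom", "start", "end"))
  bad <- which(dt$start >= dt$end)
  if (length(bad) > 0L)
    mk_stop("BED interval with start >= end at line %d of %s", bad[1L], path)
  nm <- name %||% stem
  if (use_name_column && ncol(dt) >= 4L) nm <- as.character(dt[[4L]][1L])
  new_feature_track(nm, data.table(chrom = norm_chrom(dt$chrom),
                                   start = as.integer(dt$start),
                                   end = as.integer(dt$end)))
}

new_feature_track <- function(name, intervals) {
  if (!nzchar(name)) mk_stop("feature track name must be nonempty")
  structure(list(name = name, intervals = intervals), class = "feature_track")
}

#' @export
print.feature_track <- function(x, ...) {
  cat(sprintf("feature_track '%s': %d intervals\n", x$name, nrow(x$intervals)))
  invisible(x)
}

#' Convert a feature track to a GRanges object
#'
#' @param track A `feature_track`.
#' @return GRanges (1-based closed, as GRanges requires).
#' @export
track_to_granges <- function(track) {
  GenomicRanges::GRanges(track$intervals$chrom,
                         IRanges::IRanges(start = track$intervals$start + 1L,
                                          end = track$intervals$end))
}

#' Read a gene annotation table
#'
#' @param path TSV with columns `gene_id`, `chrom`, `start`, `end`, `biotype`
#'   (1-based inclusive coordinates).
#' @return data.table of genes.
#' @export
read_genes <- function(path) {
  dt <- fread(path, sep = "\t", colClasses = list(character = "chrom"))
  need <- c("gene_id", "chrom", "start", "end", "biotype")
  if (!all(need %in% names(dt)))
    mk_stop("gene TSV must have columns %s", paste(need, collapse = ", "))
  if (any(dt$start > dt$end)) mk_stop("gene with start > end")
  dt[, chrom := norm_chrom(chrom)]
  dt[]
}

#' Read an externally published meQTL list
#'
#' @param path TSV with columns `snp_id`, `cpg_id`, `p` (positions optional).
#' @param provenance Label describing the source (e.g. tissue).
#' @return A `meqtl_map` (see [build_meqtl_map()]); duplicate (snp, cpg)
#'   pairs are dropped with a log message.
#' @export
read_meqtl_list <- function(path, provenance = basename(path)) {
  dt <- fread(path, sep = "\t")
  need <- c("snp_id", "cpg_id", "p")
  if (!all(need %in% names(dt)))
    mk_stop("meQTL list must have columns %s", paste(need, collapse = ", "))
  ndup <- sum(duplicated(dt[, .(snp_id, cpg_id)]))
  if (ndup > 0L) {
    mk_log("dropped %d duplicate (snp, cpg) rows from %s", ndup, path)
    dt <- dt[!duplicated(dt[, .(snp_id, cpg_id)])]
  }
  new_meqtl_map(dt, p_threshold = NA_real_, provenance = provenance)
}
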