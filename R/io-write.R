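# Writers mirroring the reader dialects (lossless round-trips).

#' Write a genotype matrix in the dosage TSV dialect
#'
#' @param genotypes A `genotype_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path) {
  dt <- data.table(snp_id = genotypes$snps$snp_id,
                   chrom = genotypes$snps$chrom,
                   pos = genotypes$snps$pos)
  dose <- t(genotypes$dosage)
  dt <- cbind(dt, as.data.table(dose))
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Write a methylation matrix in the beta TSV dialect
#'
#' @param methylation A `methylation_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_methylation <- function(methylation, path) {
  dt <- data.table(cpg_id = methylation$cpgs$cpg_id,
                   chrom = methylation$cpgs$chrom,
                   pos = methylation$cpgs$pos,
                   snp_proximal = methylation$cpgs$snp_proximal)
  dt <- cbind(dt, as.data.table(t(methylation$beta)))
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Write GWAS summary statistics
#'
#' @param gwas data.table with `snp_id`, `chrom`, `pos`, `p`, `maf`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gwas <- function(gwas, path) {
  fwrite(gwas[, .(snp_id, chrom, pos, p, maf)], path, sep = "\t")
  invisible(path)
}

#' Write a feature track as BED3
#'
#' @param track A `feature_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(track, path) {
  fwrite(track$intervals[, .(chrom, start, end)], path, sep = "\t",
         col.names = FALSE)
  invisible(path)
}

#' Write a gene annotation table
#'
#' @param genes data.table of genes.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path) {
  fwrite(genes[, .(gene_id, chrom, start, end, biotype)], path, sep = "\t")
  invisible(path)
}

#' Write a meQTL map's records
#'
#' Columns: snp_id, cpg_id, snp_chrom, snp_pos, cpg_chrom, cpg_pos,
#' distance_bp, slope, se, t, p (coordinate and statistic columns are
#' included when present in the records).
#'
#' @param map A `meqtl_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meqtl_map <- function(map, path) {
  keep <- intersect(c("snp_id", "cpg_id", "snp_chrom", "snp_pos", "cpg_chrom",
                      "cpg_pos", "distance_bp", "slope", "se", "t", "p"),
                    names(map$records))
  fwrite(map$records[, keep, with = FALSE], path, sep = "\t")
  invisible(path)
}
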