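# Enrichment of disease-associated SNPs for meQTL status: proxy expansion,
# GWAS-p-supervised LD pruning, MAF x CpG-opportunity stratification, and
# resampled matched null SNP sets.

#' Composite LD r-squared between two dosage vectors
#'
#' Squared Pearson correlation of unphased additive dosages.
#'
#' @param dosage_a,dosage_b Equal-length dosage vectors with nonzero variance.
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(dosage_a, dosage_b) {
  if (length(dosage_a) != length(dosage_b)) mk_stop("unequal vector lengths")
  if (var(dosage_a) == 0 || var(dosage_b) == 0)
    mk_stop("zero dosage variance")
  cor(dosage_a, dosage_b)^2
}

#' Expand index SNPs to include LD proxies
#'
#' Returns the union of the index set and every panel SNP within `window`
#' bp of an index SNP on the same chromosome with `r^2 >= r2_min` to it.
#' Index SNPs absent from the panel are kept but cannot recruit proxies
#' (logged).
#'
#' @param index_snps Character vector of SNP ids.
#' @param panel A `genotype_matrix` reference panel.
#' @param r2_min Proxy threshold (default 0.8).
#' @param window Window in bp (default 500000).
#' @return Character vector: the expanded SNP set.
#' @export
find_proxies <- function(index_snps, panel, r2_min = 0.8, window = 500000) {
  if (ncol(panel$dosage) == 0L) mk_stop("empty reference panel")
  meta <- panel$snps
  present <- index_snps[index_snps %in% meta$snp_id]
  absent <- setdiff(index_snps, present)
  if (length(absent) > 0L)
    mk_log("%d index SNPs absent from the panel; kept without proxies",
           length(absent))
  prox <- character(0)
  for (s in present) {
    i <- match(s, meta$snp_id)
    cand <- which(meta$chrom == meta$chrom[i] &
                    abs(meta$pos - meta$pos[i]) <= window &
                    meta$snp_id != s)
    if (length(cand) == 0L) next
    gi <- panel$dosage[, i]
    r2 <- vapply(cand, function(j) {
      gj <- panel$dosage[, j]
      if (var(gj) == 0 || var(gi) == 0) return(0)
      cor(gi, gj)^2
    }, numeric(1))
    prox <- c(prox, meta$snp_id[cand[r2 >= r2_min]])
  }
  unique(c(index_snps, prox))
}

#' Supervised LD pruning
#'
#' Greedy pruning prioritized by a p-value: repeatedly keep the unresolved
#' SNP with the smallest priority p (ties broken by smaller position, then
#' lexicographic id) and remove all unresolved SNPs within `window` bp on the
#' same chromosome with `r^2 > r2_prune` to it. No two kept SNPs within the
#' window exceed `r2_prune`.
#'
#' @param snps data.table with `snp_id` and priority `p`.
#' @param panel A `genotype_matrix` covering all the SNPs.
#' @param r2_prune Pruning threshold, strict (default 0.7).
#' @param window Window in bp (default 500000).
#' @return Character vector of kept SNP ids.
#' @export
supervised_ld_prune <- function(snps, panel, r2_prune = 0.7, window = 500000) {
  snps <- as.data.table(snps)
  miss <- setdiff(snps$snp_id, panel$snps$snp_id)
  if (length(miss) > 0L)
    mk_stop("SNP missing from panel: %s", miss[1L])
  idx <- match(snps$snp_id, panel$snps$snp_id)
  meta <- panel$snps[idx]
  ord <- order(snps$p, meta$pos, meta$snp_id)
  resolved <- rep(FALSE, nrow(snps))
  kept <- logical(nrow(snps))
  for (k in ord) {
    if (resolved[k]) next
    kept[k] <- TRUE
    resolved[k] <- TRUE
    cand <- which(!resolved & meta$chrom == meta$chrom[k] &
                    abs(meta$pos - meta$pos[k]) <= window)
    if (length(cand) == 0L) next
    gk <- panel$dosage[, idx[k]]
    for (j in cand) {
      gj <- panel$dosage[, idx[j]]
      if (var(gk) > 0 && var(gj) > 0 && cor(gk, gj)^2 > r2_prune)
        resolved[j] <- TRUE
    }
  }
  snps$snp_id[kept]
}

#' Stratify SNPs by MAF bin and CpG opportunity bin
#'
#' Opportunity is the number of sd-filtered CpGs on the same chromosome
#' within the discovery window; it is collapsed into half-open integer bins
#' of width `opportunity_bin_width` (0-49, 50-99, ...). MAF bins have width
#' `maf_bin_width`, starting at `maf_floor`, top bin closed at 0.5.
#'
#' @param snp_meta data.table `snp_id`, `chrom`, `pos`, `maf`.
#' @param cpg_meta_filtered The post-sd-filter CpG table used in discovery.
#' @param window Discovery window in bp.
#' @param maf_bin_width Default 0.05.
#' @param opportunity_bin_width Default 50.
#' @param maf_floor Lower edge of the first MAF bin (default 0.01).
#' @return data.table: `snp_id`, `opportunity`, `maf_bin`, `opp_bin`,
#'   `stratum` (the combined label).
#' @export
stratify_snps <- function(snp_meta, cpg_meta_filtered, window,
                          maf_bin_width = 0.05, opportunity_bin_width = 50L,
                          maf_floor = 0.01) {
  snp_meta <- as.data.table(snp_meta)
  cpg_meta_filtered <- as.data.table(cpg_meta_filtered)
  opp <- integer(nrow(snp_meta))
  for (ch in unique(snp_meta$chrom)) {
    si <- which(snp_meta$chrom == ch)
    cp <- sort(cpg_meta_filtered[chrom == ch, pos])
    if (length(cp) == 0L) { opp[si] <- 0L; next }
    lo <- findInterval(snp_meta$pos[si] - window - 0.5, cp)
    hi <- findInterval(snp_meta$pos[si] + window + 0.5, cp)
    opp[si] <- hi - lo
  }
  opp_lo <- (opp %/% opportunity_bin_width) * opportunity_bin_width
  opp_bin <- sprintf("%d-%d", opp_lo, opp_lo + opportunity_bin_width - 1L)
  # bins on the natural 0.05 grid, first bin truncated at the MAF floor,
  # top bin closed at 0.5: [0.01,0.05), [0.05,0.10), ..., [0.45,0.50]
  mbin <- floor(snp_meta$maf / maf_bin_width)
  m_hi <- pmin((mbin + 1) * maf_bin_width, 0.5)
  m_lo <- pmax(pmin(mbin * maf_bin_width, 0.5 - maf_bin_width), maf_floor)
  maf_bin <- sprintf("[%.2f,%.2f)", m_lo, m_hi)
  data.table(snp_id = snp_meta$snp_id, opportunity = opp,
             maf_bin = maf_bin, opp_bin = opp_bin,
             stratum = paste(maf_bin, opp_bin, sep = "|"))
}

#' Sample stratum-matched null SNP sets
#'
#' Each null set reproduces the disease set's stratum composition exactly:
#' for every stratum, the same number of SNPs is drawn from the candidate
#' pool restricted to that stratum — without replacement within a set when
#' the stratum pool suffices, otherwise with replacement (logged warning).
#' Sets are drawn independently of each other.
#'
#' @param disease_set Character vector of disease SNP ids.
#' @param candidate_pool Character vector of candidate SNP ids
#'   (must exclude the disease set).
#' @param strata data.table from [stratify_snps()] covering all SNPs.
#' @param n_sets Number of null sets (default 1000).
#' @param seed Integer seed.
#' @return List of character vectors, each of length `length(disease_set)`.
#' @export
sample_null_sets <- function(disease_set, candidate_pool, strata,
                             n_sets = 1000L, seed = 1L) {
  strata <- as.data.table(strata)
  lut <- setNames(strata$stratum, strata$snp_id)
  ds <- lut[disease_set]
  if (anyNA(ds)) mk_stop("disease SNP missing from strata table")
  pool_by <- split(intersect(candidate_pool, strata$snp_id),
                   lut[intersect(candidate_pool, strata$snp_id)])
  need <- table(ds)
  for (s in names(need)) {
    avail <- length(pool_by[[s]] %||% character(0))
    if (avail == 0L)
      mk_stop("no candidate pool SNPs in stratum '%s'", s)
    if (avail < need[[s]])
      warning(sprintf("stratum '%s': pool (%d) smaller than disease count (%d); sampling with replacement",
                      s, avail, need[[s]]))
  }
  set.seed(seed)
  lapply(seq_len(n_sets), function(b) {
    unlist(lapply(names(need), function(s) {
      pool <- pool_by[[s]]
      k <- need[[s]]
      if (length(pool) >= k) sample(pool, k) else sample(pool, k, replace = TRUE)
    }), use.names = FALSE)
  })
}

#' Test enrichment of a SNP set for meQTL status against matched null sets
#'
#' `fold = observed proportion / mean(null proportions)`; the permutation p
#' is the fraction of null sets with a proportion as or more extreme
#' (one-sided, >=). The conservative variant `(k + 1)/(B + 1)` is reported
#' alongside since a count of zero otherwise prints as 0.
#'
#' @param disease_set,null_sets SNP id vectors / list of vectors.
#' @param meqtl_snps Character vector: SNPs with meQTL status.
#' @return An `enrichment_result` list: `observed_prop`, `null_props`,
#'   `fold`, `perm_p`, `perm_p_conservative`, `n_null_sets`.
#' @export
enrichment_test <- function(disease_set, null_sets, meqtl_snps) {
  if (length(disease_set) == 0L || length(null_sets) == 0L)
    mk_stop("empty disease or null sets")
  obs <- mean(disease_set %in% meqtl_snps)
  nulls <- vapply(null_sets, function(s) mean(s %in% meqtl_snps), numeric(1))
  mnull <- mean(nulls)
  if (mnull == 0) mk_stop("mean null meQTL proportion is zero; fold undefined")
  k <- sum(nulls >= obs)
  B <- length(nulls)
  structure(list(observed_prop = obs, null_props = nulls,
                 fold = obs / mnull, perm_p = k / B,
                 perm_p_conservative = (k + 1) / (B + 1),
                 n_null_sets = B),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  pp <- if (x$perm_p == 0) sprintf("< %.3g", 1 / x$n_null_sets) else
    format(x$perm_p)
  cat(sprintf("enrichment_result: observed %.4f, null mean %.4f, fold %.3f, permutation p %s (%d null sets)\n",
              x$observed_prop, mean(x$null_props), x$fold, pp, x$n_null_sets))
  invisible(x)
}

#' Expand disease loci via meQTL target genes, collapsed by LD block
#'
#' Each disease SNP is assigned to the recombination block containing it
#' (SNPs outside all blocks get a logged singleton block). Per block, the
#' report lists member SNPs, genes overlapping those SNPs, target CpGs of
#' those SNPs under the meQTL map, and genes overlapping those CpGs. Genes
#' with non-coding biotypes (lincRNA, lncRNA, miRNA, small RNAs) are dropped.
#'
#' @param disease_snps Character vector of SNP ids.
#' @param snp_meta data.table `snp_id`, `chrom`, `pos`.
#' @param meqtl_map A `meqtl_map`.
#' @param cpg_meta data.table `cpg_id`, `chrom`, `pos`.
#' @param genes data.table `gene_id`, `chrom`, `start`, `end`, `biotype`.
#' @param blocks data.table `chrom`, `start`, `end` (1-based inclusive).
#' @return data.table, one row per block: `block`, `chrom`, `snps`,
#'   `snp_genes`, `target_cpgs`, `cpg_genes`, `genes` (union), as
#'   comma-separated id strings.
#' @export
expand_locus <- function(disease_snps, snp_meta, meqtl_map, cpg_meta, genes,
                         blocks) {
  snp_meta <- as.data.table(snp_meta)[snp_id %in% disease_snps]
  if (nrow(snp_meta) == 0L) mk_stop("no disease SNPs in the metadata")
  cpg_meta <- as.data.table(cpg_meta)
  genes <- as.data.table(genes)
  drop_bt <- c("lincRNA", "lncRNA", "miRNA", "snoRNA", "snRNA", "scaRNA",
               "small_RNA")
  genes <- genes[!biotype %in% drop_bt]
  blocks <- as.data.table(blocks)

  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start, genes$end))
  point_genes <- function(chr, pos) {
    if (length(pos) == 0L) return(character(0))
    q <- GenomicRanges::GRanges(chr, IRanges::IRanges(pos, pos))
    hits <- GenomicRanges::findOverlaps(q, gene_gr)
    unique(genes$gene_id[S4Vectors::subjectHits(hits)])
  }
  block_of <- function(chr, pos) {
    hit <- blocks[chrom == chr & start <= pos & end >= pos]
    if (nrow(hit) == 0L) return(NA_character_)
    sprintf("%s:%d-%d", chr, hit$start[1L], hit$end[1L])
  }
  snp_meta[, block := mapply(block_of, chrom, pos)]
  n_orphan <- sum(is.na(snp_meta$block))
  if (n_orphan > 0L) {
    mk_log("%d SNPs outside all blocks; assigned singleton blocks", n_orphan)
    snp_meta[is.na(block), block := sprintf("%s:%d-%d", chrom, pos, pos)]
  }
  rec <- meqtl_map$records
  out <- snp_meta[, {
    ids <- snp_id
    sg <- point_genes(chrom[1L], pos)
    tc <- unique(rec$cpg_id[rec$snp_id %in% ids])
    cm <- cpg_meta[cpg_id %in% tc]
    cg <- unique(unlist(lapply(unique(cm$chrom), function(ch)
      point_genes(ch, cm[chrom == ch, pos]))))
    .(chrom = chrom[1L],
      snps = paste(snp_id, collapse = ","),
      snp_genes = paste(sg, collapse = ","),
      target_cpgs = paste(tc, collapse = ","),
      cpg_genes = paste(cg, collapse = ","),
      genes = paste(union(sg, cg), collapse = ","))
  }, by = block]
  out[]
}
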