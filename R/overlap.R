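# Regulatory-feature overlap: CpG-vs-track annotation, two-sided Fisher
# exact tests, the seven harmonized target lists, and the Bonferroni battery.

#' Annotate CpGs for overlap with a feature track
#'
#' A CpG at 1-based position p overlaps iff some interval of the (0-based,
#' half-open) track contains p - 1. Chromosome labels are normalized (chr1
#' vs 1) before matching.
#'
#' @param cpg_meta data.table `cpg_id`, `chrom`, `pos`.
#' @param track A `feature_track`.
#' @return Logical vector along `cpg_meta`.
#' @export
annotate_overlap <- function(cpg_meta, track) {
  cpg_meta <- as.data.table(cpg_meta)
  iv <- track$intervals
  out <- rep(FALSE, nrow(cpg_meta))
  if (nrow(iv) == 0L) return(out)
  cc <- norm_chrom(cpg_meta$chrom)
  ic <- norm_chrom(iv$chrom)
  for (ch in intersect(unique(cc), unique(ic))) {
    ci <- which(cc == ch)
    sub <- iv[ic == ch]
    ir <- IRanges::IRanges(start = sub$start + 1L, end = sub$end)  # 1-based closed
    q <- IRanges::IRanges(cpg_meta$pos[ci], cpg_meta$pos[ci])
    out[ci] <- IRanges::overlapsAny(q, ir)
  }
  out
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' The two-sided p sums hypergeometric point probabilities no larger than
#' that of the observed table (probability ordering, with the customary
#' 1e-7 relative tolerance for ties). The odds ratio reported is the sample
#' OR `ad/bc` (+Inf when `bc = 0` and `ad > 0`; NA when both products are
#' zero); the conditional-MLE OR that `fisher.test()` prints is available
#' via `or = "cmle"`.
#'
#' @param a,b,c,d Nonnegative integer counts; rows are the two groups,
#'   columns feature/no-feature.
#' @param or `"sample"` (default) or `"cmle"`.
#' @return List: `or`, `p`.
#' @export
fisher_2x2 <- function(a, b, c, d, or = c("sample", "cmle")) {
  or <- match.arg(or)
  if (any(c(a, b, c, d) < 0)) mk_stop("counts must be nonnegative")
  m <- a + b         # row 1 margin
  n2 <- c + d        # row 2 margin
  k <- a + c         # column 1 margin
  if ((m == 0 && n2 == 0) || (k == 0 && b + d == 0))
    mk_stop("both margins must be positive")
  lo <- max(0L, k - n2)
  hi <- min(k, m)
  support <- lo:hi
  dens <- dhyper(support, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  p <- sum(dens[dens <= p_obs * (1 + 1e-7)])
  p <- min(1, p)
  or_val <- if (or == "cmle") {
    if (b * c == 0 && a * d == 0) NA_real_
    else stats::fisher.test(matrix(c(a, b, c, d), 2L, byrow = TRUE))$estimate[[1L]]
  } else {
    if (b * c == 0) { if (a * d == 0) NA_real_ else Inf } else (a * d) / (b * c)
  }
  list(or = or_val, p = p)
}

#' Build the seven meQTL-target CpG lists
#'
#' Four single-tissue lists (one per map) and three intersection lists of
#' the reference tissue with each other tissue. Intersections use the
#' harmonized (down-sampled, re-screened) reference maps; their target list
#' is the intersection of targets and their universe the CpGs tested in both
#' contributing screens.
#'
#' @param tissue_maps Named list of 4 `meqtl_map`s with `tested_cpgs` set;
#'   the first is the reference tissue.
#' @param harmonized_maps Named list (one per non-reference tissue) of
#'   reference maps re-screened at that tissue's size/parameters.
#' @return Named list of lists, each with `targets` and `universe`.
#' @export
build_target_lists <- function(tissue_maps, harmonized_maps) {
  if (is.null(names(tissue_maps))) mk_stop("tissue_maps must be named")
  ref <- names(tissue_maps)[1L]
  out <- list()
  for (ts in names(tissue_maps)) {
    m <- tissue_maps[[ts]]
    out[[ts]] <- list(targets = m$target_cpgs,
                      universe = m$tested_cpgs %||% m$target_cpgs)
  }
  for (ts in setdiff(names(tissue_maps), ref)) {
    h <- harmonized_maps[[ts]]
    if (is.null(h))
      mk_stop("missing harmonized reference map for intersection with '%s'", ts)
    other <- tissue_maps[[ts]]
    targets <- intersect(h$target_cpgs, other$target_cpgs)
    if (length(targets) == 0L)
      mk_log("empty intersection target list for %s-%s", ref, ts)
    universe <- intersect(h$tested_cpgs %||% h$target_cpgs,
                          other$tested_cpgs %||% other$target_cpgs)
    out[[paste(ref, ts, sep = "_x_")]] <- list(targets = targets,
                                               universe = universe)
  }
  out
}

#' Down-sample a reference screen for a harmonized comparison
#'
#' Subsamples `target_n` samples without replacement (seeded), re-runs the
#' cis query at the other tissue's parameters, calibrates the FDR threshold
#' on a chromosome subset, and applies the threshold genome-wide.
#'
#' @param genotypes,methylation,covariates Full reference data
#'   (sample-aligned).
#' @param target_n Sample size of the other tissue.
#' @param other_params `query_params` of the other tissue's screen.
#' @param fdr_level FDR level for the threshold (default 0.05).
#' @param seed Integer seed for the subsample and permutations.
#' @param chrom_subset Chromosomes used for FDR calibration
#'   (default `as.character(1:6)`).
#' @param n_perm Permutations for the FDR calibration (default 100).
#' @param p_grid Candidate threshold grid (see [permutation_fdr()]).
#' @return A `meqtl_map` with provenance recording `target_n` and `seed`.
#' @export
harmonized_downsample <- function(genotypes, methylation, covariates,
                                  target_n, other_params, fdr_level = 0.05,
                                  seed = 1L,
                                  chrom_subset = as.character(1:6),
                                  n_perm = 100L,
                                  p_grid = 10^seq(-12, -2, length.out = 40L)) {
  n <- nrow(genotypes$dosage)
  if (target_n > n) mk_stop("target_n (%d) exceeds available samples (%d)",
                            target_n, n)
  set.seed(seed)
  keep <- sort(sample.int(n, target_n))
  g <- new_genotype_matrix(genotypes$dosage[keep, , drop = FALSE],
                           genotypes$snps)
  g$snps$maf <- snp_maf_from_dosage(g$dosage)
  m <- new_methylation_matrix(methylation$beta[keep, , drop = FALSE],
                              methylation$cpgs)
  m$cpgs$sd <- apply(m$beta, 2L, stats::sd)
  cv <- if (is.null(covariates)) NULL else covariates[keep, , drop = FALSE]
  q <- build_query(g, m, other_params)
  fit <- fit_meqtls(q$genotypes, q$methylation, cv, q$pairs)
  cal <- permutation_fdr(q$genotypes, q$methylation, cv, q$pairs,
                         n_perm = n_perm, p_grid = p_grid, seed = seed,
                         chrom_subset = intersect(chrom_subset,
                                                  unique(q$pairs$chrom)))
  p_o <- threshold_for_fdr(cal, fdr_level)
  build_meqtl_map(fit, p_o,
                  provenance = sprintf("harmonized(n=%d, seed=%d)", target_n,
                                       seed),
                  tested_cpgs = q$methylation$cpgs$cpg_id,
                  tested_snps = q$genotypes$snps$snp_id)
}

#' Run the regulatory-feature overlap battery
#'
#' For every (target list, feature) cell, two contrasts are available:
#' \describe{
#'   \item{targets_vs_nontargets}{meQTL-target CpGs vs non-target CpGs in
#'     the list's universe.}
#'   \item{disease_targets_vs_other_targets}{targets of disease SNPs (with
#'     proxies) vs targets of the remaining meQTL SNPs.}
#' }
#' The Bonferroni threshold is `alpha / (n_features x n_lists)`.
#'
#' @param target_lists Output of [build_target_lists()].
#' @param feature_tracks Named list of `feature_track`s.
#' @param cpg_meta data.table `cpg_id`, `chrom`, `pos` for every CpG
#'   appearing in a universe.
#' @param disease_target_cpgs Character vector: meQTL targets of disease
#'   SNPs (needed for the second contrast; NULL skips it).
#' @param alpha Family-wise level (default 0.05).
#' @param modes Contrast modes to run.
#' @return data.table: `list_name`, `feature`, `mode`, `a`, `b`, `c`, `d`,
#'   `or`, `p`, `bonferroni_sig`, with the threshold in attribute
#'   `"bonferroni_threshold"`.
#' @export
overlap_battery <- function(target_lists, feature_tracks, cpg_meta,
                            disease_target_cpgs = NULL, alpha = 0.05,
                            modes = c("targets_vs_nontargets",
                                      "disease_targets_vs_other_targets")) {
  if (length(target_lists) == 0L || length(feature_tracks) == 0L)
    mk_stop("need at least one target list and one feature track")
  cpg_meta <- as.data.table(cpg_meta)
  thr <- alpha / (length(feature_tracks) * length(target_lists))
  # precompute overlap flags once per track
  flags <- lapply(feature_tracks, function(tr) {
    setNames(annotate_overlap(cpg_meta, tr), cpg_meta$cpg_id)
  })
  rows <- vector("list", 0L)
  for (ln in names(target_lists)) {
    tl <- target_lists[[ln]]
    for (fn in names(feature_tracks)) {
      fl <- flags[[fn]]
      for (mode in modes) {
        if (mode == "targets_vs_nontargets") {
          grp1 <- tl$targets
          grp2 <- setdiff(tl$universe, tl$targets)
        } else {
          if (is.null(disease_target_cpgs)) next
          grp1 <- intersect(tl$targets, disease_target_cpgs)
          grp2 <- setdiff(tl$targets, disease_target_cpgs)
        }
        a <- sum(fl[grp1], na.rm = TRUE); b <- length(grp1) - a
        c_ <- sum(fl[grp2], na.rm = TRUE); d <- length(grp2) - c_
        if ((a + b) == 0L || (c_ + d) == 0L || (a + c_) == 0L ||
            (b + d) == 0L) {
          rows[[length(rows) + 1L]] <- data.table(
            list_name = ln, feature = fn, mode = mode,
            a = a, b = b, c = c_, d = d, or = NA_real_, p = NA_real_,
            bonferroni_sig = NA, note = "degenerate margin")
          next
        }
        ft <- fisher_2x2(a, b, c_, d)
        rows[[length(rows) + 1L]] <- data.table(
          list_name = ln, feature = fn, mode = mode,
          a = a, b = b, c = c_, d = d, or = ft$or, p = ft$p,
          bonferroni_sig = ft$p < thr, note = "")
      }
    }
  }
  out <- rbindlist(rows)
  attr(out, "bonferroni_threshold") <- thr
  out[]
}
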