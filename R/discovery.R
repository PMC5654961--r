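# Cis-meQTL discovery: query construction, additive-model regression via
# Frisch-Waugh residualization, permutation FDR, and map construction.

#' Build the cis query
#'
#' Applies the SNP MAF and CpG sd inclusion filters and enumerates all
#' same-chromosome SNP-CpG pairs within the window.
#'
#' @param genotypes A `genotype_matrix`.
#' @param methylation A `methylation_matrix` (sample-aligned with the
#'   genotypes; see [align_samples()]).
#' @param params A `query_params`.
#' @return A list: `genotypes`, `methylation` (filtered), and `pairs`, a
#'   data.table with `snp_id`, `cpg_id`, `chrom`, `snp_idx`, `cpg_idx`
#'   (columns of the filtered matrices) and `distance_bp`.
#' @export
build_query <- function(genotypes, methylation, params) {
  if (!identical(rownames(genotypes$dosage), rownames(methylation$beta)))
    mk_stop("genotypes and methylation are not sample-aligned")
  keep_s <- which(genotypes$snps$maf >= params$maf_min)
  keep_c <- which(methylation$cpgs$sd >= params$sd_cutoff)
  if (length(keep_s) == 0L)
    mk_stop("no SNPs pass maf_min = %g; relax the parameters", params$maf_min)
  if (length(keep_c) == 0L)
    mk_stop("no CpGs pass sd_cutoff = %g; relax the parameters", params$sd_cutoff)
  g <- new_genotype_matrix(genotypes$dosage[, keep_s, drop = FALSE],
                           genotypes$snps[keep_s])
  m <- new_methylation_matrix(methylation$beta[, keep_c, drop = FALSE],
                              methylation$cpgs[keep_c])
  pairs <- enumerate_cis_pairs(g$snps, m$cpgs, params$window_bp)
  if (nrow(pairs) == 0L)
    mk_stop("query yields zero SNP-CpG pairs; widen the window or relax filters")
  list(genotypes = g, methylation = m, pairs = pairs, params = params)
}

enumerate_cis_pairs <- function(snps, cpgs, window_bp) {
  out <- vector("list", 0L)
  for (ch in intersect(unique(snps$chrom), unique(cpgs$chrom))) {
    si <- which(snps$chrom == ch)
    ci <- which(cpgs$chrom == ch)
    cp <- cpgs$pos[ci]
    o <- order(cp)
    ci <- ci[o]; cp <- cp[o]
    lo <- findInterval(snps$pos[si] - window_bp - 0.5, cp)
    hi <- findInterval(snps$pos[si] + window_bp + 0.5, cp)
    n_per <- hi - lo
    if (sum(n_per) == 0L) next
    srep <- rep(si, n_per)
    cidx <- ci[unlist(lapply(which(n_per > 0L),
                             function(k) (lo[k] + 1L):hi[k]))]
    out[[length(out) + 1L]] <- data.table(
      snp_idx = srep, cpg_idx = cidx, chrom = ch,
      snp_id = snps$snp_id[srep], cpg_id = cpgs$cpg_id[cidx],
      distance_bp = abs(snps$pos[srep] - cpgs$pos[cidx]))
  }
  if (length(out) == 0L)
    return(data.table(snp_idx = integer(), cpg_idx = integer(),
                      chrom = character(), snp_id = character(),
                      cpg_id = character(), distance_bp = integer()))
  rbindlist(out)
}

# Design matrix for the covariate adjustment: intercept + PC1 + PC2 + sex.
covariate_design <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1L))
  need <- c("PC1", "PC2", "sex")
  if (!all(need %in% names(covariates)))
    mk_stop("covariates must have columns %s", paste(need, collapse = ", "))
  cbind(1, as.matrix(covariates[, need]))
}

# Residualize the columns of M against the design X (orthogonal projection).
residualize <- function(M, X, XtX_inv = NULL) {
  if (is.null(XtX_inv)) XtX_inv <- solve(crossprod(X))
  M - X %*% (XtX_inv %*% crossprod(X, M))
}

# Per-pair cross products sum(gr * yr) computed chromosome by chromosome so
# the dense crossprod stays small. Gr, Yr are residualized matrices.
pair_cross <- function(Gr, Yr, pairs) {
  sgy <- numeric(nrow(pairs))
  for (ch in unique(pairs$chrom)) {
    idx <- which(pairs$chrom == ch)
    su <- sort(unique(pairs$snp_idx[idx]))
    cu <- sort(unique(pairs$cpg_idx[idx]))
    M <- crossprod(Gr[, su, drop = FALSE], Yr[, cu, drop = FALSE])
    sgy[idx] <- M[cbind(match(pairs$snp_idx[idx], su),
                        match(pairs$cpg_idx[idx], cu))]
  }
  sgy
}

#' Fit additive-model meQTL regressions for a set of cis pairs
#'
#' For each pair, methylation beta (0-100) is regressed on additive dosage
#' plus intercept, the first two ancestry principal components and sex. The
#' per-pair fit uses Frisch-Waugh residualization, which is numerically
#' identical to the full OLS fit; with the three covariates the residual
#' degrees of freedom are `n - 5`.
#'
#' @param genotypes,methylation Sample-aligned, filtered matrices
#'   (from [build_query()]).
#' @param covariates data.frame with columns `PC1`, `PC2`, `sex` in sample
#'   order, or `NULL` for an intercept-only adjustment (df = n - 2).
#' @param pairs Pair table from [build_query()].
#' @return data.table of records: `snp_id`, `cpg_id`, `snp_chrom`, `snp_pos`,
#'   `cpg_chrom`, `cpg_pos`, `distance_bp`, `slope`, `se`, `t`, `p`. Pairs
#'   whose SNP has zero dosage variance are skipped (logged).
#' @export
fit_meqtls <- function(genotypes, methylation, covariates, pairs) {
  n <- nrow(genotypes$dosage)
  X <- covariate_design(covariates, n)
  df <- n - ncol(X) - 1L
  if (df < 1L) mk_stop("need at least %d samples for %d model parameters",
                       ncol(X) + 2L, ncol(X) + 1L)
  Gr <- residualize(genotypes$dosage, X)
  Yr <- residualize(methylation$beta, X)
  sgg <- colSums(Gr^2)[pairs$snp_idx]
  syy <- colSums(Yr^2)[pairs$cpg_idx]
  keep <- sgg > 1e-12
  if (!all(keep)) {
    mk_log("skipped %d pairs with zero genotype variance", sum(!keep))
    pairs <- pairs[keep]; sgg <- sgg[keep]; syy <- syy[keep]
  }
  sgy <- pair_cross(Gr, Yr, pairs)
  slope <- sgy / sgg
  rss <- pmax(syy - slope * sgy, 0)
  se <- sqrt(rss / df / sgg)
  t_stat <- ifelse(se > 0, slope / se, ifelse(slope != 0, Inf, 0))
  p <- 2 * pt(-abs(t_stat), df)
  degenerate <- is.infinite(t_stat)
  if (any(degenerate)) {
    mk_log("flagged %d pairs with zero residual variance", sum(degenerate))
    p[degenerate] <- .Machine$double.xmin
  }
  data.table(snp_id = pairs$snp_id, cpg_id = pairs$cpg_id,
             snp_chrom = pairs$chrom,
             snp_pos = genotypes$snps$pos[pairs$snp_idx],
             cpg_chrom = pairs$chrom,
             cpg_pos = methylation$cpgs$pos[pairs$cpg_idx],
             distance_bp = pairs$distance_bp,
             slope = slope, se = se, t = t_stat, p = p,
             degenerate = degenerate)
}

# Squared partial correlation per pair for one genotype matrix; used by the
# permutation engine where only threshold exceedance is needed.
pair_r2 <- function(Gr, Yr, pairs, sgg, syy) {
  sgy <- pair_cross(Gr, Yr, pairs)
  denom <- sgg * syy
  r2 <- ifelse(denom > 0, sgy^2 / denom, 0)
  pmin(r2, 1)
}

# Map two-sided p thresholds to squared-correlation thresholds at given df.
p_grid_to_r2 <- function(p_grid, df) {
  t_thr <- qt(p_grid / 2, df, lower.tail = FALSE)
  t_thr^2 / (df + t_thr^2)
}

#' Permutation-based FDR calibration for the cis screen
#'
#' The observed screen counts, for each candidate threshold `p_o`, the number
#' `N_obs` of distinct CpGs with at least one association at `p <= p_o`. Each
#' permutation applies one shared shuffle of the genotype sample labels (so
#' LD between SNPs is retained) while methylation and covariates stay fixed,
#' and counts `N_null` the same way. The estimated FDR at `p_o` is
#' `mean(N_null) / N_obs`.
#'
#' @param genotypes,methylation,covariates,pairs As in [fit_meqtls()].
#' @param n_perm Number of permutations (the screen design uses 100).
#' @param p_grid Ascending candidate thresholds; default 40 log-spaced points
#'   in \[1e-12, 1e-2\].
#' @param seed Integer seed for the permutations.
#' @param chrom_subset Optional chromosome subset: both observed and null
#'   counts are restricted to pairs on these chromosomes.
#' @param permute_covariates If TRUE the ancestry covariates are permuted
#'   together with the genotypes (default FALSE: they stay with methylation).
#' @return An `fdr_calibration`: data.table `grid` with `p_o`, `N_obs`,
#'   `mean_N_null`, `fdr` (NA where `N_obs` is 0), plus `n_perm` and `seed`.
#' @export
permutation_fdr <- function(genotypes, methylation, covariates, pairs,
                            n_perm = 100L,
                            p_grid = 10^seq(-12, -2, length.out = 40L),
                            seed = 1L, chrom_subset = NULL,
                            permute_covariates = FALSE) {
  if (n_perm < 1L) mk_stop("n_perm must be >= 1")
  if (is.unsorted(p_grid)) mk_stop("p_grid must be sorted ascending")
  if (!is.null(chrom_subset)) {
    pairs <- pairs[chrom %in% as.character(chrom_subset)]
    if (nrow(pairs) == 0L) mk_stop("no pairs on the requested chromosomes")
  }
  n <- nrow(genotypes$dosage)
  X <- covariate_design(covariates, n)
  df <- n - ncol(X) - 1L
  XtX_inv <- solve(crossprod(X))
  Yr <- residualize(methylation$beta, X, XtX_inv)
  syy <- colSums(Yr^2)[pairs$cpg_idx]
  r2_thr <- p_grid_to_r2(p_grid, df)

  # distinct CpGs with >= 1 association past each threshold; the per-CpG
  # pair index lists are precomputed once, the permutation loop only maxes
  cpg_groups <- split(seq_len(nrow(pairs)), pairs$cpg_idx)
  count_cpgs <- function(r2) {
    best <- vapply(cpg_groups, function(i) max(r2[i]), numeric(1))
    vapply(r2_thr, function(th) sum(best >= th), numeric(1))
  }

  Gr <- residualize(genotypes$dosage, X, XtX_inv)
  sgg <- colSums(Gr^2)[pairs$snp_idx]
  n_obs <- count_cpgs(pair_r2(Gr, Yr, pairs, sgg, syy))
  if (all(n_obs == 0L))
    mk_stop("N_obs is zero at every grid point; extend the grid")

  null_counts <- matrix(0, n_perm, length(p_grid))
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    if (permute_covariates) {
      Gp <- Gr[perm, , drop = FALSE]  # covariates travel with genotype
    } else {
      Gp <- residualize(genotypes$dosage[perm, , drop = FALSE], X, XtX_inv)
    }
    sgg_p <- colSums(Gp^2)[pairs$snp_idx]
    null_counts[b, ] <- count_cpgs(pair_r2(Gp, Yr, pairs, sgg_p, syy))
  }
  grid <- data.table(p_o = p_grid, N_obs = as.numeric(n_obs),
                     mean_N_null = colMeans(null_counts))
  grid[, fdr := ifelse(N_obs > 0, mean_N_null / N_obs, NA_real_)]
  structure(list(grid = grid[], n_perm = n_perm, seed = seed),
            class = "fdr_calibration")
}

#' @export
print.fdr_calibration <- function(x, ...) {
  cat(sprintf("fdr_calibration: %d grid points, %d permutations (seed %d)\n",
              nrow(x$grid), x$n_perm, x$seed))
  print(x$grid)
  invisible(x)
}

#' Find the p-value threshold controlling the FDR at a given level
#'
#' The empirical FDR curve need not be monotone in `p_o`; a pool-adjacent-
#' violators (isotonic, nondecreasing) adjustment is applied first, then the
#' largest grid `p_o` with adjusted FDR at or below `level` is returned.
#'
#' @param calibration An `fdr_calibration`.
#' @param level Target FDR (the screen design uses 0.10, 0.05, 0.01).
#' @return The selected `p_o`.
#' @export
threshold_for_fdr <- function(calibration, level) {
  g <- calibration$grid[!is.na(fdr)]
  if (nrow(g) == 0L) mk_stop("no grid point has a defined FDR")
  adj <- if (nrow(g) > 1L) isoreg(seq_len(nrow(g)), g$fdr)$yf else g$fdr
  ok <- which(adj <= level)
  if (length(ok) == 0L)
    mk_stop("no threshold attains FDR <= %g (minimum achievable: %.4g)",
            level, min(adj))
  g$p_o[max(ok)]
}

new_meqtl_map <- function(records, p_threshold, provenance,
                          tested_cpgs = NULL, tested_snps = NULL) {
  records <- as.data.table(records)
  snps <- unique(records$snp_id)
  cpgs <- unique(records$cpg_id)
  structure(list(records = records,
                 meqtl_snps = snps, target_cpgs = cpgs,
                 mean_targets_per_snp =
                   if (length(snps) > 0L) nrow(records) / length(snps) else NA_real_,
                 p_threshold = p_threshold, provenance = provenance,
                 tested_cpgs = tested_cpgs, tested_snps = tested_snps),
            class = "meqtl_map")
}

#' @export
print.meqtl_map <- function(x, ...) {
  cat(sprintf(
    "meqtl_map [%s]: %d associations, %d meQTL SNPs, %d target CpGs (mean %.2f targets/SNP), p <= %s\n",
    x$provenance %||% "unlabelled", nrow(x$records), length(x$meqtl_snps),
    length(x$target_cpgs),
    x$mean_targets_per_snp %||% NA_real_, format(x$p_threshold)))
  invisible(x)
}

#' Build a meQTL map at a significance threshold
#'
#' Retains records with `p <= p_o` (ties included) and derives the meQTL SNP
#' set, the target CpG set and the mean number of target CpGs per meQTL SNP.
#'
#' @param records Record table from [fit_meqtls()].
#' @param p_o Significance threshold in (0, 1].
#' @param provenance Label (e.g. tissue) carried with the map.
#' @param tested_cpgs,tested_snps Optional universes of CpGs/SNPs actually
#'   queried; used by downstream universe constructions.
#' @return A `meqtl_map`.
#' @export
build_meqtl_map <- function(records, p_o, provenance = NULL,
                            tested_cpgs = NULL, tested_snps = NULL) {
  if (p_o <= 0 || p_o > 1) mk_stop("p_o must be in (0, 1]")
  records <- as.data.table(records)
  sig <- records[p <= p_o]
  if (nrow(sig) == 0L) mk_log("meQTL map at p <= %g is empty", p_o)
  new_meqtl_map(sig, p_o, provenance, tested_cpgs, tested_snps)
}

#' Partition a SNP universe by cross-map meQTL membership
#'
#' @param maps Named list of `meqtl_map`s (>= 2).
#' @param common_universe Character vector of SNPs tested in all maps.
#' @return data.table with one row per membership pattern: logical columns
#'   per map name and `count`; counts sum to `length(common_universe)`.
#' @export
partition_snp_overlap <- function(maps, common_universe) {
  if (length(maps) < 2L) mk_stop("need at least 2 maps")
  if (is.null(names(maps)) || any(!nzchar(names(maps))))
    mk_stop("maps must be named")
  if (length(common_universe) == 0L) mk_stop("empty SNP universe")
  member <- vapply(maps, function(m) common_universe %in% m$meqtl_snps,
                   logical(length(common_universe)))
  member <- matrix(member, nrow = length(common_universe),
                   dimnames = list(NULL, names(maps)))
  pat <- as.data.table(member)[, .(count = .N), by = names(maps)]
  setorderv(pat, names(maps), order = -1L)
  pat[]
}
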