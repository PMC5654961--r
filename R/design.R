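# Study design: counting candidate tests, additive-model power, and
# hierarchical selection of the most permissive query parameters.

#' Construct cis-meQTL query parameters
#'
#' @param sd_cutoff Minimum per-CpG methylation standard deviation
#'   (beta units, 0-100 scale) for a CpG to be queried.
#' @param maf_min Minimum SNP minor allele frequency.
#' @param window_bp Maximum SNP-to-CpG distance in bp.
#' @return A `query_params` list.
#' @export
query_params <- function(sd_cutoff, maf_min, window_bp) {
  if (sd_cutoff < 0) mk_stop("sd_cutoff must be >= 0")
  if (maf_min <= 0 || maf_min > 0.5) mk_stop("maf_min must be in (0, 0.5]")
  if (window_bp <= 0) mk_stop("window_bp must be > 0")
  structure(list(sd_cutoff = sd_cutoff, maf_min = maf_min,
                 window_bp = as.numeric(window_bp)),
            class = "query_params")
}

#' Count candidate SNP-CpG regression tests
#'
#' A pair (SNP, CpG) is counted when both pass their inclusion filters
#' (`maf >= maf_min`, `sd >= sd_cutoff`), lie on the same chromosome, and
#' are within `window_bp` of each other.
#'
#' @param snp_meta data.table with `chrom`, `pos`, `maf`.
#' @param cpg_meta data.table with `chrom`, `pos`, `sd`.
#' @param params A `query_params`.
#' @return Integer count (0 for empty input).
#' @export
count_tests <- function(snp_meta, cpg_meta, params) {
  s <- as.data.table(snp_meta)[maf >= params$maf_min]
  cg <- as.data.table(cpg_meta)[sd >= params$sd_cutoff]
  if (nrow(s) == 0L || nrow(cg) == 0L) return(0L)
  total <- 0L
  for (ch in intersect(unique(s$chrom), unique(cg$chrom))) {
    sp <- sort(s[chrom == ch, pos])
    cp <- sort(cg[chrom == ch, pos])
    # per SNP, CpGs within window via binary search on the sorted positions
    lo <- findInterval(sp - params$window_bp - 0.5, cp)
    hi <- findInterval(sp + params$window_bp + 0.5, cp)
    total <- total + sum(hi - lo)
  }
  as.integer(total)
}

#' Power of the additive-model Wald test
#'
#' Two-sided normal-approximation power for detecting a per-allele effect on
#' a continuous trait, with genotype variance `2 maf (1 - maf)` under
#' Hardy-Weinberg equilibrium. The noncentrality is
#' `lambda = effect * sqrt(n * 2 maf (1 - maf)) / residual_sd` and
#' `power = Phi(lambda - z) + Phi(-lambda - z)` with `z = z_{1 - alpha/2}`.
#'
#' @param maf Minor allele frequency in (0, 0.5].
#' @param n_samples Sample size.
#' @param effect_per_allele Methylation difference per minor allele
#'   (beta units; default 5, i.e. a 5% difference).
#' @param residual_sd Residual standard deviation of the trait (beta units).
#' @param alpha Two-sided significance level.
#' @return Power in \[0, 1\].
#' @export
power_additive <- function(maf, n_samples, effect_per_allele = 5,
                           residual_sd, alpha) {
  if (any(maf <= 0 | maf > 0.5)) mk_stop("maf must be in (0, 0.5]")
  if (residual_sd <= 0) mk_stop("residual_sd must be > 0")
  stopifnot_scalar_prob(alpha, "alpha")
  lambda <- abs(effect_per_allele) *
    sqrt(n_samples * 2 * maf * (1 - maf)) / residual_sd
  z <- qnorm(1 - alpha / 2)
  pnorm(lambda - z) + pnorm(-lambda - z)
}

#' Select the most permissive passing query parameters
#'
#' Each candidate's Bonferroni alpha is `fwer / count_tests(candidate)` and
#' its power is evaluated at the candidate's own `maf_min` (the least-powered
#' admitted SNP). Among candidates reaching `target_power`, the winner is the
#' lexicographic optimum: smallest `sd_cutoff` (most CpGs), then smallest
#' `maf_min` (most SNPs), then largest `window_bp`.
#'
#' @param candidate_grid List of `query_params`.
#' @param snp_meta,cpg_meta Metadata tables (see [count_tests()]).
#' @param n_samples Sample size.
#' @param effect_per_allele Per-allele effect (beta units, default 5).
#' @param residual_sd Residual sd; defaults to each candidate's `sd_cutoff`
#'   when `NULL` is given a numeric value is required — supply one.
#' @param target_power Required power (default 0.8).
#' @param fwer Family-wise error rate for the Bonferroni alpha (default 0.05).
#' @return The selected `query_params`, with the evaluation table attached as
#'   attribute `"evaluation"`.
#' @export
select_params <- function(candidate_grid, snp_meta, cpg_meta, n_samples,
                          effect_per_allele = 5, residual_sd,
                          target_power = 0.8, fwer = 0.05) {
  if (length(candidate_grid) == 0L) mk_stop("candidate grid is empty")
  ev <- rbindlist(lapply(candidate_grid, function(q) {
    m <- count_tests(snp_meta, cpg_meta, q)
    pw <- if (m == 0L) NA_real_ else
      power_additive(q$maf_min, n_samples, effect_per_allele,
                     residual_sd, alpha = fwer / m)
    data.table(sd_cutoff = q$sd_cutoff, maf_min = q$maf_min,
               window_bp = q$window_bp, n_tests = m, power = pw)
  }))
  ev[, pass := !is.na(power) & power >= target_power]
  passing <- ev[pass == TRUE]
  if (nrow(passing) == 0L)
    mk_stop("no candidate reaches power %.2f (best achieved: %.3f)",
            target_power, max(ev$power, na.rm = TRUE))
  setorder(passing, sd_cutoff, maf_min, -window_bp)
  best <- query_params(passing$sd_cutoff[1L], passing$maf_min[1L],
                       passing$window_bp[1L])
  attr(best, "evaluation") <- ev[]
  best
}
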