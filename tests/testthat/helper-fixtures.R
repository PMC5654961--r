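# Fixture builders and independent brute-force oracles used across tests.
# Oracles are deliberately naive (double loops, full enumeration) and never
# share code with the implementation paths they check.

suppressMessages(mk_verbosity(0))

tiny_genotypes <- function(n = 6L, snps = NULL) {
  if (is.null(snps)) {
    snps <- data.table::data.table(
      snp_id = c("s1", "s2", "s3"), chrom = c("1", "1", "2"),
      pos = c(1000L, 5000L, 1000L), maf = NA_real_)
  }
  set.seed(42)
  d <- matrix(sample(0:2, n * nrow(snps), replace = TRUE), n, nrow(snps),
              dimnames = list(sprintf("sample%04d", 1:n), snps$snp_id))
  storage.mode(d) <- "numeric"
  af <- colMeans(d) / 2
  snps$maf <- pmin(af, 1 - af)
  meqtlkit:::new_genotype_matrix(d, snps)
}

rand_genotypes <- function(n, S, seed = 1L, n_chrom = 2L, maf = NULL) {
  set.seed(seed)
  if (is.null(maf)) maf <- runif(S, 0.05, 0.5)
  d <- sapply(maf, function(q) rbinom(n, 2L, q))
  storage.mode(d) <- "numeric"
  ids <- sprintf("snp%05d", seq_len(S))
  dimnames(d) <- list(sprintf("sample%04d", seq_len(n)), ids)
  snps <- data.table::data.table(
    snp_id = ids, chrom = as.character(rep_len(seq_len(n_chrom), S)),
    pos = as.integer(seq_len(S) * 1000L), maf = pmin(colMeans(d) / 2,
                                                     1 - colMeans(d) / 2))
  meqtlkit:::new_genotype_matrix(d, snps)
}

rand_methylation <- function(n, C, seed = 2L, n_chrom = 2L) {
  set.seed(seed)
  b <- matrix(runif(n * C, 10, 90), n, C)
  ids <- sprintf("cg%05d", seq_len(C))
  dimnames(b) <- list(sprintf("sample%04d", seq_len(n)), ids)
  cpgs <- data.table::data.table(
    cpg_id = ids, chrom = as.character(rep_len(seq_len(n_chrom), C)),
    pos = as.integer(seq_len(C) * 1500L + 500L),
    sd = apply(b, 2L, sd), snp_proximal = FALSE)
  meqtlkit:::new_methylation_matrix(b, cpgs)
}

# --- oracles -----------------------------------------------------------------

# full normal-equations OLS for one pair: y ~ 1 + g + covariates
ols_oracle <- function(g, y, covars = NULL) {
  X <- cbind(1, g)
  if (!is.null(covars)) X <- cbind(X, as.matrix(covars))
  bet <- solve(crossprod(X), crossprod(X, y))
  res <- y - X %*% bet
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  covb <- s2 * solve(crossprod(X))
  se <- sqrt(covb[2, 2])
  t <- bet[2] / se
  list(slope = bet[2], se = se, t = t, p = 2 * pt(-abs(t), df))
}

# brute-force double loop over all SNP-CpG pairs
count_tests_oracle <- function(snps, cpgs, sd_cutoff, maf_min, window) {
  n <- 0L
  for (i in seq_len(nrow(snps))) {
    if (snps$maf[i] < maf_min) next
    for (j in seq_len(nrow(cpgs))) {
      if (cpgs$sd[j] < sd_cutoff) next
      if (snps$chrom[i] == cpgs$chrom[j] &&
          abs(snps$pos[i] - cpgs$pos[j]) <= window) n <- n + 1L
    }
  }
  n
}

# two-sided Fisher p by full enumeration over tables with fixed margins,
# probability ordering with the documented 1e-7 relative tie tolerance
fisher_enum_oracle <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  xs <- max(0, k - n2):min(k, m)
  pr <- vapply(xs, function(x)
    exp(lchoose(m, x) + lchoose(n2, k - x) - lchoose(m + n2, k)), numeric(1))
  obs <- pr[match(a, xs)]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# greedy supervised pruning, direct restatement of the definition
prune_oracle <- function(snps, panel, r2_prune, window) {
  meta <- panel$snps[match(snps$snp_id, panel$snps$snp_id)]
  ord <- order(snps$p, meta$pos, meta$snp_id)
  state <- rep("unresolved", nrow(snps))
  for (k in ord) {
    if (state[k] != "unresolved") next
    state[k] <- "kept"
    for (j in seq_len(nrow(snps))) {
      if (state[j] != "unresolved") next
      if (meta$chrom[j] == meta$chrom[k] &&
          abs(meta$pos[j] - meta$pos[k]) <= window) {
        gi <- panel$dosage[, meta$snp_id[k]]
        gj <- panel$dosage[, meta$snp_id[j]]
        if (var(gi) > 0 && var(gj) > 0 && cor(gi, gj)^2 > r2_prune)
          state[j] <- "removed"
      }
    }
  }
  snps$snp_id[state == "kept"]
}

# nearest gene by linear scan
nearest_gene_oracle <- function(pos, chr, genes) {
  g <- genes[genes$chrom == chr, ]
  if (nrow(g) == 0L) return(NA_character_)
  d <- mapply(function(s, e) {
    if (pos >= s && pos <= e) 0 else min(abs(pos - s), abs(pos - e))
  }, g$start, g$end)
  g <- g[order(d, g$start), ]
  g$gene_id[1L]
}
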