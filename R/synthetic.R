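# Synthetic data with planted, parameterized structure: LD-blocked diploid
# genotypes (Gaussian copula), beta-valued methylation with planted additive
# SNP effects, GWAS p-values with a planted meQTL enrichment factor, feature
# tracks with planted target-CpG enrichment, and gene/GO annotations with
# non-uniform probes-per-gene.

#' Specify a simulation scenario
#'
#' Defaults describe the screen the package is designed for: a peripheral
#' blood-sized cohort (n = 339), a 5 beta-unit per-allele planted effect
#' (the design effect size), residual noise of 10 beta units, and LD blocks
#' of 10 SNPs with moderate within-block correlation.
#'
#' @param n_samples,n_snps,n_cpgs Problem dimensions.
#' @param n_chrom Number of chromosomes SNPs/CpGs are spread over.
#' @param block_size SNPs per LD block.
#' @param rho Latent AR(1) correlation within a block, in \[0, 1).
#' @param maf_range Range minor allele frequencies are drawn from.
#' @param pos_step Base-pair spacing between consecutive SNPs (CpGs are
#'   interleaved on the same grid, offset by half a step).
#' @param n_planted Number of planted SNP-CpG effects.
#' @param planted_slope Per-allele effect of planted pairs (beta units).
#' @param planted_window_bp Maximum planted SNP-CpG distance.
#' @param noise_sd Residual methylation noise (beta units).
#' @param covar_effects Effects of (PC1, PC2, sex) on methylation.
#' @param gwas_threshold GWAS p-value threshold `t`: disease SNPs receive
#'   `p ~ U(0, t)`, all others `p ~ U(0, 1)`.
#' @param enrichment_factor Planted meQTL enrichment factor `f >= 1` of the
#'   disease SNP set relative to stratum baselines.
#' @param n_disease Size of the disease SNP set.
#' @param feature_odds Planted odds ratio of feature coverage for target vs
#'   non-target CpGs.
#' @param feature_p0 Baseline feature coverage of non-target CpGs.
#' @param probes_per_gene Function `n -> integer vector` drawing the number
#'   of CpG probes per gene (non-uniform by default).
#' @param n_go_terms,go_term_size Size of the GO term map.
#' @param go_enrichment Weight multiplier drawing target genes into the one
#'   planted GO term.
#' @param seed Integer seed; every generator consumes it deterministically.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(n_samples = 339L, n_snps = 600L, n_cpgs = 600L,
                          n_chrom = 2L, block_size = 10L, rho = 0.8,
                          maf_range = c(0.05, 0.5), pos_step = 2000L,
                          n_planted = 200L, planted_slope = 5,
                          planted_window_bp = 30000L, noise_sd = 10,
                          covar_effects = c(PC1 = 2, PC2 = 2, sex = 2),
                          gwas_threshold = 1e-4, enrichment_factor = 1,
                          n_disease = 200L,
                          feature_odds = 1, feature_p0 = 0.2,
                          probes_per_gene = function(n) 1L + stats::rnbinom(n, size = 2, mu = 3),
                          n_go_terms = 50L, go_term_size = 15L,
                          go_enrichment = 8,
                          seed = 1L) {
  if (rho >= 1 || rho < 0) mk_stop("rho must be in [0, 1)")
  if (enrichment_factor < 1) mk_stop("enrichment_factor must be >= 1")
  structure(as.list(environment()), class = "scenario_spec")
}

#' Simulate LD-blocked diploid genotypes
#'
#' Gaussian-copula model: within each block of `block_size` SNPs, latent
#' normals follow an AR(1) process with parameter `rho`; each haplotype's
#' minor-allele indicator is the latent variable thresholded at the SNP's
#' MAF quantile, and the dosage is the sum of two independent haplotypes
#' (Hardy-Weinberg by construction). Blocks are independent; positions are
#' evenly spaced; block boundaries are attached as attribute `"blocks"`.
#'
#' @param spec A `scenario_spec`.
#' @return A `genotype_matrix` with a `"blocks"` attribute
#'   (data.table `block_id`, `chrom`, `start`, `end` in 1-based bp).
#' @export
simulate_genotypes <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_samples; S <- spec$n_snps
  maf <- runif(S, spec$maf_range[1], spec$maf_range[2])
  block <- rep(seq_len(ceiling(S / spec$block_size)),
               each = spec$block_size)[seq_len(S)]
  latent <- function() {
    Z <- matrix(rnorm(n * S), n, S)
    for (j in 2:S) {
      if (block[j] == block[j - 1L])
        Z[, j] <- spec$rho * Z[, j - 1L] + sqrt(1 - spec$rho^2) * Z[, j]
    }
    Z
  }
  thr <- qnorm(maf)
  hap1 <- sweep(latent(), 2L, thr, `<`)
  hap2 <- sweep(latent(), 2L, thr, `<`)
  dosage <- hap1 + hap2
  storage.mode(dosage) <- "numeric"
  # layout: SNPs split evenly over chromosomes, never splitting a block
  per_chrom <- ceiling(max(block) / spec$n_chrom)
  chrom <- as.character((block - 1L) %/% per_chrom + 1L)
  pos <- integer(S)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos[idx] <- seq_along(idx) * spec$pos_step
  }
  snp_id <- sprintf("snp%05d", seq_len(S))
  rownames(dosage) <- sprintf("sample%04d", seq_len(n))
  colnames(dosage) <- snp_id
  snps <- data.table(snp_id = snp_id, chrom = chrom, pos = pos,
                     maf = snp_maf_from_dosage(dosage))
  g <- new_genotype_matrix(dosage, snps)
  blocks <- data.table(block_id = block, chrom = chrom, pos = pos)[
    , .(start = min(pos), end = max(pos)), by = .(block_id, chrom)]
  attr(g, "blocks") <- blocks[]
  g
}

# Pick cis planted pairs (same chromosome, within planted_window_bp).
plant_pairs <- function(snps, cpgs, spec) {
  if (spec$n_planted == 0L)
    return(data.table(snp_id = character(), cpg_id = character(),
                      slope = numeric()))
  cand <- enumerate_cis_pairs(snps, cpgs, spec$planted_window_bp)
  if (nrow(cand) == 0L) mk_stop("no cis candidates to plant effects on")
  # at most one planted SNP per CpG so planted effects do not stack
  cand <- cand[sample.int(nrow(cand))][!duplicated(cpg_idx)]
  take <- cand[seq_len(min(spec$n_planted, nrow(cand)))]
  if (nrow(take) < spec$n_planted)
    mk_log("only %d of %d requested planted pairs available", nrow(take),
           spec$n_planted)
  data.table(snp_id = take$snp_id, cpg_id = take$cpg_id,
             slope = spec$planted_slope)
}

#' Simulate methylation with planted additive SNP effects
#'
#' `y_ij = mu_j + sum(planted slope x dosage) + g1 PC1 + g2 PC2 + d sex + e`,
#' `e ~ N(0, noise_sd^2)`, `mu_j ~ U(20, 80)`; PCs standard normal, sex
#' Bernoulli(0.5). Values are clipped to \[0, 100\] (clip fraction logged,
#' warning if planted effects drive more than 5% of values to the bounds).
#'
#' @param genotypes A `genotype_matrix` from [simulate_genotypes()].
#' @param spec A `scenario_spec`.
#' @param planted_pairs Optional data.table `snp_id`, `cpg_id`, `slope`;
#'   by default `n_planted` cis pairs are drawn from the genotype layout.
#' @return List: `methylation` (a `methylation_matrix`), `covariates`
#'   (data.frame `sample_id`, `PC1`, `PC2`, `sex`), `planted`
#'   (the pair table used).
#' @export
simulate_methylation <- function(genotypes, spec, planted_pairs = NULL) {
  set.seed(spec$seed + 1L)
  n <- nrow(genotypes$dosage); C <- spec$n_cpgs
  snps <- genotypes$snps
  # CpGs interleave the SNP grid, offset half a step
  cpg <- vector("list", 0L)
  for (ch in unique(snps$chrom)) {
    rng <- range(snps$pos[snps$chrom == ch])
    pos <- as.integer(seq(rng[1], rng[2], length.out = ceiling(C / length(unique(snps$chrom)))) +
                        spec$pos_step %/% 2L)
    cpg[[ch]] <- data.table(chrom = ch, pos = pos)
  }
  cpgs <- rbindlist(cpg)[seq_len(C)]
  cpgs[, cpg_id := sprintf("cg%05d", seq_len(.N))]
  planted <- planted_pairs %||% plant_pairs(snps, cpgs, spec)

  mu <- runif(C, 20, 80)
  pc1 <- rnorm(n); pc2 <- rnorm(n); sex <- rbinom(n, 1L, 0.5)
  eff <- spec$covar_effects
  Y <- matrix(rep(mu, each = n), n, C) +
    outer(eff[["PC1"]] * pc1 + eff[["PC2"]] * pc2 + eff[["sex"]] * sex,
          rep(1, C)) +
    matrix(rnorm(n * C, 0, spec$noise_sd), n, C)
  if (nrow(planted) > 0L) {
    si <- match(planted$snp_id, snps$snp_id)
    ci <- match(planted$cpg_id, cpgs$cpg_id)
    for (k in seq_len(nrow(planted)))
      Y[, ci[k]] <- Y[, ci[k]] + planted$slope[k] * genotypes$dosage[, si[k]]
  }
  n_clip <- sum(Y < 0 | Y > 100)
  if (n_clip > 0L) {
    frac <- n_clip / length(Y)
    mk_log("clipped %.3f%% of methylation values to [0, 100]", 100 * frac)
    if (frac > 0.05)
      warning(sprintf("planted effects drive %.1f%% of values to the clip bounds",
                      100 * frac))
    Y <- pmin(pmax(Y, 0), 100)
  }
  rownames(Y) <- rownames(genotypes$dosage)
  colnames(Y) <- cpgs$cpg_id
  cpgs_meta <- data.table(cpg_id = cpgs$cpg_id, chrom = cpgs$chrom,
                          pos = cpgs$pos, sd = apply(Y, 2L, stats::sd),
                          snp_proximal = FALSE)
  covars <- data.frame(sample_id = rownames(Y), PC1 = pc1, PC2 = pc2,
                       sex = sex)
  list(methylation = new_methylation_matrix(Y, cpgs_meta),
       covariates = covars, planted = planted)
}

#' Simulate GWAS summary statistics with a planted meQTL enrichment
#'
#' A disease SNP set is chosen, stratified so that within each stratum the
#' meQTL proportion among disease SNPs equals `f` times the stratum baseline
#' (capped at 1). Disease SNPs receive `p ~ U(0, t)`; all other SNPs
#' `p ~ U(0, 1)`.
#'
#' @param snp_meta data.table `snp_id`, `chrom`, `pos`, `maf`.
#' @param meqtl_truth Character vector of SNP ids that are true meQTLs.
#' @param spec A `scenario_spec` (uses `enrichment_factor`, `n_disease`,
#'   `gwas_threshold`, `seed`).
#' @param strata Optional factor/character per SNP (e.g. from
#'   [stratify_snps()]); default puts every SNP in one stratum.
#' @return List: `gwas` (data.table `snp_id`, `chrom`, `pos`, `p`, `maf`),
#'   `disease_snps` (character).
#' @export
simulate_gwas <- function(snp_meta, meqtl_truth, spec, strata = NULL) {
  set.seed(spec$seed + 2L)
  snp_meta <- as.data.table(snp_meta)
  S <- nrow(snp_meta)
  strata <- as.character(strata %||% rep("all", S))
  is_meqtl <- snp_meta$snp_id %in% meqtl_truth
  f <- spec$enrichment_factor
  # allocate disease slots across strata proportional to stratum size
  tab <- table(strata)
  alloc <- round(spec$n_disease * as.numeric(tab) / S)
  names(alloc) <- names(tab)
  disease <- character(0)
  for (s in names(alloc)) {
    nd <- alloc[[s]]
    if (nd == 0L) next
    in_s <- which(strata == s)
    base <- mean(is_meqtl[in_s])
    if (f * base > 1 + 1e-9)
      mk_stop("enrichment factor %g infeasible in stratum '%s' (baseline %.3f)",
              f, s, base)
    target_prop <- min(1, f * base)
    k <- round(nd * target_prop)
    pool_m <- snp_meta$snp_id[in_s][is_meqtl[in_s]]
    pool_o <- snp_meta$snp_id[in_s][!is_meqtl[in_s]]
    if (k > length(pool_m) || (nd - k) > length(pool_o))
      mk_stop("enrichment factor %g infeasible in stratum '%s'", f, s)
    disease <- c(disease,
                 sample(pool_m, k),
                 sample(pool_o, nd - k))
  }
  p <- runif(S)
  di <- snp_meta$snp_id %in% disease
  p[di] <- runif(sum(di), 0, spec$gwas_threshold)
  gwas <- data.table(snp_id = snp_meta$snp_id, chrom = snp_meta$chrom,
                     pos = snp_meta$pos, p = p, maf = snp_meta$maf)
  list(gwas = gwas, disease_snps = disease)
}

#' Simulate feature, gene, and GO annotations with planted enrichment
#'
#' The feature track covers target CpGs with probability `p1` and the rest
#' with `p0`, where `odds(p1)/odds(p0) = feature_odds`. Genes tile each
#' chromosome contiguously over the CpGs with a non-uniform number of probes
#' per gene; one GO term is planted enriched in genes carrying target CpGs.
#'
#' @param cpg_meta data.table `cpg_id`, `chrom`, `pos`.
#' @param target_truth Character vector of meQTL-target CpG ids.
#' @param spec A `scenario_spec`.
#' @return List: `track` (a `feature_track`), `genes` (data.table),
#'   `go_terms` (data.table `term_id`, `term_name`, `gene_id`),
#'   `planted_term` (the enriched term id).
#' @export
simulate_annotations <- function(cpg_meta, target_truth, spec) {
  set.seed(spec$seed + 3L)
  cpg_meta <- as.data.table(cpg_meta)
  is_target <- cpg_meta$cpg_id %in% target_truth
  p0 <- spec$feature_p0
  odds1 <- spec$feature_odds * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)
  covered <- runif(nrow(cpg_meta)) < ifelse(is_target, p1, p0)
  iv <- cpg_meta[covered]
  b <- pos1_to_bed0(iv$pos)
  track <- new_feature_track("synthetic_feature",
                             data.table(chrom = iv$chrom, start = b[, "start"],
                                        end = b[, "end"]))
  # genes tile consecutive CpGs per chromosome
  genes_list <- vector("list", 0L)
  gene_of_cpg <- character(nrow(cpg_meta))
  gid <- 0L
  for (ch in unique(cpg_meta$chrom)) {
    idx <- which(cpg_meta$chrom == ch)
    idx <- idx[order(cpg_meta$pos[idx])]
    left <- length(idx)
    sizes <- integer(0)
    while (sum(sizes) < left) sizes <- c(sizes, spec$probes_per_gene(1L))
    sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - left)
    ends <- cumsum(sizes); starts <- c(1L, head(ends, -1L) + 1L)
    for (k in seq_along(sizes)) {
      gid <- gid + 1L
      members <- idx[starts[k]:ends[k]]
      gene_of_cpg[members] <- sprintf("gene%04d", gid)
      pr <- range(cpg_meta$pos[members])
      genes_list[[gid]] <- data.table(
        gene_id = sprintf("gene%04d", gid), chrom = ch,
        start = pr[1], end = pr[2],
        biotype = sample(c("protein_coding", "lincRNA", "miRNA"), 1L,
                         prob = c(0.9, 0.05, 0.05)))
    }
  }
  genes <- rbindlist(genes_list)
  target_genes <- unique(gene_of_cpg[is_target])
  # GO terms: uniform draws, except one planted term weighted toward genes
  # that carry target CpGs
  all_genes <- genes$gene_id
  terms <- vector("list", spec$n_go_terms)
  for (tt in seq_len(spec$n_go_terms)) {
    w <- rep(1, length(all_genes))
    if (tt == 1L) w[all_genes %in% target_genes] <- spec$go_enrichment
    m <- sample(all_genes, min(spec$go_term_size, length(all_genes)),
                prob = w / sum(w))
    terms[[tt]] <- data.table(term_id = sprintf("GO:%07d", tt),
                              term_name = sprintf("synthetic process %d", tt),
                              gene_id = m)
  }
  list(track = track, genes = genes[], go_terms = rbindlist(terms),
       planted_term = "GO:0000001", gene_of_cpg = gene_of_cpg)
}

#' Scenario registry: write a full input bundle to disk
#'
#' Known scenarios: `"null"` (no planted structure anywhere),
#' `"planted_meqtl"` (planted SNP-CpG effects), `"planted_enrichment"`
#' (disease SNPs enriched for meQTL status, factor 2),
#' `"planted_feature"` (feature odds 3 for target CpGs), and `"planted_go"`
#' (one GO term enriched in target genes). All files use the dialects read
#' by the package readers; a `manifest.txt` records the scenario, seed and
#' planted parameters.
#'
#' @param name Scenario name (see above).
#' @param dir Output directory (created).
#' @param seed Integer seed.
#' @param spec Optional `scenario_spec` overriding the registry defaults.
#' @return Invisibly, a list with the in-memory objects and file paths.
#' @export
make_scenario <- function(name, dir, seed = 1L, spec = NULL) {
  registry <- c("null", "planted_meqtl", "planted_enrichment",
                "planted_feature", "planted_go")
  if (!name %in% registry)
    mk_stop("unknown scenario '%s'; known: %s", name,
            paste(registry, collapse = ", "))
  if (is.null(spec)) {
    spec <- switch(name,
      null = scenario_spec(n_planted = 0L, seed = seed),
      planted_meqtl = scenario_spec(seed = seed),
      planted_enrichment = scenario_spec(n_snps = 5000L, n_cpgs = 1000L,
                                         n_planted = 0L, n_chrom = 4L,
                                         enrichment_factor = 2, seed = seed),
      planted_feature = scenario_spec(feature_odds = 3, seed = seed),
      planted_go = scenario_spec(go_enrichment = 8, seed = seed))
  } else {
    spec$seed <- seed
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- simulate_genotypes(spec)
  sim <- simulate_methylation(g, spec)

  # truth used for GWAS/annotation planting
  if (name == "planted_enrichment") {
    # meQTL status assigned directly with stratum-dependent baseline so that
    # matched-null testing is non-trivial
    set.seed(spec$seed + 9L)
    base_p <- 0.1 + 0.3 * (g$snps$maf - min(g$snps$maf)) /
      diff(range(g$snps$maf))
    meqtl_truth <- g$snps$snp_id[runif(nrow(g$snps)) < base_p]
    target_truth <- character(0)
  } else {
    meqtl_truth <- unique(sim$planted$snp_id)
    target_truth <- unique(sim$planted$cpg_id)
  }
  gw <- simulate_gwas(g$snps, meqtl_truth, spec)
  ann <- simulate_annotations(sim$methylation$cpgs, target_truth, spec)

  paths <- list(
    genotypes = file.path(dir, "genotypes.tsv"),
    methylation = file.path(dir, "methylation.tsv"),
    covariates = file.path(dir, "covariates.tsv"),
    gwas = file.path(dir, "gwas.tsv"),
    feature = file.path(dir, "feature.bed"),
    genes = file.path(dir, "genes.tsv"),
    go_terms = file.path(dir, "go_terms.tsv"),
    blocks = file.path(dir, "blocks.tsv"),
    planted = file.path(dir, "planted_pairs.tsv"),
    meqtl_truth = file.path(dir, "meqtl_truth.tsv"),
    manifest = file.path(dir, "manifest.txt"))
  write_genotypes(g, paths$genotypes)
  write_methylation(sim$methylation, paths$methylation)
  fwrite(sim$covariates, paths$covariates, sep = "\t")
  write_gwas(gw$gwas, paths$gwas)
  write_bed(ann$track, paths$feature)
  write_genes(ann$genes, paths$genes)
  fwrite(ann$go_terms, paths$go_terms, sep = "\t")
  fwrite(attr(g, "blocks"), paths$blocks, sep = "\t")
  fwrite(sim$planted, paths$planted, sep = "\t")
  fwrite(data.table(snp_id = meqtl_truth), paths$meqtl_truth, sep = "\t")
  manifest <- c(scenario = name, seed = seed,
                n_samples = spec$n_samples, n_snps = spec$n_snps,
                n_cpgs = spec$n_cpgs, n_planted = spec$n_planted,
                planted_slope = spec$planted_slope, noise_sd = spec$noise_sd,
                enrichment_factor = spec$enrichment_factor,
                feature_odds = spec$feature_odds,
                go_enrichment = spec$go_enrichment,
                gwas_threshold = spec$gwas_threshold)
  writeLines(paste(names(manifest), manifest, sep = "="), paths$manifest)
  invisible(list(spec = spec, genotypes = g, methylation = sim$methylation,
                 covariates = sim$covariates, planted = sim$planted,
                 gwas = gw$gwas, disease_snps = gw$disease_snps,
                 meqtl_truth = meqtl_truth, annotations = ann,
                 blocks = attr(g, "blocks"), paths = paths))
}
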