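test_that("genotype simulator: dosage range, HWE, determinism", {
  spec <- scenario_spec(n_samples = 1000L, n_snps = 60L, seed = 9L)
  g <- simulate_genotypes(spec)
  expect_true(all(g$dosage %in% 0:2))
  expect_identical(simulate_genotypes(spec)$dosage, g$dosage)
  expect_false(identical(simulate_genotypes(scenario_spec(
    n_samples = 1000L, n_snps = 60L, seed = 10L))$dosage, g$dosage))

  # HWE: genotype frequencies within 3 binomial SEs of (1-q)^2, 2q(1-q), q^2
  q <- g$snps$maf
  for (j in seq_len(10L)) {
    d <- g$dosage[, j]
    exp_f <- c((1 - q[j])^2, 2 * q[j] * (1 - q[j]), q[j]^2)
    obs_f <- c(mean(d == 0), mean(d == 1), mean(d == 2))
    se <- sqrt(exp_f * (1 - exp_f) / 1000)
    expect_true(all(abs(obs_f - exp_f) <= 3 * se + 1e-9))
  }
})

test_that("copula LD: independence at rho = 0, strong r2 at rho = 0.99", {
  g0 <- simulate_genotypes(scenario_spec(n_samples = 500L, n_snps = 20L,
                                         rho = 0, seed = 2L))
  r <- cor(g0$dosage)
  expect_lt(max(abs(r[upper.tri(r)])), 0.15)

  g1 <- simulate_genotypes(scenario_spec(n_samples = 500L, n_snps = 20L,
                                         block_size = 10L, rho = 0.99,
                                         maf_range = c(0.3, 0.3), seed = 2L))
  # adjacent SNPs within one block
  expect_gt(cor(g1$dosage[, 1], g1$dosage[, 2])^2, 0.5)
  expect_error(scenario_spec(rho = 1), "rho")
})

test_that("empirical MAF concentrates on its target", {
  g <- simulate_genotypes(scenario_spec(n_samples = 2000L, n_snps = 30L,
                                        maf_range = c(0.3, 0.3), seed = 5L))
  expect_true(all(abs(g$snps$maf - 0.3) <= 0.03))
})

test_that("noiseless planted effect shifts genotype classes by the slope", {
  spec <- scenario_spec(n_samples = 30L, n_snps = 4L, n_cpgs = 4L,
                        noise_sd = 1e-9, covar_effects = c(PC1 = 0, PC2 = 0, sex = 0),
                        n_planted = 0L, seed = 3L)
  g <- simulate_genotypes(spec)
  planted <- data.table::data.table(snp_id = g$snps$snp_id[1L],
                                    cpg_id = "cg00001", slope = 5)
  sim <- simulate_methylation(g, spec, planted_pairs = planted)
  y <- sim$methylation$beta[, "cg00001"]
  d <- g$dosage[, 1L]
  cls <- tapply(y, d, mean)
  expect_equal(as.numeric(diff(cls)), c(5, 5), tolerance = 1e-6)
})

test_that("planted slope estimates follow the analytic sampling distribution", {
  # analytic se = noise_sd / sqrt(n * 2 maf (1 - maf)); 200 replicates
  spec0 <- scenario_spec(n_samples = 339L, n_snps = 2L, n_cpgs = 2L,
                         n_planted = 0L, noise_sd = 10, seed = 1L,
                         maf_range = c(0.3, 0.3))
  g <- simulate_genotypes(spec0)
  planted <- data.table::data.table(snp_id = g$snps$snp_id[1L],
                                    cpg_id = "cg00001", slope = 5)
  est <- vapply(1:200, function(r) {
    sp <- spec0; sp$seed <- 1000L + r
    sim <- simulate_methylation(g, sp, planted_pairs = planted)
    ols_oracle(g$dosage[, 1L], sim$methylation$beta[, "cg00001"],
               cbind(sim$covariates$PC1, sim$covariates$PC2,
                     sim$covariates$sex))$slope
  }, numeric(1))
  se_ana <- 10 / sqrt(sum((g$dosage[, 1] - mean(g$dosage[, 1]))^2))
  expect_lt(abs(mean(est) - 5), 3 * se_ana / sqrt(200))
  expect_gt(sd(est) / se_ana, 0.8)
  expect_lt(sd(est) / se_ana, 1.25)
})

test_that("global null: regression p-values are uniform (KS)", {
  sc <- make_scenario("null", tempfile("sc"), seed = 17L)
  q <- build_query(sc$genotypes, sc$methylation, query_params(0, 0.05, 30000))
  fit <- fit_meqtls(q$genotypes, q$methylation, sc$covariates, q$pairs)
  expect_gt(nrow(fit), 10000L)
  # KS assumes independent observations; cis pairs sharing a SNP, a CpG or an
  # LD block are dependent, so the test runs on one pair per (LD block, CpG)
  blk <- (match(fit$snp_id, sc$genotypes$snps$snp_id) - 1L) %/%
    sc$spec$block_size
  indep <- fit[!duplicated(blk)][!duplicated(cpg_id)]
  expect_gt(nrow(indep), 30L)
  ks <- suppressWarnings(stats::ks.test(indep$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  # marginal calibration on the full pair set
  expect_lt(abs(mean(fit$p < 0.05) - 0.05), 0.02)
})

test_that("simulate_gwas plants the requested enrichment", {
  spec <- scenario_spec(n_snps = 2000L, n_disease = 300L,
                        enrichment_factor = 1, seed = 21L)
  snps <- data.table::data.table(snp_id = sprintf("s%04d", 1:2000),
                                 chrom = "1", pos = 1:2000 * 100L,
                                 maf = runif(2000, 0.05, 0.5))
  truth <- snps$snp_id[seq_len(400L)]  # baseline 0.2
  g1 <- simulate_gwas(snps, truth, spec)
  prop <- mean(g1$disease_snps %in% truth)
  se <- sqrt(0.2 * 0.8 / 300)
  expect_lt(abs(prop - 0.2), 2 * se + 1 / 300)

  spec2 <- spec; spec2$enrichment_factor <- 2
  g2 <- simulate_gwas(snps, truth, spec2)
  expect_lt(abs(mean(g2$disease_snps %in% truth) - 0.4), 2 * se + 1 / 300)

  # threshold recovers the planted set: all disease p < t, null p uniform
  expect_true(all(g2$gwas[snp_id %in% g2$disease_snps, p] < spec$gwas_threshold))
  null_p <- g2$gwas[!snp_id %in% g2$disease_snps, p]
  expect_lt(mean(null_p < spec$gwas_threshold), 0.01)

  spec3 <- spec; spec3$enrichment_factor <- 6  # 6 x 0.2 > 1 infeasible
  expect_error(simulate_gwas(snps, truth, spec3), "infeasible")
})

test_that("simulate_annotations plants feature odds and tiles genes", {
  cpgs <- data.table::data.table(cpg_id = sprintf("c%05d", 1:5000),
                                 chrom = as.character(rep(1:2, 2500)),
                                 pos = as.integer(1:5000 * 200L))
  truth <- cpgs$cpg_id[1:1000]
  spec <- scenario_spec(feature_odds = 3, seed = 8L)
  ann <- simulate_annotations(cpgs, truth, spec)
  ov <- annotate_overlap(cpgs, ann$track)
  tab <- table(target = cpgs$cpg_id %in% truth, covered = ov)
  or <- (tab[2, 2] * tab[1, 1]) / (tab[2, 1] * tab[1, 2])
  expect_gt(or, 2); expect_lt(or, 4.5)
  expect_true(all(nzchar(ann$gene_of_cpg)))  # every CpG in exactly one gene

  # null odds: Fisher CI covers 1 in most replicates
  cover <- vapply(1:40, function(r) {
    sp <- scenario_spec(feature_odds = 1, seed = 100L + r)
    a <- simulate_annotations(cpgs[1:1500], truth[1:300], sp)
    ovr <- annotate_overlap(cpgs[1:1500], a$track)
    ci <- stats::fisher.test(table(cpgs$cpg_id[1:1500] %in% truth, ovr))$conf.int
    ci[1] <= 1 && ci[2] >= 1
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("scenario registry: determinism, manifest, unknown name", {
  expect_error(make_scenario("nope", tempfile()), "null, planted_meqtl")
  d1 <- tempfile("a"); d2 <- tempfile("b")
  make_scenario("planted_enrichment", d1, seed = 4L)
  make_scenario("planted_enrichment", d2, seed = 4L)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  man <- readLines(file.path(d1, "manifest.txt"))
  expect_true("enrichment_factor=2" %in% man)
  d3 <- tempfile("c")
  make_scenario("planted_enrichment", d3, seed = 5L)
  expect_false(identical(readLines(file.path(d1, "gwas.tsv")),
                         readLines(file.path(d3, "gwas.tsv"))))
})
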