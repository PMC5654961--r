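test_that("annotate_overlap: conventions, chr normalization, brute force", {
  tr <- meqtlkit:::new_feature_track(
    "t", data.table::data.table(chrom = "chr1", start = 100L, end = 200L))
  cpgs <- data.table::data.table(cpg_id = c("a", "b", "c"), chrom = "1",
                                 pos = c(100L, 101L, 200L))
  # pos 100 -> 0-based 99, not in [100, 200); pos 101 -> 100, in; 200 -> in
  expect_equal(annotate_overlap(cpgs, tr), c(FALSE, TRUE, TRUE))

  set.seed(91)
  st <- sort(sample.int(1e6, 300))
  tr2 <- meqtlkit:::new_feature_track(
    "t2", data.table::data.table(chrom = "1", start = st,
                                 end = st + sample.int(400, 300)))
  cp2 <- data.table::data.table(cpg_id = sprintf("c%04d", 1:5000), chrom = "1",
                                pos = as.integer(sample.int(1e6, 5000)))
  got <- annotate_overlap(cp2, tr2)
  want <- vapply(cp2$pos, function(p) {
    any(p - 1L >= tr2$intervals$start & p - 1L < tr2$intervals$end)
  }, logical(1))
  expect_equal(got, want)
})

test_that("fisher_2x2: exact cases, symmetry, cmle flag, errors", {
  f <- fisher_2x2(10, 10, 10, 10)
  expect_equal(f$or, 1.0)
  expect_equal(f$p, 1.0)

  f2 <- fisher_2x2(12, 5, 7, 15)
  expect_equal(f2$p, fisher_enum_oracle(12, 5, 7, 15), tolerance = 1e-12)
  expect_equal(f2$or, 12 * 15 / (5 * 7))

  f3 <- fisher_2x2(5, 0, 0, 5)
  expect_equal(f3$or, Inf)
  expect_equal(f3$p, 2 / choose(10, 5), tolerance = 1e-12)

  # swapping the rows inverts the OR and preserves p
  a <- fisher_2x2(8, 3, 2, 9); b <- fisher_2x2(2, 9, 8, 3)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_equal(a$or, 1 / b$or, tolerance = 1e-12)

  cm <- fisher_2x2(12, 5, 7, 15, or = "cmle")
  expect_equal(cm$or,
               stats::fisher.test(matrix(c(12, 5, 7, 15), 2,
                                         byrow = TRUE))$estimate[[1]])
  expect_error(fisher_2x2(-1, 2, 3, 4), "nonnegative")
})

test_that("build_target_lists: singles plus harmonized intersections", {
  mk <- function(targets, universe, prov) meqtlkit:::new_meqtl_map(
    data.table::data.table(snp_id = paste0("s", seq_along(targets)),
                           cpg_id = targets, p = 1e-9),
    1e-8, prov, tested_cpgs = universe)
  uni <- sprintf("c%02d", 1:30)
  ref <- mk(uni[1:10], uni, "ref")
  oth <- mk(uni[6:14], uni[1:25], "oth")
  harm <- mk(uni[2:11], uni, "harm")
  lists <- build_target_lists(list(ref = ref, oth = oth),
                              list(oth = harm))
  expect_equal(sort(names(lists)), sort(c("ref", "oth", "ref_x_oth")))
  expect_setequal(lists$ref_x_oth$targets,
                  intersect(harm$target_cpgs, oth$target_cpgs))
  expect_setequal(lists$ref_x_oth$universe, uni[1:25])

  ident <- build_target_lists(list(ref = ref, oth = ref), list(oth = ref))
  expect_setequal(ident$ref_x_oth$targets, ref$target_cpgs)

  disj <- build_target_lists(list(ref = ref, oth = mk(uni[20:25], uni, "d")),
                             list(oth = ref))
  expect_length(disj$ref_x_oth$targets, 0L)
  expect_error(build_target_lists(list(ref = ref, oth = oth), list()),
               "harmonized")
})

test_that("harmonized_downsample with the full sample equals the reference", {
  spec <- scenario_spec(n_samples = 80L, n_snps = 200L, n_cpgs = 200L,
                        n_planted = 50L, seed = 92L)
  g <- simulate_genotypes(spec)
  sim <- simulate_methylation(g, spec)
  prm <- query_params(0, 0.05, 30000)
  q <- build_query(g, sim$methylation, prm)
  fit <- fit_meqtls(q$genotypes, q$methylation, sim$covariates, q$pairs)
  cal <- permutation_fdr(q$genotypes, q$methylation, sim$covariates, q$pairs,
                         n_perm = 30L, seed = 93L,
                         chrom_subset = c("1", "2"))
  ref <- build_meqtl_map(fit, threshold_for_fdr(cal, 0.05), "ref")
  hm <- harmonized_downsample(g, sim$methylation, sim$covariates,
                              target_n = 80L, other_params = prm,
                              seed = 93L, chrom_subset = c("1", "2"),
                              n_perm = 30L)
  expect_setequal(hm$target_cpgs, ref$target_cpgs)
  expect_equal(nrow(hm$records), nrow(ref$records))
  expect_error(harmonized_downsample(g, sim$methylation, sim$covariates,
                                     target_n = 81L, other_params = prm),
               "exceeds")
})

test_that("overlap_battery: contrasts, degenerate margins, planted recovery", {
  set.seed(94)
  cpgs <- data.table::data.table(cpg_id = sprintf("c%04d", 1:2000),
                                 chrom = "1", pos = as.integer(1:2000 * 100L))
  targets <- cpgs$cpg_id[1:500]
  spec <- scenario_spec(feature_odds = 3, seed = 95L)
  ann <- simulate_annotations(cpgs, targets, spec)
  lists <- list(tissue = list(targets = targets, universe = cpgs$cpg_id))
  res <- overlap_battery(lists, list(feat = ann$track), cpgs,
                         modes = "targets_vs_nontargets")
  expect_equal(nrow(res), 1L)
  expect_gt(res$or, 2); expect_lt(res$or, 4.5)
  expect_lt(res$p, 0.05)  # relaxed per-test alpha for the planted signal

  # feature covering every CpG: degenerate margin reported missing
  alltr <- meqtlkit:::new_feature_track(
    "all", data.table::data.table(chrom = "1", start = 0L, end = 500000L))
  res2 <- overlap_battery(lists, list(all = alltr), cpgs,
                          modes = "targets_vs_nontargets")
  expect_true(is.na(res2$p))
  expect_equal(res2$note, "degenerate margin")

  # second contrast uses disease targets vs other targets
  res3 <- overlap_battery(lists, list(feat = ann$track), cpgs,
                          disease_target_cpgs = targets[1:250])
  expect_setequal(res3$mode, c("targets_vs_nontargets",
                               "disease_targets_vs_other_targets"))
  b <- res3[res3$mode == "disease_targets_vs_other_targets", ]
  expect_equal(b$a + b$b, 250L)
})

test_that("null feature scenario: Fisher p < 0.05 near nominal rate", {
  set.seed(96)
  cpgs <- data.table::data.table(cpg_id = sprintf("c%04d", 1:800),
                                 chrom = "1", pos = as.integer(1:800 * 100L))
  targets <- cpgs$cpg_id[1:200]
  ps <- vapply(1:200, function(r) {
    spec <- scenario_spec(feature_odds = 1, seed = 1000L + r)
    ann <- simulate_annotations(cpgs, targets, spec)
    ov <- annotate_overlap(cpgs, ann$track)
    is_t <- cpgs$cpg_id %in% targets
    fisher_2x2(sum(is_t & ov), sum(is_t & !ov),
               sum(!is_t & ov), sum(!is_t & !ov))$p
  }, numeric(1))
  frac <- mean(ps < 0.05)
  # binomial 99% band around 0.05 at 200 replicates (Fisher is conservative,
  # so the lower edge sits at 0)
  expect_lte(frac, 0.05 + 2.58 * sqrt(0.05 * 0.95 / 200))
})
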