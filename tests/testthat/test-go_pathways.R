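test_that("snp-proximal flagging and target selection", {
  cpgs <- data.table::data.table(
    cpg_id = c("c1", "c2", "c3"), chrom = "1",
    pos = c(100L, 500L, 1000L),
    snp_proximal = c(FALSE, TRUE, FALSE))
  snps <- data.table::data.table(chrom = "1", pos = c(95L, 505L))
  expect_equal(flag_snp_proximal(cpgs, snps), c(TRUE, TRUE, FALSE))

  map <- meqtlkit:::new_meqtl_map(
    data.table::data.table(snp_id = c("s1", "s2", "s2"),
                           cpg_id = c("c1", "c2", "c3"), p = 1e-9), 1e-8, "t")
  sel <- select_asd_targets(map, "s1", cpgs)
  expect_equal(sel$selected, "c1")
  expect_setequal(sel$universe, c("c1", "c3"))  # c2 is snp_proximal

  # snp_proximal selection excluded entirely
  cpgs2 <- data.table::data.table(cpg_id = "c1", chrom = "1", pos = 100L,
                                  snp_proximal = TRUE)
  map2 <- meqtlkit:::new_meqtl_map(
    data.table::data.table(snp_id = "s1", cpg_id = "c1", p = 1e-9), 1e-8, "t")
  expect_error(select_asd_targets(map2, "s1", cpgs2), "no disease")
})

test_that("nearest-gene mapping: body, ties, oracle equivalence", {
  genes <- data.table::data.table(
    gene_id = c("A", "B"), chrom = "1", start = c(100L, 500L),
    end = c(200L, 700L), biotype = "protein_coding")
  cpgs <- data.table::data.table(
    cpg_id = c("in_body", "tie", "nearer_b"), chrom = "1",
    pos = c(150L, 350L, 480L))
  mp <- map_to_genes(cpgs$cpg_id, cpgs, genes)
  expect_equal(mp[mp$cpg_id == "in_body", ]$gene_id, "A")
  expect_equal(mp[mp$cpg_id == "in_body", ]$distance, 0)
  expect_equal(mp[mp$cpg_id == "tie", ]$gene_id, "A")   # 150 vs 150: smaller start
  expect_equal(mp[mp$cpg_id == "nearer_b", ]$gene_id, "B")

  set.seed(81)
  genes2 <- data.table::data.table(
    gene_id = sprintf("g%02d", 1:20), chrom = "1",
    start = as.integer(sort(sample.int(1e5, 20))), biotype = "protein_coding")
  genes2$end <- genes2$start + sample.int(2000, 20)
  cpgs2 <- data.table::data.table(cpg_id = sprintf("c%02d", 1:50), chrom = "1",
                                  pos = as.integer(sample.int(1e5, 50)))
  mp2 <- map_to_genes(cpgs2$cpg_id, cpgs2, genes2)
  for (k in seq_len(nrow(cpgs2))) {
    expect_equal(mp2$gene_id[mp2$cpg_id == cpgs2$cpg_id[k]],
                 nearest_gene_oracle(cpgs2$pos[k], "1", genes2))
  }
})

test_that("go_test: hypergeometric limit and degenerate term", {
  u <- data.table::data.table(gene_id = sprintf("g%02d", 1:30),
                              probe_count = 4L,
                              selected = c(rep(TRUE, 8), rep(FALSE, 22)))
  tm <- data.table::data.table(
    term_id = rep(c("T1", "T2"), c(6, 30)),
    term_name = "t",
    gene_id = c(sprintf("g%02d", c(1, 2, 3, 10, 11, 12)),
                sprintf("g%02d", 1:30)))
  res <- go_test(u, tm)
  x <- 3; m1 <- 6
  expect_equal(res[res$term_id == "T1", ]$p,
               phyper(x - 1, m1, 24, 8, lower.tail = FALSE), tolerance = 1e-9)
  expect_equal(res[res$term_id == "T2", ]$p, 1)
})

test_that("Wallenius recursion matches the integral route", {
  for (cfg in list(c(10, 40, 12, 2.5), c(5, 20, 8, 0.5), c(30, 70, 25, 4))) {
    for (x in c(1L, 3L, 5L)) {
      a <- meqtlkit:::wallenius_upper_tail(x, cfg[1], cfg[2], cfg[3], cfg[4])
      b <- meqtlkit:::wallenius_upper_tail_integral(x, cfg[1], cfg[2],
                                                    cfg[3], cfg[4])
      expect_equal(a, b, tolerance = 1e-5)
    }
  }
})

test_that("probe-count bias: Wallenius calibrated, hypergeometric is not", {
  # Terms preferentially contain high-probe-count genes; selection is
  # probe-count-biased but independent of term membership (null).
  # probe counts follow the generator default (1 + NB(size 2, mu 3)); heavier
  # within-class skew makes the two-class approximation conservative
  set.seed(82)
  n_genes <- 400L; n_terms <- 150L; n_sel <- 100L
  pw <- numeric(0); ph <- numeric(0)
  for (rep_i in 1:6) {
    probe <- 1L + stats::rnbinom(n_genes, size = 2, mu = 3)
    ids <- sprintf("g%04d", seq_len(n_genes))
    sel_idx <- sample(n_genes, n_sel, prob = probe)
    u <- data.table::data.table(gene_id = ids, probe_count = probe,
                                selected = seq_len(n_genes) %in% sel_idx)
    tm <- data.table::rbindlist(lapply(seq_len(n_terms), function(tt)
      data.table::data.table(term_id = sprintf("T%03d", tt), term_name = "t",
                             gene_id = sample(ids, 40L, prob = probe))))
    res <- go_test(u, tm)
    pw <- c(pw, res$p)
    # unweighted hypergeometric on the same data
    ph <- c(ph, vapply(unique(tm$term_id), function(tt) {
      g <- tm$gene_id[tm$term_id == tt]
      x <- sum(u$selected & u$gene_id %in% g)
      phyper(x - 1, length(g), n_genes - length(g), n_sel, lower.tail = FALSE)
    }, numeric(1)))
  }
  expect_gt(mean(pw < 0.05), 0.02)
  expect_lt(mean(pw < 0.05), 0.09)
  expect_gt(mean(ph < 0.05), 0.09)  # anti-conservative without the correction
})

test_that("overlap_filter: duplicates dropped, disjoint kept, greedy oracle", {
  res <- data.table::data.table(
    term_id = c("T1", "T2", "T3"), term_name = "t",
    n_selected_in_term = 3L, n_universe_in_term = 5L, odds = 1,
    p = c(0.001, 0.002, 0.01))
  tm <- data.table::data.table(
    term_id = rep(c("T1", "T2", "T3"), each = 4),
    gene_id = c(paste0("g", 1:4), paste0("g", 1:4), paste0("h", 1:4)))
  kept <- overlap_filter(res, tm)
  expect_setequal(kept$term_id, c("T1", "T3"))  # T2 duplicates T1
  expect_equal(kept$scaled_rank, c(1, 2) / 2)

  # greedy oracle on a 20-term random fixture
  set.seed(83)
  terms <- sprintf("T%02d", 1:20)
  tm2 <- data.table::rbindlist(lapply(terms, function(tt)
    data.table::data.table(term_id = tt,
                           gene_id = sample(sprintf("g%02d", 1:40), 8))))
  res2 <- data.table::data.table(term_id = terms, term_name = "t",
                                 n_selected_in_term = 1L,
                                 n_universe_in_term = 8L, odds = 1,
                                 p = sort(runif(20, 0, 0.049)))
  kept2 <- overlap_filter(res2, tm2)
  gl <- split(tm2$gene_id, tm2$term_id)
  keep_or <- character(0)
  for (tt in res2$term_id[order(res2$p)]) {
    ok <- TRUE
    for (kk in keep_or) {
      ov <- length(intersect(gl[[tt]], gl[[kk]])) /
        min(length(gl[[tt]]), length(gl[[kk]]))
      if (ov > 0.7) ok <- FALSE
    }
    if (ok) keep_or <- c(keep_or, tt)
  }
  expect_equal(kept2$term_id, keep_or)
})

test_that("scaled_rank_table: >=2-tissue rule, grouping and ordering", {
  mk <- function(ids, ps) {
    d <- data.table::data.table(term_id = ids, term_name = ids, p = ps)
    d$rank <- seq_along(ids); d$scaled_rank <- d$rank / length(ids)
    d
  }
  pt <- list(blood = mk(c("T1", "T2", "T3"), c(0.001, 0.002, 0.003)),
             cord = mk(c("T2", "T1"), c(0.001, 0.002)),
             brain = mk(c("T9", "T1"), c(0.01, 0.02)))
  tab <- scaled_rank_table(pt)
  expect_false("T9" %in% tab$term_id)  # single-tissue term excluded
  expect_true(all(c("T1", "T2") %in% tab$term_id))
  # T1 in all three tissues; T2 in blood+cord only
  expect_equal(tab[tab$term_id == "T1", ]$pattern, "blood+cord+brain")
  expect_equal(tab[tab$term_id == "T2", ]$pattern, "blood+cord")
  # within-group ordering by rank sum equals a brute-force sort
  g1 <- tab[tab$pattern == "blood+cord", ]
  expect_equal(g1$rank_sum, sort(g1$rank_sum))
  expect_error(scaled_rank_table(pt[1]), ">= 2")
})

test_that("planted GO term ranks first in most seeds", {
  hits <- vapply(1:20, function(s) {
    spec <- scenario_spec(n_cpgs = 600L, n_snps = 150L, n_planted = 60L,
                          go_enrichment = 8, seed = 200L + s)
    g <- simulate_genotypes(spec)
    sim <- simulate_methylation(g, spec)
    truth <- unique(sim$planted$cpg_id)
    ann <- simulate_annotations(sim$methylation$cpgs, truth, spec)
    mapping <- map_to_genes(sim$methylation$cpgs$cpg_id,
                            sim$methylation$cpgs, ann$genes)
    uni <- gene_universe(mapping, truth)
    res <- go_test(uni, ann$go_terms)
    res$term_id[1L] == ann$planted_term
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
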