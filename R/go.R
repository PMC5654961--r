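# GO analysis of meQTL-target CpGs: target selection, nearest-gene mapping,
# Wallenius probe-count bias correction, overlap-based term deduplication,
# and cross-tissue scaled-rank tables.

#' Flag CpGs with a SNP within 10 bp or at the single-base extension
#'
#' @param cpg_meta data.table `cpg_id`, `chrom`, `pos`.
#' @param snp_meta data.table `chrom`, `pos`.
#' @param dist_bp Proximity distance (default 10).
#' @return Logical vector along `cpg_meta`.
#' @export
flag_snp_proximal <- function(cpg_meta, snp_meta, dist_bp = 10L) {
  cpg_meta <- as.data.table(cpg_meta)
  snp_meta <- as.data.table(snp_meta)
  out <- rep(FALSE, nrow(cpg_meta))
  for (ch in unique(cpg_meta$chrom)) {
    ci <- which(cpg_meta$chrom == ch)
    sp <- sort(snp_meta[chrom == ch, pos])
    if (length(sp) == 0L) next
    lo <- findInterval(cpg_meta$pos[ci] - dist_bp - 0.5, sp)
    hi <- findInterval(cpg_meta$pos[ci] + dist_bp + 0.5, sp)
    out[ci] <- (hi - lo) > 0L
  }
  out
}

#' Select disease-related meQTL-target CpGs and the test universe
#'
#' The selection is every target CpG of a disease SNP (or proxy); the
#' universe is every meQTL-target CpG. Both exclude CpGs flagged
#' `snp_proximal` (a SNP within 10 bp or at the single-base extension),
#' which are known to distort functional enrichment.
#'
#' @param meqtl_map A `meqtl_map`.
#' @param disease_snps Character vector of disease SNPs plus proxies.
#' @param cpg_meta data.table with `cpg_id` and `snp_proximal`.
#' @return List: `selected`, `universe` (character vectors of CpG ids).
#' @export
select_asd_targets <- function(meqtl_map, disease_snps, cpg_meta) {
  cpg_meta <- as.data.table(cpg_meta)
  prox <- cpg_meta$cpg_id[cpg_meta$snp_proximal]
  universe <- setdiff(meqtl_map$target_cpgs, prox)
  rec <- meqtl_map$records
  selected <- setdiff(unique(rec$cpg_id[rec$snp_id %in% disease_snps]), prox)
  if (length(selected) == 0L)
    mk_stop("no disease-SNP meQTL targets selected; consider a more liberal threshold")
  list(selected = selected, universe = universe)
}

#' Map CpGs to their nearest gene
#'
#' Distance is 0 for a CpG inside the gene body, otherwise the distance to
#' the nearer boundary; ties go to the gene with the smaller start. CpGs on
#' chromosomes without genes are excluded (logged).
#'
#' @param cpg_ids Character vector (the universe).
#' @param cpg_meta data.table `cpg_id`, `chrom`, `pos`.
#' @param genes data.table `gene_id`, `chrom`, `start`, `end`.
#' @return data.table `cpg_id`, `gene_id`, `distance`.
#' @export
map_to_genes <- function(cpg_ids, cpg_meta, genes) {
  cpg_meta <- as.data.table(cpg_meta)[cpg_id %in% cpg_ids]
  genes <- as.data.table(genes)
  res <- vector("list", 0L)
  unmapped <- 0L
  for (ch in unique(cpg_meta$chrom)) {
    cm <- cpg_meta[chrom == ch]
    gs <- genes[chrom == ch]
    if (nrow(gs) == 0L) { unmapped <- unmapped + nrow(cm); next }
    setorder(gs, start)
    d <- outer(cm$pos, gs$start, function(p, s) s - p)     # left gap
    d2 <- outer(cm$pos, gs$end, function(p, e) p - e)      # right gap
    dist <- pmax(d, d2, 0)                                  # 0 inside body
    dim(dist) <- dim(d)
    j <- apply(dist, 1L, which.min)  # ties: smaller start (sorted)
    res[[length(res) + 1L]] <- data.table(
      cpg_id = cm$cpg_id, gene_id = gs$gene_id[j],
      distance = dist[cbind(seq_len(nrow(cm)), j)])
  }
  if (unmapped > 0L) mk_log("%d CpGs on gene-less chromosomes left unmapped",
                            unmapped)
  if (length(res) == 0L) mk_stop("no CpG could be mapped to a gene")
  rbindlist(res)
}

#' Build a gene universe for the bias-corrected GO test
#'
#' @param mapping data.table from [map_to_genes()] on the universe CpGs.
#' @param selected_cpgs Character vector of selected CpG ids.
#' @return data.table `gene_id`, `probe_count`, `selected`.
#' @export
gene_universe <- function(mapping, selected_cpgs) {
  mapping <- as.data.table(mapping)
  u <- mapping[, .(probe_count = .N,
                   selected = any(cpg_id %in% selected_cpgs)), by = gene_id]
  u[]
}

# Two-class Wallenius noncentral hypergeometric upper tail.
# Urn: m1 genes in the term (weight odds w), m2 outside (weight 1); n genes
# drawn one at a time without replacement, probability proportional to
# remaining weight. Exact O(n * m1) forward recursion on the count of
# in-term draws.
wallenius_upper_tail <- function(x_obs, m1, m2, n, odds) {
  if (x_obs <= 0L) return(1)
  x_max <- min(n, m1)
  if (x_obs > x_max) return(0)
  # forward recursion in log space is unnecessary: probabilities stay in
  # [0,1] and sum to 1 at every step
  prob <- c(1, rep(0, x_max))  # prob[x + 1] = P(X = x after k draws)
  for (k in seq_len(n)) {
    xs <- 0:min(k - 1L, x_max)
    w_in <- odds * (m1 - xs)
    w_out <- pmax(m2 - (k - 1L - xs), 0)
    tot <- w_in + w_out
    p_in <- ifelse(tot > 0, w_in / tot, 0)
    nxt <- rep(0, x_max + 1L)
    nxt[xs + 1L] <- prob[xs + 1L] * (1 - p_in)
    mv <- xs[xs < x_max]
    nxt[mv + 2L] <- nxt[mv + 2L] + prob[mv + 1L] * p_in[xs < x_max]
    prob <- nxt
  }
  sum(prob[(x_obs + 1L):(x_max + 1L)])
}

# Integral representation of the Wallenius pmf, for large universes.
# The raw form integrates (1 - t^(w/D))^x (1 - t^(1/D))^(n-x) over [0, 1],
# which concentrates near t = 0 when D is large; the substitution u = t^(1/D)
# yields the smooth integrand D u^(D-1) (1 - u^w)^x (1 - u)^(n-x).
wallenius_upper_tail_integral <- function(x_obs, m1, m2, n, odds) {
  if (n >= m1 + m2) return(if (x_obs <= m1) 1 else 0)  # full depletion
  pmf1 <- function(x) {
    d <- odds * (m1 - x) + (m2 - (n - x))
    f <- function(u) {
      exp(log(d) + (d - 1) * log(u) + x * log1p(-u^odds) +
            (n - x) * log1p(-u))
    }
    int <- integrate(f, 0, 1, rel.tol = 1e-9, subdivisions = 500L,
                     stop.on.error = FALSE)
    exp(lchoose(m1, x) + lchoose(m2, n - x)) * int$value
  }
  xs <- x_obs:min(n, m1)
  min(1, sum(vapply(xs, pmf1, numeric(1))))
}

#' Bias-corrected gene set test (Wallenius noncentral hypergeometric)
#'
#' Tests each term for over-representation among selected genes while
#' correcting for per-gene probe counts: a gene's chance of selection is
#' taken proportional to its probe count, so a term's odds parameter is the
#' mean probe count of its universe genes divided by the mean probe count of
#' the remaining universe genes. The exact recursion is used for universes
#' up to `exact_limit` genes, numeric integration beyond; when all probe
#' counts are equal the test reduces to the ordinary hypergeometric.
#'
#' @param universe data.table from [gene_universe()]:
#'   `gene_id`, `probe_count`, `selected`.
#' @param term_map data.table `term_id`, `term_name`, `gene_id`.
#' @param exact_limit Universe size limit for the exact recursion
#'   (default 2000).
#' @return data.table, one row per term with >= 1 universe gene:
#'   `term_id`, `term_name`, `n_selected_in_term`, `n_universe_in_term`,
#'   `odds`, `p`, sorted by ascending p (ties: term_id).
#' @export
go_test <- function(universe, term_map, exact_limit = 2000L) {
  universe <- as.data.table(universe)
  term_map <- as.data.table(term_map)
  if (any(universe$probe_count < 1L)) mk_stop("probe_count must be >= 1")
  n_sel <- sum(universe$selected)
  N <- nrow(universe)
  if (n_sel > N) mk_stop("more selected genes than universe genes")
  term_map <- term_map[gene_id %in% universe$gene_id]
  uniform <- length(unique(universe$probe_count)) == 1L
  res <- term_map[, {
    in_term <- universe$gene_id %in% gene_id
    m1 <- sum(in_term); m2 <- N - m1
    x <- sum(universe$selected & in_term)
    if (uniform || m2 == 0L) {
      pval <- phyper(x - 1L, m1, m2, n_sel, lower.tail = FALSE)
      w <- 1
    } else {
      w <- mean(universe$probe_count[in_term]) /
        mean(universe$probe_count[!in_term])
      pval <- if (N <= exact_limit)
        wallenius_upper_tail(x, m1, m2, n_sel, w)
      else wallenius_upper_tail_integral(x, m1, m2, n_sel, w)
    }
    .(term_name = term_name[1L], n_selected_in_term = x,
      n_universe_in_term = m1, odds = w, p = pval)
  }, by = term_id]
  setorder(res, p, term_id)
  res[]
}

#' Deduplicate GO terms by gene-list overlap
#'
#' Only nominally significant terms (p < `p_nominal`) are considered.
#' Iterating in ascending p order, a term is dropped when its gene list
#' overlaps a retained term by more than `threshold` of the smaller list.
#'
#' @param results data.table from [go_test()].
#' @param term_map data.table `term_id`, `gene_id` (full gene lists).
#' @param threshold Overlap fraction (default 0.70, strict >).
#' @param p_nominal Nominal significance gate (default 0.05).
#' @return The retained rows of `results`, with 1-based `rank` and
#'   `scaled_rank` = rank / number retained.
#' @export
overlap_filter <- function(results, term_map, threshold = 0.70,
                           p_nominal = 0.05) {
  results <- as.data.table(results)[p < p_nominal]
  term_map <- as.data.table(term_map)
  setorder(results, p, term_id)
  gl <- split(term_map$gene_id, term_map$term_id)
  kept <- character(0)
  for (tt in results$term_id) {
    g <- gl[[tt]]
    dup <- any(vapply(kept, function(k) {
      ov <- length(intersect(g, gl[[k]])) / min(length(g), length(gl[[k]]))
      ov > threshold
    }, logical(1)))
    if (!dup) kept <- c(kept, tt)
  }
  out <- results[term_id %in% kept]
  out[, rank := seq_len(.N)]
  out[, scaled_rank := rank / .N]
  out[]
}

#' Cross-tissue scaled-rank table
#'
#' Keeps terms retained in at least two tissues, groups them by the pattern
#' of tissues they appear in, and orders each group by the sum of the
#' available scaled ranks (ascending). Missing tissues show NA.
#'
#' @param per_tissue Named list of [overlap_filter()] outputs.
#' @return data.table: `term_id`, `term_name`, one `scaled_rank_<tissue>`
#'   column per tissue, `pattern`, `rank_sum`.
#' @export
scaled_rank_table <- function(per_tissue) {
  if (length(per_tissue) < 2L) mk_stop("need results for >= 2 tissues")
  tissues <- names(per_tissue)
  long <- rbindlist(lapply(tissues, function(ts)
    as.data.table(per_tissue[[ts]])[, .(term_id, term_name, scaled_rank,
                                        tissue = ts)]))
  wide <- data.table::dcast(long, term_id + term_name ~ tissue,
                            value.var = "scaled_rank")
  setnames(wide, tissues, paste0("scaled_rank_", tissues))
  cols <- paste0("scaled_rank_", tissues)
  present <- !is.na(as.matrix(wide[, cols, with = FALSE]))
  wide <- wide[rowSums(present) >= 2L]
  present <- present[rowSums(present) >= 2L, , drop = FALSE]
  if (nrow(wide) == 0L) return(wide[])
  wide[, pattern := apply(present, 1L, function(r)
    paste(tissues[r], collapse = "+"))]
  wide[, rank_sum := rowSums(as.matrix(.SD), na.rm = TRUE),
       .SDcols = cols]
  setorder(wide, pattern, rank_sum)
  wide[]
}
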