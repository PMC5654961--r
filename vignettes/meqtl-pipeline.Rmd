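---
title: "Methods: cis-meQTL screens and downstream enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cis-meQTL screens and downstream enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope

meqtlkit implements the statistical backbone of a genotype-methylation
integration study: design of a cis-meQTL screen under a power constraint,
additive-model meQTL discovery with permutation-calibrated FDR, enrichment of
GWAS SNP sets for meQTL status against stratum-matched null SNP sets, Gene
Ontology analysis of meQTL-target CpGs with probe-count bias correction, and
regulatory-feature overlap testing. Array preprocessing, imputation and
ancestry inference are out of scope: the package consumes cleaned dosage,
beta-value, summary-statistic and BED inputs.

# The discovery model

For a SNP $s$ and CpG $c$ on the same chromosome within the window, percent
methylation $y$ (beta value, 0–100) is regressed on the additive dosage
$g \in \{0,1,2\}$ with the first two ancestry principal components and sex as
covariates:

$$ y_i = \beta_0 + \beta_1 g_i + \gamma_1 \mathrm{PC1}_i +
   \gamma_2 \mathrm{PC2}_i + \delta\,\mathrm{sex}_i + \varepsilon_i. $$

`fit_meqtls()` computes the per-pair fit by Frisch–Waugh residualization:
dosages and beta values are residualized against the covariate design once,
and each pair then reduces to a simple regression of residuals. This is
algebraically identical to the full OLS fit (the test suite verifies
agreement with a normal-equations oracle to 1e-8 relative error) and lets
the permutation loop reuse one matrix cross-product per chromosome. Two-sided
p-values use the t distribution with $n - 5$ degrees of freedom (intercept,
dosage, three covariates).

Numerical edge cases: pairs whose SNP has zero dosage variance after
filtering are skipped and logged; a zero residual variance with a nonzero
slope yields the machine-minimum p-value and a `degenerate` flag rather than
a spurious zero.

# Permutation FDR

For a candidate threshold $p_o$, $N_\mathrm{obs}(p_o)$ counts distinct CpGs
with at least one association at $p \le p_o$ (ties included). Each of the
(default 100) permutations applies **one shared shuffle of genotype sample
labels** — per-SNP shuffles would destroy LD between SNPs, which is exactly
what the null must retain — while methylation and covariates stay fixed;
$N_\mathrm{null}$ is counted the same way and
$\widehat{\mathrm{FDR}}(p_o) = \overline{N_\mathrm{null}}/N_\mathrm{obs}$.

Because the empirical FDR curve need not be monotone in $p_o$,
`threshold_for_fdr()` first applies a pool-adjacent-violators (isotonic,
nondecreasing) adjustment and then returns the largest grid $p_o$ whose
adjusted FDR is at or below the requested level (0.10/0.05/0.01 in the
screen design). The default grid is 40 log-spaced points in
$[10^{-12}, 10^{-2}]$.

Whether ancestry PCs should travel with the genotypes under permutation is
ambiguous; the default keeps them with methylation (they are confounders of
the trait), and `permute_covariates = TRUE` provides the alternative.

# Screen design

`count_tests()` counts candidate pairs under a (sd cutoff, MAF floor,
window) triple, and `power_additive()` evaluates the two-sided Wald power
for a per-allele effect $\beta$ on a continuous trait with HWE genotype
variance $2q(1-q)$:

$$ \lambda = \beta \sqrt{n \cdot 2q(1-q)}/\sigma, \qquad
   \mathrm{power} = \Phi(\lambda - z_{1-\alpha/2}) +
   \Phi(-\lambda - z_{1-\alpha/2}), $$

with $\alpha = 0.05 / \#\mathrm{tests}$ (Bonferroni) and power evaluated at
the candidate's own MAF floor — the least-powered SNP admitted.
`select_params()` returns the most permissive passing candidate,
hierarchically: smallest sd cutoff (most CpGs), then smallest MAF floor
(most SNPs), then largest window. The residual sd $\sigma$ is a required
argument: the field-standard default of "the sd cutoff" is degenerate when
the cutoff is 0 and confuses the 0–1 with the 0–100 scale, so no default is
supplied. The design effect size defaults to 5 beta units (a 5% methylation
difference per allele) and target power to 0.8.

# GWAS enrichment with matched nulls

Three nuisance factors distinguish a GWAS SNP set from random SNPs: LD,
MAF, and the number of testable CpGs in the SNP's window (its
*opportunity*). The pipeline addresses them in order: `find_proxies()`
expands index SNPs at $r^2 \ge 0.8$ within 500 kb; `supervised_ld_prune()`
thins at $r^2 > 0.7$ within a sliding 500 kb window, greedily keeping the
SNP with the best GWAS p-value (ties: position, then id) so the disease
signal survives pruning; `stratify_snps()` bins SNPs by MAF (width 0.05,
first bin truncated at the 0.01 analysis floor, top bin closed at 0.5) and
opportunity (0–49, 50–99, ...). Each of the 1000 null sets reproduces the
disease set's stratum histogram exactly, drawn without replacement within a
set when the stratum pool allows (with replacement plus a warning
otherwise); repeats across sets are allowed since sets are independent
draws. The enrichment fold is the observed meQTL proportion over the mean
null proportion; the permutation p is the one-sided fraction of null sets
as or more extreme, with the conservative $(k+1)/(B+1)$ variant reported
alongside because $k = 0$ occurs.

# GO analysis with probe-count bias correction

CpGs land on genes non-uniformly, so a gene's chance of contributing a
selected CpG grows with its probe count and a plain hypergeometric test is
anti-conservative (the test suite demonstrates this on a null simulation).
`go_test()` models selection probability as proportional to probe count:
each term is tested with a two-class Wallenius noncentral hypergeometric
upper tail whose odds parameter is the mean probe count of in-term universe
genes over the mean for out-of-term genes. Proportionality is the simplest
monotone weight model and is validated against a weighted-sampling Monte
Carlo oracle. The exact $O(n \cdot m_1)$ draw-by-draw recursion is used for
universes up to 2000 genes; beyond that an integral representation is used
(with the substitution $u = t^{1/D}$, without which the integrand
concentrates on an interval of width $\sim 10^{-6}$ and quadrature fails).
When all probe counts are equal both routes reduce to the hypergeometric
tail exactly.

Two approximations are deliberate: the two-class odds collapses within-class
weight heterogeneity (strongly skewed probe-count distributions make the
test somewhat conservative), and term p-values are discrete, so the null
fraction below 0.05 sits near 0.03 rather than 0.05 at typical term sizes.

Term redundancy is handled by the stated gene-list rule rather than a
semantic-similarity engine: iterating by ascending p among nominally
significant terms ($p < 0.05$), a term is dropped if it overlaps a retained
term by more than 70% of the smaller gene list. `scaled_rank_table()` keeps
terms retained in at least two tissues, with each tissue's scaled rank =
raw rank / number of retained terms, grouped by tissue pattern and ordered
by the sum of available scaled ranks.

# Regulatory overlap

CpGs are points (1-based); tracks are 0-based half-open intervals, so a CpG
at position $p$ overlaps an interval containing $p-1$ — the conversion is
centralized in `pos1_to_bed0()`/`bed0_to_pos1()` and unit-tested at the
boundaries. `fisher_2x2()` implements the two-sided exact test by
probability ordering with the customary 1e-7 relative tie tolerance and
reports the sample odds ratio $ad/bc$ ($+\infty$ when $bc=0$, missing when
both products vanish); the conditional-MLE estimate is available via
`or = "cmle"`. The battery's Bonferroni threshold is
$\alpha / (\#\mathrm{features} \times \#\mathrm{lists})$ — 3.95e-05 for the
canonical 181 features by 7 lists. Intersection lists are built from
harmonized re-screens (`harmonized_downsample()`: subsample to the other
tissue's n, re-query at its parameters, calibrate the FDR threshold on a
chromosome subset — the default first six chromosomes, where FDR estimates
empirically stabilize — and apply it genome-wide).

# What the synthetic scenarios emulate

`make_scenario()` plants known structure so every stage can be exercised
without restricted cohort data:

* **Genotypes** — Gaussian copula: within each LD block (default 10 SNPs)
  latent normals follow AR(1) with parameter $\rho$ (default 0.8); each
  haplotype thresholds its latent at the MAF quantile and the dosage sums
  two independent haplotypes, so HWE holds by construction and $r^2$ decays
  geometrically within blocks. Blocks are exported for the locus-expansion
  stage.
* **Methylation** — planted additive effects (default 200 pairs at 5 beta
  units per allele, the design effect), simulated PC and sex covariates,
  Gaussian noise (default sd 10 beta units — a repo choice, as no noise
  model is prescribed by the screen design), clipped to [0, 100] with the
  clip fraction logged and effect sizes chosen to keep it below 1%.
  Covariate PCs are simulated rather than computed from the genotypes: this
  keeps the generator stages independent, at the cost of not emulating
  genotype-driven ancestry structure.
* **GWAS** — disease SNPs are chosen within (MAF x opportunity) strata so
  their meQTL proportion is exactly $f$ times the stratum baseline;
  an $f$ with $f \times \mathrm{baseline} > 1$ in any stratum is an error,
  not a silent cap. Disease SNPs receive $p \sim U(0, t)$, others
  $p \sim U(0, 1)$.
* **Annotations** — one feature track covering target CpGs at a planted
  odds ratio; genes tiling consecutive CpGs with probes-per-gene
  $1 + \mathrm{NB}(2, \mu = 3)$; one GO term with membership weighted
  toward target genes.

A green test on these scenarios establishes that the estimators recover
planted parameters under the generator's assumptions (AR(1) LD, additive
effects, uniform GWAS nulls). It does not establish robustness to real-data
features the generator omits: bimodal beta distributions, batch structure,
probe cross-reactivity, population stratification, or realistic GWAS
polygenicity.

# Numerical and convention choices

* Ties at $p = p_o$ are included ($\le$).
* Proxy inclusion uses $r^2 \ge 0.8$; pruning removal uses strict
  $r^2 > 0.7$.
* Disease-set meQTL status counts direct-or-proxy membership by default.
* Chromosome labels are normalized (`chr1` vs `1`) before any overlap.
* Uniformity checks on null p-values subsample one pair per
  (LD block, CpG): cis pairs sharing a SNP, CpG or block are dependent, so
  a KS test over all pairs is invalid even under a correct null.
* All generators and resampling stages consume explicit integer seeds; the
  same configuration and seed reproduce outputs byte-identically.

# Known limitations

* The Wallenius odds parameter uses class-mean weights; heavy within-class
  skew makes the GO test conservative.
* The trans (inter-chromosomal / beyond-window) space is intentionally not
  searched.
* The VCF path accepts hard GT calls only; dosage TSVs accept integers
  only.
* `expand_locus()` assigns SNPs outside every supplied recombination block
  to singleton blocks rather than erroring.
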