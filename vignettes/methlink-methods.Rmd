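---
title: "Methods: discovery, overlap and characterisation of genetically influenced DNA methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovery, overlap and characterisation of genetically influenced DNA methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methlink)
```

# The scientific problem

Genome-wide association studies implicate hundreds of loci in cancer risk,
but most risk variants are non-coding and their mechanism is opaque. One
well-supported route is epigenetic: a risk allele alters DNA methylation at
a nearby CpG (it is a *meQTL*), the methylation change alters the
expression of a target gene, and that change shifts risk. `methlink`
implements a pipeline that finds CpGs sitting on this causal path by
combining two independent lines of evidence — genetic prediction of
methylation tested against GWAS summary statistics, and observed
differential methylation in tumour versus control tissue — and then
characterises the survivors at the gene and SNP level.

# Discovery

## Imputation-based methylome-wide association

Individual-level genotype and methylation data are rarely co-available at
GWAS scale. Instead, prediction weights $w_l$ for each CpG's cis SNPs
(within 1 Mb), trained elsewhere, are combined with per-SNP GWAS effects
$\beta_l$ (standard error $se_l$) and a reference LD panel:

$$Z \;=\; \sum_l w_l \,\frac{\sigma_l}{\sigma_g}\,\frac{\beta_l}{se_l},
\qquad \sigma_g = \sqrt{w^\top \Sigma\, w},$$

where $\Sigma$ is the panel covariance of the SNP dosages and $\sigma_l$
its diagonal square roots. This is algebraically the Wald statistic of
regressing the genetically predicted methylation score on the phenotype,
reconstructed from summary statistics — the transcriptome-wide association
statistic transplanted to methylation. Design points:

* $\sigma_l$ and $\Sigma$ come from the reference panel (empirical
  covariance, denominator $n-1$), not from GWAS allele frequencies.
* Model SNPs absent from the GWAS are dropped (partial-model imputation)
  and the coverage fraction reported; a model with no remaining SNPs, or
  with $\sigma_g \le 10^{-8}$ (an untestable model), is skipped.
* $p = 2\Phi(-|z|)$, two-sided, then Benjamini–Hochberg FDR across all
  tested CpGs; hypomethylation means $z < 0$.
* All sources are first rotated onto the panel's counted (alt) allele;
  strand-ambiguous A/T and C/G SNPs are dropped by default because their
  orientation cannot be verified.

**What validates it.** On synthetic cohorts the statistic is compared with
the individual-level regression of $w^\top g$ on the phenotype. In the
exact-LD limit — LD estimated from the cohort itself — the two agree to
$|\Delta Z| < 0.2$ per model and correlate above 0.99 across models; this
isolates the summary-level algebra from reference-panel sampling noise,
which is an irreducible (and well-known) additional variance source when
the panel is an independent finite sample.

## Differential methylation from observed beta values

For each CpG the beta value is regressed by ordinary least squares on

$$\text{beta} \sim \text{sample type} + \text{age} + \text{age}^2 +
\text{top } K \text{ principal components},$$

with the case group coded 1 (tumour vs healthy, and tumour vs NAT, as two
contrasts). The sample-type coefficient's $t$ statistic is the signed $z$;
$p$ is two-sided from the $t$ reference distribution (exact in small
samples; the choice matters little at $n > 100$), BH-adjusted per
contrast. Constant CpGs yield NA rows excluded from the FDR denominator.

Upstream QC: CpGs missing in more than 10% of the samples of any group
(tumour, NAT, healthy evaluated separately) are removed; remaining gaps
take the CpG's median; then one round of PCA outlier screening removes,
within each group, samples whose PC1 score falls outside the 1.5 × IQR
box-plot whiskers (groups under 4 samples are skipped). PCs used as
covariates are recomputed from the post-QC matrix of the specific
contrast.

**Number of PCs.** With array-scale data (hundreds of thousands of CpGs)
ten or five PCs absorb technical structure while barely touching a sparse
biological contrast. At this package's desk scale (tens of CpGs, a fifth
of them differential) any direction with above-noise variance competes for
the top PCs, and the tumour contrast itself is such a direction, so extra
PCs *absorb the signal being tested*. The pipeline default is therefore
$K = 2$, matching the two structured nuisance axes the generator plants
(technical batch and age); `dm_test(n_pcs = )` scales it up for real
array-dimension data.

# Overlap: the stepwise enrichment cascade

Let $U$ be the intersection of the tested-CpG universes. Starting from the
imputation-significant set, iteration $j$ intersects the current set (size
$n$) with the significant set of tissue analysis $j$ and tests the overlap
count $k$ with a one-sided exact binomial against
$p_0 = (\text{DM count of analysis } j)/|U|$ — the null that the current
set is no more enriched for analysis-$j$ DM CpGs than the universe is. The
cascade proceeds only while $p < 0.05$ (strict inequality); its surviving
overlap is the enriched set. With a single tissue contrast (no healthy
group available) exactly one iteration runs. The iteration order is the
order given and is recorded in the trace, because permuting the analyses
can change the outcome.

Directional variants take, per analysis, the nominally significant CpGs
($p < 0.05$ uncorrected) with matching sign ($z<0$ hypo, $z>0$ hyper) and
run the same cascade.

Annotation-category enrichment uses the **two-sided** exact binomial
(point-probability summation: all outcomes with probability at most
$(1+10^{-7})$ times that of the observed count), while overlap-cascade
tests are **one-sided**. The printed worked examples this package
reproduces (45/77 vs 0.4448 → 0.016; 3/77 vs 0.1581 → 0.002) are matched
by the two-sided convention and not by one-sided tails (≈0.010, ≈0.001),
which fixes the convention; both sidednesses remain available in
`binom_enrich()`.

# Characterisation

* **Interval annotation** with precedence splicing (within 2 bp of an
  internal exon boundary) > exonic > 5'/3'-UTR > intronic >
  upstream/downstream (1 kb beyond the transcript, strand-aware) >
  intergenic; non-coding genes give ncRNA categories; all overlapping
  genes are reported, the winning category is the highest-precedence call.
* **Differential expression** is a transparent stand-in for a full
  negative-binomial analysis: genes under 10 total counts removed,
  median-of-ratios size factors, per-gene OLS on
  $\log_2(\text{count}/sf + 0.5)$, fold change as the ratio of normalised
  group means, BH FDR. The interface (fold change, $p$, FDR, direction)
  is what the pipeline consumes; per-gene $p$ values will differ from a
  shrinkage-based NB fit, and a unit test confirms the log fold changes
  track a reference NB implementation closely on strong signals.
* **Distance-window scan**: for half-widths from 1 kb to 10 Mb, genes
  overlapping (even partially) ±w of any enriched CpG are collected, the
  DEG proportion tested one-sided against the genome-wide DE rate, and
  the window preceding the *maximum drop* in proportion is selected (ties
  toward the smaller window) — the heuristic being that enrichment decays
  once the window outgrows the true regulatory neighbourhood.
* **eQTL overlap linking**: a gene is linked to the CpG set when its
  expression-model SNPs are enriched for the CpGs' meQTL SNPs
  (one-sided binomial; null = median overlap proportion among genes with
  at least one shared SNP); linked genes can then be tested for imputed
  differential expression by the same $Z$ statistic with expression
  weights.
* **Mediation**: per CpG–gene pair,
  $\log_2 \text{expr} \sim \text{type} + \text{meth} +
  \text{type}\times\text{meth}$; the interaction $p$ (BH-adjusted)
  measures conditional differential expression given methylation.
  Collinear designs (e.g. constant methylation) yield NA.
* **Familial relative risk**: the proportion of $\ln\lambda$ explained by
  a SNP set is $\sum_i p_i(1-p_i)(\beta_i^2-\tau_i^2)/\ln\lambda$ with
  $p_i$ the MAF, $\tau_i$ the SE and $\lambda$ the overall familial
  relative risk (2 for breast, 2.5 for prostate cancer). The formula is
  applied exactly as printed — without the conventional factor 2 in the
  genotype variance term — because fidelity to the published estimator
  matters more than the convention; `factor2 = TRUE` switches to the
  conventional form, and negative per-SNP terms are retained.
* **Conditional scan** (summary-level stepwise selection): CpGs within
  1 Mb are pooled; the meQTL SNP with the smallest marginal $p < 0.05$
  enters; thereafter each candidate's conditional $p$ given the selected
  set is computed from reconstructed normal equations
  $X^\top X \approx n\,S R S$ ($S = \mathrm{diag}\sqrt{2p(1-p)}$, $R$ the
  panel correlation), $X^\top y$ from marginal effects, phenotypic
  variance fixed at 1 and residual variance updated to
  $\max(1-\text{explained}, 0.1)$; the best candidate enters while
  $p_\mathrm{cond} < 0.05$. Candidates with $r^2 > 0.9$ to the selected
  set are never chosen; singular systems are skipped and flagged rather
  than ridge-stabilised, mirroring the collinearity exclusion. The shared
  $n$ is the GWAS median $n$; per-SNP sample-size refinement is the main
  divergence from the original conditional-analysis software.
* **Meta-analysis**: inverse-variance fixed effects
  ($\hat\beta = \sum w_i \beta_i / \sum w_i$, $w_i = se_i^{-2}$,
  $se = (\sum w_i)^{-1/2}$) with Cochran's
  $Q = \sum w_i(\beta_i-\hat\beta)^2$ on $k-1$ df; $p_\mathrm{het}$ is NA
  for a single study. Region classification around a CpG uses the
  minimum GWAS $p$ within ±1 Mb with the boundaries
  $p \le 5\times10^{-8}$ (genome-wide), $\le 10^{-5}$ (suggestive), else
  novel; pleiotropy between two CpGs' meQTL sets requires a shared SNP or
  a cross-pair with $r^2 > 0.4$.

# The synthetic data generator

`simulate_study()` builds every input with the statistical structure the
analysis assumes, plus a truth set for validation:

* **Genome & annotation**: one chromosome (2 Mb default), 30
  non-overlapping three-exon gene models (one in six non-coding), CpGs
  placed to cover every annotation category, LD blocks tiling the
  chromosome in 50 kb tiles.
* **Genotypes**: a haplotype copy process — each allele is copied from
  its left neighbour with probability `ld_decay`, else drawn at its
  target MAF (uniform on (0.1, 0.4)) — giving adjacent-dosage correlation
  ≈ `ld_decay` and marginal frequencies inside the target range by
  convexity. Panel of 500; GWAS cohort of 2000 drawn from the same
  process. Allele pairs always pair one of {A,T} with one of {C,G}, so
  no simulated SNP is strand-ambiguous.
* **Weight models**: 3 cis SNPs per CpG, Gaussian weights rescaled so the
  genetic score explains `h2_meth` = 0.3 of unit latent methylation
  variance.
* **Phenotype**: a continuous liability
  $y = \sum_c \gamma_c M_c + \varepsilon$ over 8 causal CpGs
  ($\gamma = 0.3$, alternating sign), with per-SNP marginal least squares
  producing the summary statistics. A continuous trait keeps the
  individual-level oracle exact; the imputation statistic consumes only
  $\beta/se$, so nothing downstream depends on the trait scale.
* **Tissue methylation**: latent-Gaussian model squashed through the
  logistic into beta values — per-CpG baseline N(0, 0.8), tumour-only
  shift `dm_effect` = 0.15 (sign matching the liability effect), age
  slope 0.005/yr over ages 30–80, technical batch offsets (two random
  batches cross-cutting the biological groups, per-CpG shifts sd 0.4 on
  30% of CpGs — batches must cross-cut the groups, as plates and scanners
  do, or the PC covariates could not be used at all), residual sd 0.2,
  2 planted outliers (latent shift 3) and 2% missingness. 60 samples per
  group, the scale at which the recovery checks are stated.
* **Expression**: negative-binomial counts (dispersion 0.1, base
  abundance $2^{U(3,8)}$, library sizes ×0.5–2) for tumour and NAT
  samples matched to the methylation study. Genes hosting causal CpGs get
  a tumour log2 fold change of 1 with sign *opposing* methylation (the
  canonical repressive direction), plus a tumour-only interaction slope
  of 8 log2 units per unit beta of the linked CpG. The slope is a power
  calculation: the realised within-tumour beta sd is 0.05–0.09 (logistic
  squashing attenuates the latent sd), and 8 puts the planted interaction
  at $t \approx 4$–5 for $n = 60+60$, i.e. reliably detectable but not
  trivial.

**What the generator does not emulate**: realistic human LD maps and MAF
spectra, array probe chemistry and batch artefacts beyond additive
shifts, cell-type heterogeneity, case/control ascertainment (the liability
is continuous), trans effects, and count outliers. Passing tests
demonstrate the *algebra and logic* of the pipeline under its stated
assumptions, not robustness to everything real data does.

# Numerical choices and conventions

* Coordinates are 1-based inclusive throughout; BED input/output converts
  at the boundary.
* Panel dosages count the alt allele; every other source is rotated onto
  that frame before analysis, and harmonisation is idempotent.
* Exact binomial p-values follow `stats::binom.test`, whose two-sided
  point-probability summation (relative tolerance $1+10^{-7}$) is the
  convention matched by the published worked examples.
* BH adjustment is `stats::p.adjust(method = "BH")` behind a validating
  wrapper; Fisher tests use `stats::fisher.test` with Bonferroni
  adjustment and the ≥ 2 overlapping-genes rule.
* The LD matrix is used unregularised; $\sigma_g^2 = w^\top\Sigma w$ is
  floored at 0 before the square root, and models with $\sigma_g$ below
  $10^{-8}$ are skipped rather than inverted.
* Ties at the cascade threshold ($p = \alpha$) do not proceed; ties in
  the window scan resolve to the smaller window.
* Seeds: every generator derives deterministic streams from
  `sim_config(seed = )` with fixed offsets, using R's default RNG
  (Mersenne-Twister; R ≥ 3.6 sample semantics).

# Problem sizes used in validation

The test suite and acceptance checks run at: 50 weight models × 2000
cohort samples for the oracle-equivalence check; 10 seeded regions of 20
SNPs (AR 0.6) for the conditional-scan comparison; 10 end-to-end all-null
and 10 recovery pipelines at the default conditions above; 500
quasi-independent null units (2000 SNPs on a 10 Mb genome) for the type-I
calibration of the imputation statistic. These sizes give stable Monte
Carlo behaviour for the stated bounds while remaining quick to run.

# Known limitations

* Summary-level conditional selection inherits reference-panel LD noise:
  with an independent finite panel, borderline selections among SNPs in
  moderate LD ($r \approx 0.6$) can flip relative to individual-level
  stepwise regression even though the reconstruction algebra is exact
  (the package verifies exactness in the matched-LD limit). Larger panels
  reduce but do not remove this.
* The type-I error of the imputation statistic is assessed over
  quasi-independent units; units sharing cis SNPs have correlated
  statistics and their empirical rejection fraction fluctuates more than
  a binomial bound suggests.
* The DE stand-in is not a shrinkage NB model; at low counts its $p$
  values are less well calibrated than its fold changes.
* FRR apportionment uses the printed estimator without the factor-2
  genotype-variance convention; both forms are exposed, and sums over LD
  pruned versus raw SNP sets are the caller's choice.
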