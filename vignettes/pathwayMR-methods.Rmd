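---
title: "Pathway-level transcriptional MR: models, defaults and design choices"
author: "pathwayMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-level transcriptional MR: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathwayMR)
```

## The causal question and the exposure model

`pathwayMR` asks whether the *average expression of a gene set* causally
affects an outcome trait, using cis-eQTLs as instruments. The working model
treats the genes of a pathway as acting together:

$$Y = \beta_e \sum_{j=1}^{p} h_j E_j + X\alpha + \varepsilon,
\qquad E_{ij} = \beta_s\,\mathrm{SNP}_{ij} + x_i \alpha_j + \varepsilon_{ij},$$

with $\beta_e$ the pathway-average causal effect and $h_j = \beta_j/\beta_e$
per-gene heterogeneity ratios. The ratios are constrained to average 1;
without that constraint $\beta_e$ and the $h_j$ are only jointly identified
(any rescaling of $\beta_e$ can be absorbed into the ratios). The IVW
estimate targets $\beta_e$ exactly when $h_j \equiv 1$ and a
weighted average of the $\beta_j$ otherwise — which is why the package also
ships the per-gene and per-tissue decompositions: a pathway estimate with
strongly heterogeneous gene effects should be read as an average, not a
shared effect.

The usual instrumental-variable assumptions apply per SNP: association with
the exposure (checked via the mean F statistic and $I^2_{GX}$),
independence from confounders, and no horizontal pleiotropy (probed by the
Egger intercept, Q/Q′, leave-one-out and MR-PRESSO — probes, not
guarantees).

## Instrument construction

Selection mimics a cross-tissue expression signal while maximizing
instrument strength:

1. per gene and tissue, the most significant cis-eQTL with $p < 10^{-5}$
   (strict) within ±1 Mb of the TSS (inclusive edges; evaluated on
   `tss_distance` when present, else from `pos` and a TSS table);
2. union across tissues, deduplicated by variant keeping the most
   significant tissue's statistics;
3. union across the pathway's genes, deduplicated keeping the smallest
   exposure p (ties broken by larger $|\hat b_X|$, then lexicographic gene
   id — determinism matters more than the choice itself);
4. greedy LD clumping at $r^2 < 0.01$ (strict), ranked by exposure p.

Clumping is re-applied independently within every grouping (gene, tissue,
pathway); the pathway-level pass starts from the *unclumped* union so an
independent variant cannot be lost to a per-gene pass. Instruments absent
from an outcome GWAS are replaced by the highest-LD proxy with $r^2 > 0.8$
(strict); the original exposure statistics are retained and paired with the
proxy's outcome statistics. Proxy allele phase is taken from the LD panel's
signed dosage correlation when the panel was built from genotypes;
otherwise the proxy is only used when its allele pair matches the
original's by identity or strand complement and is not palindromic.

Harmonization aligns outcome effects to the exposure effect allele,
allowing strand complements, and drops palindromic (A/T, C/G) variants when
either side's allele frequency is missing or within $0.5 \pm 0.08$; outside
that band the orientation is inferred from frequency concordance. The band
is configurable (`palindromic_eaf_band`); 0.08 is the conventional
two-sample MR default. Every drop is itemized with a reason.

## Estimators and numerical choices

With weights $w_j = 1/se_{Yj}^2$:

* **IVW**: weighted regression through the origin. The default standard
  error is multiplicative random-effects — the fixed-effect SE inflated by
  $\max(1, \sqrt{Q/(J-1)})$ — with under-dispersion floored at 1, and
  normal p-values. `dispersion = "fixed"` switches the floor off entirely.
* **MR-Egger**: weighted regression with free intercept after orienting
  all instruments to $\hat b_X \ge 0$. SEs scale by
  $\max(1, \sqrt{Q'/(J-2)})$; p-values use $t_{J-2}$. The singular-design
  guard rejects exposure spreads below $10^{-12}$ of the weighted second
  moment, so numerically-identical exposure effects fail loudly rather
  than producing astronomical slopes.
* **Wald ratio** (single instrument): $\hat b_Y/\hat b_X$ with the
  first-order SE $se_Y/|\hat b_X|$; exposure-side uncertainty is ignored
  (standard at strong instruments) but still feeds the F statistic,
  $I^2_{GX}$ and MR-PRESSO.
* **MR-PRESSO**: leave-one-out expected residuals, parametric simulation
  under the no-pleiotropy null, empirical p-values with the
  $(\#\{\ge\}+1)/(n_{sim}+1)$ correction (no zero p-values), Bonferroni
  over instruments for outlier flags, fully seeded. The distortion test is
  not computed — outlier detection is the diagnostic reported here. The
  default $n_{sim} = 1000$ bounds the smallest attainable adjusted p at
  $J/1001$; with very many instruments, raise it.
* Missing p-values in input tables are recomputed as two-sided normal
  tails of $\hat b/se$ and clamped into $(0, 1]$; a stored p-value is
  never overwritten.

Two structural identities are useful for review and are enforced by the
test suite: constraining the Egger intercept to zero reproduces IVW
exactly, hence Rücker's $Q' \le$ Cochran's $Q$ always; and all estimators
are invariant to simultaneous sign flips of $(\hat b_X, \hat b_Y)$.

## Multiple testing

The per-test threshold is $\alpha/(M_\mathrm{eff} \times
\#\mathrm{pathways})$ with $M_\mathrm{eff}$ the Li–Ji eigenvalue count,
reported unrounded and floored for thresholding. When no phenotype
correlation matrix is available the package offers a Spearman correlation
of per-variant z-scores across the shared variants of the outcome GWAS —
an approximation that inherits whatever genetic correlation the shared
variants capture, which is exactly the dependence the correction needs to
discount. Secondary screens (e.g. a larger GO family) use the same formula
with that family's pathway count.

## One-sample validation

`computeAssociations` reproduces summary statistics from individual-level
data: expression targets are zero-imputed at half the minimum positive
value, log-transformed, and passed through the fully-adjusted two-stage
rank normalization — OLS residuals on covariates, Blom inverse-normal
transform ($z_i = \Phi^{-1}((r_i - 3/8)/(n + 1/4))$, average ranks for
ties), rescaled by the residual SD, with the same covariates re-entered in
the association model. The Blom offset and residual-SD rescaling are the
common instantiation of the fully-adjusted procedure. Stratified runs drop
covariates that are constant within the stratum (including the stratum
indicator itself). Exposure- and outcome-side samples may overlap; no
overlap correction is applied, matching the summary-level one-sample
design the stage validates.

## What the synthetic generator emulates — and what it does not

`simulateTwoSample` / `simulateIndividual` generate data *under the
pathway-exposure model above*, with:

* one causal cis-variant per gene inside an AR(1) LD block (correlation
  `ld_rho`, default 0.5), zero LD across blocks; each gene sits on its own
  chromosome label, which is sufficient to exercise clumping, proxying and
  the cross-chromosome shortcut;
* per-tissue eQTL effects sharing a gene-level value with
  $N(0, \tau^2)$ deviations (default $\tau = 0.05$);
* shared eQTL effect sizes drawn on $\pm[0.25, 0.7]$ SD of expression per
  allele with allele frequencies on $[0.05, 0.5]$ — at the default
  per-tissue eQTL sample size of 500 this yields mean F statistics in the
  tens, the strong-instrument regime the estimators assume;
* summary SEs of $1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})\,n}$ (unit trait
  variance, covariate $R^2$ ignored) with outcome GWAS $n$ defaulting to
  20{,}000, matching the scale of the motivating OSA meta-analyses;
* per-SNP pleiotropic effects $N(\mu_\alpha, \sigma_\alpha^2)$ oriented to
  the expression-increasing allele. That orientation is what makes the
  pleiotropy *directional* in the sense the Egger intercept estimates;
  drawing it independently of $\beta_s$ satisfies the InSIDE assumption.
* individual-level dosages from two thresholded Gaussian AR(1) chains,
  with the latent correlation calibrated by quadrature so the *dosage*
  correlation between adjacent variants equals `ld_rho` (a naive Gaussian
  copula undershoots it substantially).

Deliberately not emulated: realistic effect-size and allele-frequency
spectra, cross-block LD, population structure, relatedness, sample overlap
between exposure and outcome panels, and any real genetic architecture of
OSA or expression. Passing tests therefore demonstrate that the machinery
is correct and calibrated under its own assumptions — not that those
assumptions hold in any particular real dataset.

Default allele pairs are non-palindromic so that generator-level truths
survive harmonization untouched; `palindromic = TRUE` adds strand-ambiguous
pairs for testing the drop rules.

## Scenario fixtures and problem sizes

`makeFixtureBundle` writes six deterministic study-shaped file sets:
`null`, `causal` ($\beta_e = 0.05$ on every outcome of the first pathway),
`directional_pleiotropy` ($\mu_\alpha = 0.02$), `single_outlier` (one
outcome effect inflated by ten times the largest), `tissue_heterogeneity`
($\tau = 0.15$) and `paper_shape` — four pathways by four outcomes with the
focal pathway carrying 30 genes so that, at roughly one independent cis
signal per gene, it yields on the order of 30 clumped instruments.

The test suite and `scripts/acceptance.R` use replicate counts sized to
keep the full run in the low minutes on one core: 1000 null replicates for
type-I error (J = 25), 500 for parameter recovery at $\beta_e = 0.1$, 400
for Egger-intercept recovery, 100 seeded MR-PRESSO runs each for
sensitivity and specificity (J = 15, $n_{sim} = 1000$), 20 end-to-end
discovery runs on the causal fixture, and 10 one-sample validation cohorts
of n = 2000. These are the sizes at which the Monte-Carlo error of each
check is comfortably inside its acceptance band.

## Known limitations

* The Wald/IVW first-order SEs ignore exposure-side sampling error;
  weak-instrument settings (mean F near 10) push work onto $I^2_{GX}$ and
  the Egger SIMEX-style corrections, which are not implemented.
* Weighted-median/mode estimators, multivariable MR and
  contamination-mixture methods are out of scope.
* The cross-tissue "most significant tissue" selection maximizes
  instrument strength at the cost of winner's-curse inflation of
  $\hat b_X$; with many tissues and modest eQTL sample sizes this
  attenuates causal estimates toward zero. The estimator-calibration
  checks therefore run at a single tissue; the pipeline-level checks
  absorb the (small, at the default settings) attenuation.
* LD handling is panel-based only; there is no server-side clumping, no
  multi-allelic decomposition, and unknown same-chromosome pairs are
  treated as unlinked (with a warning).
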