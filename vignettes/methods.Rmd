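---
title: "Models and methods behind sexdiffmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sexdiffmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sexdiffmeth)
```

sexdiffmeth analyses sex differences in placental DNA methylation across
several cohorts: per-CpG robust regression, empirical-null correction of
test-statistic inflation, random-effects meta-analysis, region calling,
cis-meQTL mapping with a sex-consistent/sex-specific split, enrichment
testing, and cross-tissue comparison. This vignette explains the models,
the tunable parameters and their defaults, the numerical choices, what the
synthetic-data generator does and does not emulate, and the design
decisions that were genuinely open.

## Per-CpG robust regression

All modeling is done on M-values, `M = log2(beta/(1-beta))`, whose
near-Gaussian behavior suits linear models better than bounded
beta-values. For each CpG the model is

$$M_i = \beta_0 + \beta_1\,\mathrm{female}_i + \gamma^\top x_i + \varepsilon_i,$$

with males the reference category, so a CpG with lower methylation in
females has $\beta_1 < 0$. Covariates $x$ are gestational age (weeks —
any affine rescaling such as days changes only the coefficient scale, not
the p-values), maternal age (years), smoking (0/1), and five of the six
placental cell-type proportions. Since proportions sum to one, one column
must be dropped; we always drop syncytiotrophoblast, the largest mean
share, so runs are comparable.

Fitting is Huber M-estimation by IRLS: tuning constant `c = 1.345`
(95% Gaussian efficiency), residual scale re-estimated each iteration as
`1.4826 * median(|r|)`, convergence when the largest coefficient change
falls below `1e-8` (cap: 50 iterations). A perfect fit (zero scale)
falls back to OLS and is flagged degenerate, as is a constant response.

Standard errors are a White-type sandwich on the converged fit. The bread
uses the Huber $\psi'$ weights — the indicator of the linear zone — in
expectation form, $\overline{\psi'}\,X^\top X$; the meat is
$X^\top W\,\mathrm{diag}(r^2)\,W X$ with $W$ the final IRLS weights (so
$Wr$ is the $\psi$-residual). Two remarks explain this choice:

* With unit weights this is exactly HC0, the canonical unqualified
  "White estimator".
* The naive alternative of putting $W$ itself in the bread overstates
  $|z|$ by $E[w]/E[\psi'] \approx 1.16$ at `c = 1.345` on clean Gaussian
  data — a 16% spurious inflation that the downstream correction stage
  would then have to absorb. The $\psi'$ form is the asymptotically
  correct M-estimator covariance. The expectation (scalar) form of the
  bread is used because the raw 0/1 indicator matrix can annihilate a
  sparse design column (a stratum's only smoker flagged as an outlier)
  and make the bread singular.

p-values use the standard normal reference, not $t$: the z-statistics are
consumed as-is by the inflation model and the meta-analysis, which are
normal-theory throughout.

## Empirical-null correction

Per cohort, the z-statistics are modeled as a three-component Gaussian
mixture — a dominant null component plus a hypo- and a hyper-methylated
signal component — fitted by EM with initial weights (0.9, 0.05, 0.05),
means (0, −3, 3), unit SDs, and convergence on a log-likelihood change
below `1e-6` (cap: 10,000 iterations; non-convergence returns the best
fit, flagged). The null component is the one with the largest weight (ties
broken by mean closest to zero); its mean is the *bias* and its SD the
*inflation*.

Unconstrained, this mixture is poorly identified when signal is weak: a
"signal" component drifts into the null bulk and silently absorbs null
mass (on pure N(0,1) data the null mean estimate was 0.04; on a wide null
the inflation was underestimated by 0.12). The Gibbs-sampling formulation
of this model solves that with informative priors; the EM analogue used
here is an M-step constraint keeping the signal means at least 2 null-SDs
away from the null mean. The offset 2 was fixed by a scenario sweep (null
SDs 1.0/1.14/1.37; a planted 0.9/0.05/0.05 mixture with signal at ±3;
three seeds each): 1.5 still under-recovers wide nulls, while 2.5 or more
misfits genuine signal at $|z| = 3$ and overstates inflation.

Correction rescales: $z' = z/\hat\lambda$ and $se' = se\,\hat\lambda$,
leaving effect estimates untouched, so $z' = \beta/se'$ and the p-value
ranking within a cohort is preserved. Bias subtraction
($z' = (z-\hat b)/\hat\lambda$) is available but off by default — the
default procedure corrects for inflation only. The classical
genomic-control $\lambda_{GC} = \mathrm{median}(z^2)/0.4549$ is reported
alongside; note it is a *variance*-scale summary, so a null with z-SD 1.3
shows $\lambda_{GC} \approx 1.69$.

## Random-effects meta-analysis

CpGs present in at least one cohort are pooled with the DerSimonian–Laird
moment estimator: fixed weights $w_i = 1/se_i^2$, Cochran's
$Q = \sum w_i (b_i - \bar b)^2$,
$\tau^2 = \max\!\big(0,\, (Q - (k-1)) / (\sum w_i - \sum w_i^2/\sum w_i)\big)$,
random-effects weights $1/(se_i^2 + \tau^2)$. A METAL-style direction
string ("+", "−", "0", "?" for absent) summarises cross-cohort
consistency. Epigenome-wide significance is $p < 9\times10^{-8}$, the
accepted array-wide threshold; `min_cohorts` tightens availability to ≥ 2
where required (the meQTL analysis uses exactly that rule).

## Region calling

Region detection follows the comb-p construction on the meta-analysis
p-values:

1. **ACF** — Pearson correlation of z-score pairs binned by inter-probe
   distance (bins of 50 bp up to 200 bp), pooled over chromosomes; bins
   with fewer than 10 pairs fall back to 0 with a warning.
2. **Smoothing** — per probe, neighbors within 200 bp are combined by
   Stouffer–Liptak–Kechris: two-sided p-values become one-sided z-scores
   signed by the meta z (so opposite-direction neighbors cancel rather
   than reinforce), $Z = \sum z_i / \sqrt{k + 2\sum_{i<j}\rho(d_{ij})}$,
   and $Z$ maps back to a two-sided p. An isolated probe keeps its p;
   if the correlation adjustment drives the variance nonpositive it is
   floored at $k \cdot 10^{-6}$ with a warning.
3. **Growth** — a region seeds at a smoothed p below `seed_p = 0.05`
   ("nominal significance") and extends while the next sub-threshold
   probe lies within 200 bp; runs of fewer than 2 probes are dropped.
4. **Scoring** — each region's member probes' *original* meta p-values
   are combined (again correlation-aware) into `slk_p`, then
   Šidák-corrected for the number of region-sized windows among the
   covered bases (probes count 1 bp each):
   `sidak_p = 1 - (1 - slk_p)^(coverage/width)`, with a linear
   (Bonferroni) fallback below `1e-12` where the power form underflows.

The epigenome-wide filter applies to `sidak_p` by default — the
multiplicity-corrected region p is what "epigenome-wide significant"
plausibly means for regions — with `filter_on = "slk"` exposing the other
reading, since the seed threshold and the filtered quantity were both
genuinely open choices.

## cis-meQTL mapping and the sex split

Genotypes pass QC in the stated order — call rate ≥ 0.98, MAF ≥ 0.05,
exact Hardy–Weinberg p > 1e-5 (conditional exact test, summing
heterozygote counts no more probable than observed) — and each SNP–CpG
pair within a closed 150-kb window is fitted per cohort by OLS of M-value
on additive dosage (mean-imputed where missing) plus the EWAS covariates,
the first two genotype principal components, and sex (dropped in the
male-only/female-only strata; covariates that become constant within a
stratum are dropped with a message). OLS rather than Huber is deliberate:
the matrix-factorized screens standard for this step are OLS-based, and
the per-pair model is a screen, not the headline estimate. Pairs present
in ≥ 2 cohorts are pooled per stratum with the same DL estimator;
significance is $p < 10^{-8}$.

Classification: a pair is **sex-consistent** if significant overall with
male and female effects in the same direction, **sex-specific** if
significant in one sex with the opposite direction in the other
(meta-analysed stratified effects are compared; the per-cohort reading is
possible but the pooled one is the stable choice). A CpG qualifying for
both groups goes to the one whose qualifying pair has the smaller p,
ties to sex-consistent — so the CpG-level classes are disjoint by
construction, and the code asserts that on every run.

## Enrichment and comparisons

Fisher tests are two-sided conditional hypergeometric: all tables with
the observed margins whose point probability is at most the observed
one (computed in log space), matching the convention of the standard
exact test; the reported odds ratio is the *sample* odds ratio $ad/bc$,
not the conditional MLE, because that is what published enrichment tables
print. The background is always the tested-but-not-significant CpG set.
Genic context is annotated by strand-aware priority — Promoter
(TSS ± 3 kb) > 5′UTR > Exon > Intron > 3′UTR > Downstream (≤ 3 kb) >
DistalIntergenic — from BED12 gene models (exon blocks, CDS thick range);
plain BED6 input collapses the genic levels to Exon since exon structure
is simply not representable there.

Cross-tissue and sensitivity comparisons correlate effect estimates
(beta weights, not z — effect sizes are the scientifically comparable
quantity), optionally restricted to a BH-FDR subset; model comparisons
additionally report the fraction of sign-concordant CpGs.

Demographics tables are reproduced from summary data alone: one-way
ANOVA from (n, mean, SD) triples — algebraically identical to full-data
ANOVA — and Pearson chi-square on the 2×g count table without continuity
correction, which is the convention that reproduces published cohort
tables from their printed counts. Printed summaries are rounded, so
recomputed ANOVA p-values agree to about an order of magnitude at the
extreme tail, while chi-square rows recomputed from exact counts agree to
printed precision.

## The synthetic generator

`simulate_multi_cohort()` emulates the statistical structure the analysis
assumes, with all planted truth recorded:

* **Cohorts** of 137/470/139 samples by default, with per-cohort
  phenotype profiles (gestational age ≈ 38.2/40.0/39.9 ± 1.4–2.0 weeks;
  maternal age ≈ 29/34.5/32 years; smoking prevalence 23%/2%/10%; sex
  ratio near 1:1) mirroring the kind of heterogeneity real birth cohorts
  show. Cell proportions are Dirichlet with concentration
  50 × (0.05, 0.15, 0.50, 0.15, 0.05, 0.10) over nRBC, trophoblast,
  syncytiotrophoblast, stromal, Hofbauer, endothelial — a plausible
  placental composition; the exact values are immaterial to the tests.
* **M-values** with bimodal baselines, lognormal per-CpG residual SDs
  around 0.5, and per-CpG covariate loadings, so designs are realistic
  rather than orthogonal.
* **Sex effects** at a configurable fraction of CpGs, negative in
  females with probability 0.85 by default (female hypomethylation
  dominates in placenta); planted regions share one sign across their
  probes, and neighbors within 200 bp get AR-style correlated noise
  (ρ = 0.5 at one step) for the region caller to exploit.
* **Inflation** is planted as a sex-aligned polygenic background: each
  null CpG receives a cohort-specific effect
  $b \sim N(\mathrm{bias}\cdot s,\ (\lambda^2-1)\,s^2)$ where
  $s = \sigma_j\,\|w_c\|$ is the sampling SD of the female coefficient
  under the realized cohort design. Null z-statistics then genuinely have
  SD ≈ λ (defaults 1.14/1.37/1.17). This construction was chosen over
  per-observation variance heterogeneity because independent
  heteroskedastic noise cannot inflate sandwich-based z-statistics — the
  estimator is consistent for it — whereas an unmodeled sex-aligned
  background is precisely the mechanism that inflates real EWAS.
* **Genotypes** are binomial(2, p) in HWE with MAF in [0.05, 0.5];
  planted meQTLs add dosage effects to their target CpGs, identical in
  both sexes (sex-consistent) or opposite in sign and 4× weaker in the
  non-driving sex (sex-specific) so the stratified direction rules have
  something to detect. The planting term uses expectation-centered
  dosage: a sex-dependent genotype effect on raw dosage would leak a
  marginal sex effect of ≈ 2·MAF·(δf − δm) into those CpGs (as real
  sex-specific meQTLs in fact do), which would muddle the planted-truth
  bookkeeping that recovery tests rely on.
* **Tissue sets** draw per-tissue true effect vectors from a trivariate
  normal with configurable pairwise correlations (defaults: 0.55 for
  CVS–placenta, 0 elsewhere) on 65 shared samples. Observed
  effect-estimate correlations are attenuated relative to the truth by
  estimation noise, by the factor
  $\sqrt{\prod_t v_t/(v_t + \overline{se_t^2})}$; tests compare against
  that attenuated oracle, not the raw target.

One RNG stream per cohort is derived from the master seed, so cohort-level
draws are reproducible when other cohorts' sizes change. Small-n guards
keep designs estimable (a cohort is never all-smokers or single-sex).

What the generator does *not* emulate: array probe chemistry and
normalization artifacts, cross-hybridization, batch structure, linkage
disequilibrium between SNPs, imputation uncertainty, cell-type reference
error, and missing methylation values (readers reject NA cells — the
pipeline assumes complete post-QC matrices). Passing recovery tests
therefore demonstrate the estimators' correctness and calibration under
the assumed model, not robustness to upstream artifacts.

## Problem sizes and reproducibility

The test-suite and acceptance computations use 5,000-CpG genomes at the
study's cohort sizes (137/470/139), 200 planted DMPs at 0.6 M-units, one
5-probe region, and 120 planted meQTLs among 300 SNPs — sizes at which
every stage's calibration and power are measurable with comfortable
margins (meta-analysed z for a 0.6 M-unit effect is ≈ 15, far beyond the
9×10⁻⁸ threshold, so ≥ 90% sensitivity is a conservative bar).
`scripts/acceptance.R --seed N --out file.json` re-derives all headline
quantities from scratch; all randomness flows from the single seed.

## Interfaces

The package is function-driven in the style of the R analysis packages it
resembles; `run_pipeline()` orchestrates the stages from one
configuration, writes every intermediate in the documented delimited
formats (methylation TSV, sample-sheet CSV, dosage TSV or VCF, BED for
regions — 1-based closed coordinates internally, 0-based half-open on BED
output), and records seeds, thresholds and per-stage counts in a JSON
manifest. There is deliberately no shell entry point: the exemplar
packages for this kind of analysis are used from R scripts, and
`scripts/acceptance.R` shows that pattern.

## Known limitations

* The EM mixture estimates inflation slightly high at small n (the HC0
  small-sample factor, ~3% at n = 137, is real inflation in the data and
  is corrected as such); post-correction λ_GC lands near 1.04 rather
  than 1.00 on 5,000-CpG nulls.
* The ACF estimator needs dense probe spacing; with the default 10-kb
  spacing most bins are empty and fall back to zero correlation, which
  is correct for that geometry but emits warnings.
* `fit_meqtl_cohort` mean-imputes missing dosages rather than dropping
  samples per pair; at the QC call-rate floor of 98% the difference is
  negligible.
* Fisher p-values are discrete; on small universes the uniformity of
  null enrichment p-values holds only up to that discreteness.
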