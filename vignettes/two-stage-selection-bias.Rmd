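---
title: "Quantifying the winner's curse in two-stage genetic association designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the winner's curse in two-stage genetic association designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wincurse)
```

## The problem

Two-stage designs are a standard way to contain sequencing costs: a
GWAS-like first stage tests a genotyped *tag SNP* for association with a
trait, and only regions whose tag passes the significance threshold are
carried into a sequencing-like second stage, where effects are estimated at
the *causal* variant(s) directly. Two opposing distortions act on the
resulting effect estimates.

First, conditioning estimation on the same data having passed a
significance threshold inflates the magnitude of the estimate — the
*winner's curse*. Under the low power typical of genome scans, only
replicates whose estimate fluctuated upward get selected, so the
conditional mean exceeds the unconditional one.

Second, the tag SNP is only an imperfect proxy for the causal variant.
With additive (0/1/2 minor-allele count) coding and haplotype-level
allelic correlation $\rho_{TC}$ between tag and causal SNP, the expected
slope of the trait on the tag genotype is attenuated:

$$ E[\hat\beta_T] = \gamma_{TC}\,\beta_C, \qquad
   \gamma_{TC} = \rho_{TC}
   \sqrt{\frac{p_C(1-p_C)}{p_T(1-p_T)}}, $$

where $p_T$ and $p_C$ are the two minor-allele frequencies. Under
Hardy–Weinberg equilibrium the genotype-level Pearson correlation equals
the haplotype-level $\rho_{TC}$, which makes $\gamma_{TC}$ both the
attenuation factor and the quantity controlling how much of the selection
bias at the tag carries through to the causal-SNP estimate: none when
$\gamma_{TC}=0$, all of it (but with high power and hence little bias)
when $\gamma_{TC}=1$.

For rare variants (MAF below 5%), single-SNP tests are hopeless, and the
second stage instead estimates the Morris–Zeggini collapsing effect
$\lambda$: the regression coefficient of the trait on $r_i/n_i$, where
$n_i$ is the number of rare SNPs genotyped in individual $i$ and $r_i$
the number at which the individual carries at least one minor allele.
$\lambda$ is interpreted as the effect for an individual carrying a rare
allele at every genotyped rare SNP. A further constraint shapes this
setting: the allelic correlation between two loci is bounded,

$$ |\rho| \le \rho_{\max}(p_T, p_C) =
   \sqrt{\frac{p_{\min}(1-p_{\max})}{p_{\max}(1-p_{\min})}}, $$

so a common tag can never tag a very rare variant well, while a low-MAF
tag can.

`wincurse` packages this whole setting as a seeded
simulation-and-estimation pipeline: an LD-constrained genotype generator,
the stage-1/stage-2 regressions, the selection loop, and the summary
metrics (estimated power, conditional and unconditional means, relative
bias, $\gamma_{TC}$, tag–burden correlation), plus analytic
truncated-normal oracles for testing the machinery against closed forms.

## The three scenarios

* **S1 — common tag, common causal SNP.** One `ld_pair_spec(p_t, p_c,
  rho)` pair; the second stage re-estimates the additive effect at the
  causal SNP. The special case `rho = 1` with equal MAFs makes the tag
  its own causal SNP.
* **S2 — common tag, multiple rare causal SNPs.** A `gene_spec` with a
  common tag (MAF > 5%) and several rare variants; the second stage fits
  the collapsing regression for $\lambda$.
* **S3 — low-MAF tag, multiple rare causal SNPs.** As S2, but the tag has
  MAF in [1%, 5%], so it would itself belong to the gene's rare set; it
  is excluded from $r_i/n_i$ (`exclude_tag_from_burden = TRUE`, enforced
  at configuration time).

Selection happens only at the tag: a replicate is *selected* when the
stage-1 tag p-value falls below the threshold `alpha` (two-sided), or —
with the one-sided rule — when the estimate is positive and the two-sided
p-value is below `2 * alpha`, which is equivalent to a one-sided test at
level `alpha`. The one-sided rule exists because with an uncorrelated tag
the selected estimates land on both sides of zero and their signed mean
is misleading. Stage-2 estimates are computed for *every* replicate and
filtered only at summary time, so the unconditional mean (the bias
baseline) and the conditional mean come from the same records.

## The generator

Haplotypes for a pair are drawn from the 2×2 haplotype table implied by
the margins and $D = \rho\sqrt{p_T(1-p_T)p_C(1-p_C)}$; infeasible
$\rho$ (any negative cell) is rejected at spec construction, never
clipped. For a gene, the tag allele is drawn first and each rare allele
conditionally on it, the rare loci being mutually independent given the
tag — the simplest structure in which each tag–rare pair attains its
target correlation. Genotypes are two independent haplotypes (HWE); there
is no population structure, relatedness, recombination map or
sequence-level realism, which is deliberate: the quantities under study
(power, attenuation, selection bias) depend on the generating model only
through MAFs, correlations and effect sizes.

Traits follow three kinds: quantitative with Age and Smoking covariates
(Q1-like; covariates enter both stage-1 and stage-2 fits), quantitative
without covariates (Q2-like), and binary disease status fit by logistic
regression without covariates. The genetic term is either per-locus
additive effects `beta` or a burden effect `lambda` on $r_i/n_i$ —
exactly one of the two drives a given simulation. Covariate distributions
(Age uniform 20–80 years, Smoking Bernoulli 0.3) are configurable
stand-ins; their values are immaterial to the bias mechanisms studied. A
configurable per-entry missingness rate (default 0) exercises the $n_i$
denominator.

Seeding: one master seed per run; per-replicate seeds are derived
deterministically from it and the replicate index, so any replicate is
reproducible in isolation and identical `(config, seed)` pairs give
byte-identical CSV outputs.

## Canonical study conditions

`example_config()` freezes the conditions under which the package's
statistical checks run; they were chosen once, to sit in the regimes
where the winner's curse is visible, and are not tuned thereafter.

* **S1**: n = 616 individuals, tag = causal SNP with MAF 0.30,
  quantitative trait with `beta = 0.057`, `sigma = 1`. This puts the
  standardized noncentrality near 0.92, i.e. analytic power ≈ 0.15 at
  the two-sided 0.05 threshold — low power with a comfortably estimable
  selected fraction.
* **S2**: n = 697, tag MAF 0.25, ten rare variants with MAFs evenly
  spaced over 0.005–0.045, each tag–rare correlation set to 60% of its
  feasibility bound, burden trait with `lambda = 0.7`, `sigma = 1`. A
  single pilot run fixed these values so that the tag–burden correlation
  is near 0.5 and stage-1 power at the 0.05 threshold is near 0.10 —
  the published regime for this design (correlations 0.4–0.5, power
  below 20%).
* **S3**: as S2 with tag MAF 0.03. The similar MAFs make the tag–burden
  correlation much higher (≈ 0.86), so power at 0.05 is high and the
  threshold must be calibrated down: `calibrate_alpha()` walks the
  discrete ladder {0.05, 0.01, 0.001} — the levels such studies report —
  and returns the largest threshold whose pilot power is below the 20%
  ceiling (0.001 under these conditions). The ladder is discrete on
  purpose; a continuous threshold search would not correspond to any
  reported analysis.

## Numerical choices and degenerate inputs

* Regressions are ordinary `stats::lm` / `stats::glm(binomial)` fits;
  p-values are the usual Wald-type summaries (t for linear models).
  Likelihood-ratio tests, mixed models and genomic control are out of
  scope.
* A monomorphic genotype column, too few complete cases, or a constant
  burden score is a *degenerate-design error*; inside the replicate loop
  such replicates are flagged invalid with the error message as reason,
  excluded from both numerator and denominator of every summary, and
  counted in `n_invalid`.
* Complete or quasi-complete separation in the logistic fit (detected via
  non-convergence or all fitted probabilities at the boundary) is an
  explicit error, never a finite estimate.
* Relative bias is the signed ratio `100 * (mean_selected - mean_all) /
  mean_all`. When nothing is selected, or when `|mean_all|` falls below
  `1e-3` times the estimate SD, the ratio is reported `NA` rather than
  divided out; both means are still reported. A `magnitude = TRUE`
  variant summarizes `|estimate|` for sign-unstable null settings.
* `r_i` uses the carrier indicator (genotype ≥ 1) per locus — the literal
  reading of "has a rare allele"; an allele-count variant sits behind
  `burden_scores(..., carrier = FALSE)` but is not the default.
* The tag–burden correlation reported for a scenario is the mean of the
  per-replicate Pearson correlations (not a pooled correlation).
* Missing genotypes are handled per regression by complete-case deletion;
  there is no imputation.
* Feasibility tolerances: spec construction rejects `|rho|` beyond
  `rho_max` with slack `1e-12`; the haplotype table tolerates rounding of
  `-1e-10` at the exact boundary so that `rho = rho_max` itself is valid.
* File I/O re-orients genotypes so the coded allele is the in-sample
  minor allele (a tie at frequency 0.5 keeps the file's coding);
  multiallelic VCF records are skipped with a warning and counted.

## What the tests do and do not show

The checks in `tests/testthat/test-acceptance.R` validate the pipeline
against independent oracles at the problem sizes above (5,000 replicates
for the truncated-normal oracle, the carry-through null and the
threshold ladder; 2,000 for burden recovery and type-I error; n = 100,000
for attenuation; all on one CPU in a few minutes): simulated conditional
means match the analytic truncated-normal expectation; the empirical tag
slope attenuates by exactly $\gamma_{TC}$; an uncorrelated tag passes no
bias to the causal SNP while its own conditional estimates are far from
their unconditional mean; stricter thresholds lower power and worsen the
bias monotonically; $\hat\lambda$ is unbiased without selection and
inflated under low-power selection; the correlation bound is exact.

These are properties of the generating model the package assumes —
homogeneous random-mating populations, biallelic loci, additive effects,
Gaussian or Bernoulli traits. Passing them says the machinery is correct,
not that real cohorts with population structure, differential
missingness, genotyping error or long-range LD will show numerically
similar biases; published two-stage analyses of real exome data report
the same qualitative patterns but their magnitudes depend on the cohort.

## Known limitations

No bias-correction estimators (conditional likelihood, bootstrap
shrinkage) are provided — the package quantifies the bias, it does not
remove it. One tag SNP per scenario run; no genome-wide multi-SNP scans,
no replication-study sample-size planning, and no emulation of any
specific published phenotype-generating model.
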