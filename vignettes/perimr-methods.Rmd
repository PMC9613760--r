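---
title: "Methods: one-sample MR from GWAS summary statistics in perimr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: one-sample MR from GWAS summary statistics in perimr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perimr)
```

## The problem and the model

`perimr` implements a summary-level Mendelian randomization (MR) pipeline for
testing whether a perinatal exposure (the motivating case is birth weight,
with maternal smoking in pregnancy and breastfeeding as companions) causally
affects the risk of amblyopia, a binary ophthalmic outcome. MR uses genetic
variants as instrumental variables: because alleles are assigned at
conception, a variant that (1) associates with the exposure, (2) shares no
confounder with the outcome, and (3) affects the outcome only through the
exposure yields a causal contrast that is immune to the confounding and
reverse causation that plague observational perinatal epidemiology.

All computation is on GWAS summary statistics. For variant $j$, let
$\hat\beta_{Xj} \pm \sigma_{Xj}$ be its estimated effect on the exposure and
$\hat\beta_{Yj} \pm \sigma_{Yj}$ its estimated log-odds effect on the
outcome, both expressed per copy of a common effect allele. The per-variant
causal estimate is the Wald ratio

$$\hat\theta_j = \frac{\hat\beta_{Yj}}{\hat\beta_{Xj}}, \qquad
  \mathrm{se}(\hat\theta_j) \approx \frac{\sigma_{Yj}}{|\hat\beta_{Xj}|},$$

with the first-order delta-method standard error. The second-order term is
omitted deliberately: the first-order form is the convention under which the
inverse-variance weighted (IVW) estimator coincides exactly with weighted
least-squares regression of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ through the
origin (a property the test suite asserts to 1e-10), and with two-stage least
squares on individual-level data.

### The four estimators and MR-Egger

With weights $w_j = 1/\mathrm{se}(\hat\theta_j)^2$:

* **IVW, fixed effect** — $\hat\theta = \sum w_j \hat\theta_j / \sum w_j$,
  $\mathrm{se} = (\sum w_j)^{-1/2}$. Efficient when every instrument is
  valid.
* **IVW, multiplicative random effects** — same point estimate;
  $\mathrm{se}_{\mathrm{RE}} = \mathrm{se}_{\mathrm{FE}}\sqrt{Q/(J-1)}$,
  where $Q = \sum_j w_j(\hat\theta_j - \hat\theta)^2$ is Cochran's
  heterogeneity statistic. The dispersion factor is **not floored at 1** by
  default, so under-dispersed ratios ($Q/(J-1) < 1$) produce a
  random-effects SE *smaller* than the fixed-effect one. This choice is
  forced by the arithmetic of the setting the package reproduces: with 18
  instruments and a heterogeneity p of 0.998, the reported random-effects SE
  (0.258) is about half the fixed-effect SE (0.480), a pattern only the
  unfloored multiplicative model produces. `floor_dispersion = TRUE`
  restores the conservative floored variant.
* **Simple and weighted median** — order the ratios
  $\hat\theta_{(1)} \le \dots \le \hat\theta_{(J)}$, normalize the weights
  ($w'_j \equiv 1/J$ for the simple median), form cumulative midpoints
  $s_j = \sum_{k \le j} w'_k - w'_j/2$, and linearly interpolate
  $\hat\theta$ against $s$ at $s = 1/2$. Consistent when at least half the
  (weight of) instruments are valid. The SE is a parametric bootstrap
  (default 1000 replicates, seeded): each $\hat\theta_j$ is redrawn
  $N(\hat\theta_j, \mathrm{se}_j^2)$ and the SD of the re-estimated medians
  is reported. No closed-form SE exists for the interpolated median; the
  bootstrap is the standard recourse. Ties in $\theta$ are broken by stable
  sort, and exactly equal weights are collapsed to unit weights so that the
  weighted estimator degenerates to the simple one *exactly*, not merely to
  rounding.
* **MR-Egger** — weighted regression of $\hat\beta_{Yj}$ on
  $\hat\beta_{Xj}$ (weights $1/\sigma_{Yj}^2$) with a free intercept, after
  orienting each pair so $\hat\beta_{Xj} \ge 0$. The slope is a
  pleiotropy-robust causal estimate under the InSIDE assumption; the
  intercept estimates the average directional pleiotropic effect and its
  two-sided test is the horizontal-pleiotropy diagnostic. Coefficient SEs
  carry the same unfloored multiplicative residual scaling
  $\sqrt{Q_{\mathrm{Egger}}/(J-2)}$ as the random-effects IVW, for internal
  consistency.

All pooled estimates are tested against the standard normal (not $t$), and
odds ratios are $e^{\hat\beta}$ with $e^{\hat\beta \mp 1.959964\,
\mathrm{se}}$ confidence limits; $Q$ statistics are referred to
$\chi^2_{J-1}$ (about the IVW estimate) or $\chi^2_{J-2}$ (Egger residual).

### Instrument selection and harmonization

Selection applies, in order: a strict p-value filter ($p < 10^{-6}$ by
default — a deliberately relaxed genome-wide criterion that admits loci of
unknown function); greedy LD clumping (visit candidates by ascending
p-value, ties broken by chromosome, position, then ID; an index SNP removes
neighbours on the same chromosome within 10,000 kb with $r^2 \ge 0.001$,
the $r^2$ cut inclusive to match the stated exclusion rule); and a
user-supplied exclusion list for instruments with known direct outcome
associations (the motivating analysis removes rs9895335 and rs4977838 on
neurodevelopmental grounds; a no-exclusion mode reproduces the sensitivity
analysis that keeps them). Per-instrument strength is reported as
$F_j = (\hat\beta_{Xj}/\sigma_{Xj})^2$, the squared z-score — the
$(n-2)R^2/(1-R^2)$ form is unavailable because per-SNP $R^2$ is not part of
the summary-statistic schema, and for a single regressor the two agree in
large samples.

Harmonization aligns every outcome record to the exposure's effect allele,
resolving, in fixed order: identical alleles; swapped allele order (negate
$\hat\beta_Y$, mirror EAF); strand flips for non-palindromic SNPs (relabel
via A↔T/C↔G, with the swap correction when needed); palindromic SNPs; and
irreconcilable alleles (dropped). A palindromic SNP (A/T or C/G) carries no
strand information in its labels, so orientation must come from allele
frequency: if either EAF is missing or falls in the intermediate band —
**[0.42, 0.58]** by default, the community's usual ±0.08 around 0.5, since
the motivating text says "intermediate" without a number — the SNP is
dropped; otherwise EAFs on the same side of 0.5 confirm the alignment and
opposite sides trigger a flip. Palindromic SNPs outside the band are
*retained* via this inference rather than dropped wholesale (the stated
procedure aligns "effect allele frequencies for the palindromic SNPs"); a
`strict_palindromic` switch drops them all for users who prefer the blunter
convention.

### Statistical power

For a binary outcome the power module uses the non-centrality formulation
standard for summary-level MR calculators: with case fraction $K$, outcome
GWAS size $N$, instrument $R^2$ on the exposure and causal odds ratio
$\mathrm{OR}$,

$$b_{01} = K\left(\frac{\mathrm{OR}}{1 + K(\mathrm{OR}-1)} - 1\right),\qquad
  v = \frac{K(1-K) - b_{01}^2}{N R^2},\qquad
  \mathrm{power} = \Phi\!\left(-z_{1-\alpha/2} + \frac{|b_{01}|}{\sqrt v}\right).$$

At the motivating study's parameters ($N = 417{,}030$, $K = 862/417{,}030$,
$\mathrm{OR} = 0.48$, $R^2 = 0.053$, $\alpha = 0.05$) this evaluates to
0.94; the rounded OR 0.48 and the unrounded $e^{-0.731}$ agree to 2 dp. Note
the $b_{01}$ reparameterization is *not* symmetric in
$\mathrm{OR} \leftrightarrow 1/\mathrm{OR}$ except near the null, even for
rare outcomes — the test suite checks approximate symmetry only at mild
effects.

```{r power}
binary_outcome_power(417030, 862 / 417030, 0.48, 0.053)
```

## The synthetic-data world

`simulate_summary_stats()` generates paired exposure/outcome tables with
known truth so every stage is testable without any data download. Its
defaults *are* the motivating study's stated conditions: 18 instruments, a
continuous exposure GWAS of 262,966, a binary outcome GWAS of 862 cases and
416,168 controls, true causal effect $\theta = -0.73$. Where no value is
stated the defaults are chosen once as field-plausible: instrument-effect
SD $\tau = 0.02$ (puts per-SNP F statistics in the tens-to-hundreds range
typical of anthropometric instruments at this sample size), MAF uniform on
[0.05, 0.5], 20% palindromic variants, LD blocks of 3 SNPs spaced 10 kb
apart (the smallest block that makes greedy clumping non-trivial), and no
pleiotropy.

For SNP $j$ with MAF $p_j$: $b_j \sim N(0, \tau^2)$ for instruments (0
otherwise); $\sigma_{Xj} = (2p_j(1-p_j)n_X)^{-1/2}$, the large-sample SE for
a standardized continuous trait; $\hat\beta_{Xj} \sim N(b_j,
\sigma_{Xj}^2)$. The outcome uses the logistic score-test approximation
$\sigma_{Yj} = (2p_j(1-p_j) N K(1-K))^{-1/2}$ and $\hat\beta_{Yj} \sim
N(\theta b_j + a_j, \sigma_{Yj}^2)$, with $a_j$ the direct (pleiotropic)
effect: zero, $N(0, \mathrm{sd}^2)$ balanced, or half-normal directional.
Every second outcome record is written with swapped alleles (sign and EAF
flipped) to exercise harmonization, deterministically so the truth flags are
reproducible; reported EAFs equal the MAF (or its mirror for swapped
records) without sampling noise.

What this world does **not** emulate — and therefore what a green test does
not establish: LD is block-constant rather than haplotype-derived; EAFs are
noiseless, so frequency-based palindrome orientation never errs (real data
near the band edges can); exposure and outcome samples are generated
independently, so the one-sample overlap (and its weak-instrument bias
toward the confounded association) is absent; and the outcome SE model is a
rare-disease approximation whose absolute scale was never calibrated against
the real per-SNP SEs. Estimator-recovery results on this generator validate
the arithmetic of the estimators, not the epidemiology of any particular
application.

## Numerical and design choices

* **Thresholds**: the p-value filter is strict (`<`); the clumping $r^2$
  cut is inclusive (`>=`). Clumping ties on p-value break by (chromosome,
  position, ID), making the output invariant to input row order.
* **Degenerate inputs**: a single Wald ratio is returned as the IVW
  estimate flagged degenerate; medians and Egger require 3 SNPs; a
  zero-noise Egger fit (residual $Q = 0$) yields SE 0 and limiting p-values
  rather than an error, so exact-line fixtures can be verified.
* **Missing EAF** is tolerated on non-palindromic SNPs and forces a drop on
  palindromic ones (conservative).
* **Seeding**: the pipeline derives independent per-stage seeds from the
  single run seed by hashing the stage name, so adding a stage never
  perturbs another stage's randomness; identical config + seed gives a
  byte-identical `report.json`.
* **Type-I calibration**: the suite checks the size of the fixed-effect IVW
  z-test (0.05 nominal). The unfloored random-effects z-test is slightly
  anti-conservative at $J = 18$ (empirically ≈ 0.07 here) because a normal
  reference is used with an estimated dispersion; users wanting exact size
  under homogeneity should read the fixed-effect row.
* **Config format**: JSON (sections `io`, `simulate`, `selection`,
  `harmonization`, `mr`, `power`), read with `jsonlite`; exactly one of
  real input paths or a `simulate` block must be present.

## A worked run

```{r run}
rep <- run_pipeline(list(
  simulate = list(n_instruments = 15, n_null_snps = 25, tau = 0.08),
  mr = list(n_boot = 200),
  power = list(r_squared = 0.053),
  seed = 42))
rep$estimates[, c("method", "n_snp", "beta", "se", "pvalue", "or")]
unlist(rep$diagnostics[c("egger_intercept_p", "p_q_ivw")])
```

## Known limitations

Proxy-SNP substitution for instruments missing in the outcome GWAS is not
supported; LD is consumed, never computed from a reference panel; no
MR-PRESSO, mode-based, multivariable or leave-one-out analyses; power is
binary-outcome only, with $R^2$ taken as a direct input (its upstream
derivation from instrument effects is outside the summary-statistic schema
used here).
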