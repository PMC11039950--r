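---
title: "Methods: two-sample Mendelian randomization in mrbiome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization in mrbiome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the design

mrbiome estimates the causal effect of a heritable exposure — in its
motivating use case, the relative abundance of a gut-microbiome taxon — on a
binary disease outcome such as an aneurysm diagnosis, using only GWAS
summary statistics from two non-overlapping samples.  Genetic variants
associated with the exposure act as instrumental variables: because
genotypes are fixed at conception, associations between an
exposure-associated variant and the disease are protected from classical
confounding and reverse causation, provided the variant affects the disease
only through the exposure (the exclusion restriction).

Per variant $j$, the data are the exposure association $\hat\gamma_j$ (per
SD of exposure) with standard error $\sigma_{Xj}$, and the outcome
association $\hat\Gamma_j$ (log odds) with standard error $\sigma_{Yj}$.
Under a linear causal model $\Gamma_j = \beta_0 \gamma_j$, each variant
supplies a Wald ratio $\hat\beta_j = \hat\Gamma_j / \hat\gamma_j$ with
first-order standard error $\sigma_{Yj}/|\hat\gamma_j|$ and
inverse-variance weight $w_j$.  All downstream estimators combine these
ratios; results are reported both as log odds and as odds ratios per SD of
exposure.

## Instrument selection

`select_instruments()` applies, in order, with per-stage counts recorded:

1. **p-value threshold** — keep variants with exposure $p$ strictly below
   `p_threshold` (default $10^{-5}$, the locus-wide level customarily used
   for microbiome GWAS, where genome-wide-significant hits are scarce).
2. **LD clumping** — greedy: repeatedly take the remaining variant with the
   lowest $p$ as an index, and remove all others on the same chromosome
   within `clump_window_kb` (default 10,000 kb) whose $r^2$ with it exceeds
   `clump_r2` (default 0.001).  Ties on $p$ are broken by (chrom, pos,
   snp_id) so results do not depend on input row order.  Pairwise $r^2$
   values are an external input; pairs absent from the table count as
   unlinked, with the number of such in-window pairs reported.
3. **F-statistic filter** — remove weak instruments with
   $F = \hat\gamma^2/\sigma_X^2 < 10$.  At the default p-threshold the
   implied minimum is already $\approx 19.5$, so this stage only bites with
   looser thresholds.
4. **Blacklist** — user-supplied variant ids to exclude, e.g. variants known
   to associate with confounders (blood pressure, diabetes).  The package
   deliberately takes a list rather than querying a catalogue service, for
   reproducibility.

The F filter runs after clumping; because both conventions exist in the
wild, the per-stage counts let either ordering be audited, and with the
default thresholds the two orders give identical sets.

## Harmonization

`build_instrument_set()` joins instruments to the outcome table on variant
id (not position, to avoid genome-build accidents) and aligns each outcome
effect to the exposure's effect allele:

* identical allele pair → kept unchanged;
* swapped alleles → kept with the outcome beta negated and its EAF
  reflected;
* strand complements of either case → resolved the same way (a `strict`
  mode drops them instead);
* A/T and C/G palindromes → always dropped — their strand cannot be
  resolved from alleles alone, and no allele-frequency rescue is attempted;
* anything else → dropped as incompatible.

Every input instrument appears exactly once in the drop log, and
harmonization is idempotent on kept records.  Indels are rejected at read
time; the rules above are SNV-only.

## Estimators

Five estimators run on each harmonized set (minimum instrument counts in
parentheses):

* **IVW** (2): $\hat\beta = \sum w_j \hat\beta_j / \sum w_j$ — a
  fixed-effect meta-analysis of the Wald ratios with
  $\mathrm{SE} = (\sum w_j)^{-1/2}$.  The multiplicative random-effects
  variant scales the SE by $\max(1, \sqrt{Q/(J-1)})$ and never reports less
  than the fixed-effect SE.  `auto` picks random effects iff Cochran's $Q$
  has $p < 0.05$, the usual choose-by-heterogeneity rule; both rows are
  always computed so reports can select either.
* **MR-Egger** (3): weighted least squares of $\hat\Gamma$ on $\hat\gamma$
  with a free intercept, weights $1/\sigma_{Yj}^2$, each record first
  oriented so $\hat\gamma_j \ge 0$ (the estimate is orientation-dependent;
  this is the standard convention).  Both SEs are scaled by
  $\max(1, \hat\sigma)$ where $\hat\sigma$ is the weighted residual SD.  A
  nonzero intercept indicates directional pleiotropy; the slope is the
  pleiotropy-adjusted effect.
* **Weighted median** (3): the ratio at the 50% point of the cumulative
  normalized weight distribution, linearly interpolated between the two
  bracketing order statistics (breakpoints $b_j = \sum_{k\le j} u_k -
  u_j/2$).  Consistent when valid instruments carry at least half the
  weight.
* **Weighted mode** (3): argmax of the weighted Gaussian kernel density of
  the ratios, bandwidth $h = \varphi \cdot 0.9\,\min(\mathrm{sd},
  \mathrm{mad})\,J^{-1/5}$ (modified Silverman; the MAD is SD-consistent),
  evaluated on a 512-point grid over $[\min - 3h, \max + 3h]$.  If the MAD
  degenerates to zero the SD is used; identical ratios return the common
  value.  Consistent when the largest cluster of similar ratios is valid.
* **MR-PRESSO** (4): each variant's residual about its leave-one-out IVW
  slope is squared and weighted by $1/\sigma_{Yj}^2$; the global RSS is
  compared with `presso_k` parametric simulations of the no-pleiotropy
  model, per-variant outlier p-values use the add-one rule
  $(1 + \#)/(K+1)$ (never exactly zero) with Bonferroni adjustment, the
  corrected estimate is IVW on non-outliers, and the distortion test
  resamples random same-size exclusions.

Median and mode SEs come from a parametric bootstrap: `n_boot` redraws of
$(\hat\gamma_j, \hat\Gamma_j)$ around the observed values with the observed
SEs, re-deriving ratios and weights each time; the SE is the SD of the
bootstrap estimates.  All p-values and confidence intervals use the normal
distribution, the summary-data MR convention.  Every stochastic component
accepts a seed and restores the caller's RNG state, so batch runs are
byte-reproducible.

## Diagnostics and classification

Cochran's $Q$ (centred on the fixed-effect IVW estimate, $\chi^2_{J-1}$),
leave-one-out re-estimation with sign- and significance-change flags at the
0.05 level, and funnel coordinates (ratio vs precision) accompany every
pair.  Across taxa tested against one outcome, the primary IVW p-values are
Benjamini–Hochberg adjusted within that outcome's family; an association is
*significant* when $p < 0.05$ and $q < 0.1$, *suggestive* when $p < 0.05$
and $q \ge 0.1$ (the $q = 0.1$ boundary is assigned conservatively to
suggestive), otherwise null.  The FDR family is per-outcome because the
motivating analysis treats "taxa tested against one aneurysm type" as one
comparison family; a global family is a one-line change in user code.
Reverse-direction analysis (`run_reverse()`) swaps the roles and reruns the
identical pipeline.

## The synthetic generator

`simulate_pair()` produces exposure and outcome summary statistics with
known ground truth:

$$\gamma_j \sim N(0, \tau^2), \quad
  \hat\gamma_j \sim N(\gamma_j, \sigma_{Xj}^2), \quad
  \Gamma_j = \beta_0\gamma_j + \alpha_j, \quad
  \hat\Gamma_j \sim N(\Gamma_j, \sigma_{Yj}^2 + \text{het}_{\text{extra}}),$$

with $(\gamma_j, \hat\gamma_j)$ resampled until every instrument clears the
locus-wide $p < 10^{-5}$ threshold, so the instrument count is exact per
replicate.  A fraction `rho_invalid` of instruments receives a pleiotropic
effect $\alpha_j = \kappa\gamma_j + s_j\,N(\mu_\alpha, \sigma_\alpha^2)$,
where $s_j$ is the sign of $\gamma_j$: directional pleiotropy is defined
relative to the *exposure-increasing allele*, because the coded-allele sign
is arbitrary and a shift attached to it would cancel under the orientation
convention Egger uses — a constant coded-allele shift is undetectable in
principle, not just in practice.  Setting $\mu_\alpha = 0$ recovers
balanced pleiotropy and $\kappa \ne 0$ violates InSIDE either way.

Standard errors default to $n^{-1/2}$, making every variant equally
informative; `eaf_scale_se = TRUE` adds the per-variant
$1/\sqrt{2f(1-f)}$ allele-frequency factor for more realistic dispersion.
Binary-outcome effects are simulated directly on the log-odds scale — the
pipeline consumes summary statistics only, so no individual-level liability
model is needed.  Allele pairs are drawn from the eight non-palindromic
ordered pairs except where palindromes are injected deliberately;
palindromic, strand-flip and swapped-allele stressors are injected in exact
configured counts and logged in the truth table, so harmonization can be
tested against known actions.

Defaults emulate the motivating study's conditions: exposure GWAS of
$n_x = 18{,}340$ (a taxon-abundance consortium), outcome effective sample
size $n_y = 12{,}682$ (a case-control aneurysm GWAS with 3,201 cases and
317,899 controls; $n_\text{eff} = 4/(1/n_\text{case} + 1/n_\text{ctrl})$),
and $\tau = 0.04$, which puts selected-instrument F-statistics in the
$\approx 20$–$100$ range typical of locus-wide-threshold microbiome
instruments.

**What the generator does not emulate:** residual LD between instruments
(post-clumping independence is assumed, not simulated), sample overlap
between the two GWAS, population stratification, winner's-curse beyond the
significance conditioning, EAF-dependent information by default, and any
16S-abundance measurement model — only the summary-statistic layer is
reproduced.  Passing calibration tests therefore certify the estimators
and pipeline plumbing, not robustness to those real-data complications.

## Calibration study design

The test suite and `scripts/acceptance.R` run seeded Monte-Carlo studies
with a *strong-instrument* design: $\tau = 0.05$, $n_x = 5\times 10^5$,
$n_y = 12{,}682$, $J = 50$ (20 for the outlier study).  With
$\tau/\sigma_X \approx 35$ the $p < 10^{-5}$ conditioning is essentially
non-binding, so winner's-curse attenuation is negligible relative to
outcome-side noise and the studies measure estimator properties rather than
selection artifacts.  Problem sizes are 500 replicates (200 for the outlier
study) with `n_boot = 200` and `presso_k = 300` inside the coverage study —
enough for Monte-Carlo SEs of a few tenths of a percent on coverage — and
`presso_k = 1000` in the outlier study, where the Bonferroni-adjusted
add-one p-value needs $K \gtrsim 800$ to be able to fall below $0.05/20$.

Two known properties surfaced by these studies.  First, the
weighted-median bootstrap SE runs about 10% above the empirical SE under
the strong-instrument design (0.036 vs 0.032 in the 500-replicate study),
because the bootstrap re-noises a ratio cloud whose dispersion is already
noise-inflated; its intervals are correspondingly mildly conservative
(empirical coverage $\approx 0.98$ at the nominal 95%).  The point
estimate is unbiased, and the same bootstrap is well calibrated for the
weighted mode.  Second, while an injected $+10\sigma_Y$ outlier is flagged
essentially always, removing it shrinks the absolute error of the pooled
estimate in only $\approx 78\%$ of replicates under this design: when the
outlier happens to land on a near-zero-$\hat\gamma$ instrument its
inverse-variance weight is negligible, so correction is a coin flip.  With
the generator's default (significance-truncated) instruments, weak hosts
do not occur and correction helps in a clear majority of cases.

## Numerical and boundary choices

* p-value selection uses a strict inequality; F filtering keeps $F$ equal
  to the threshold (variants are removed when $F < 10$).
* Clumping ties on $p$ break by (chrom, pos, snp_id); cross-chromosome
  pairs are never clumped; the window is $|pos_i - pos_j| \le$
  `clump_window_kb` × 1000.
* Wald SEs are first-order by default (`wald_se_order = 2` adds the
  exposure-noise term); exposure noise is exercised through the bootstrap
  and the PRESSO simulations instead.
* PRESSO and bootstrap p-values use the add-one rule so no simulated
  p-value is exactly zero; simulated GWAS p-values are clamped at the
  smallest positive double so validation never rejects an extreme
  instrument.
* Degenerate cases: a single instrument yields a Wald ratio only; identical
  ratios give $Q = 0$, $p = 1$, a zero-bandwidth mode equal to the common
  ratio, and a near-zero bootstrap SE; an instrument with
  $\hat\gamma_j = 0$ raises a degenerate-instrument error rather than an
  infinite ratio.
* Insufficient instruments raise typed errors that `run_pair()` converts to
  skipped-pair records, so batch runs never crash on a sparse taxon.

## Limitations

Proxy-SNP substitution for instruments missing from the outcome GWAS is not
implemented (it requires an external LD reference panel); unmatched
instruments are dropped and logged.  $r^2$ values are consumed, never
computed from genotypes.  Only SNVs are harmonized.  Positions are treated
as opaque within one analysis; no build liftover is attempted.  Steiger
directionality filtering and multivariable MR are out of scope — reverse
causation is probed by the role-swapped reanalysis instead.
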