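---
title: "Drug-target Mendelian randomization with targetmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target Mendelian randomization with targetmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetmr)
library(dplyr)
```

## The problem

Whether lowering LDL cholesterol pharmacologically changes the risk of a
binary disease outcome can be probed without a trial by drug-target
Mendelian randomization (MR): common variants in or near the gene encoding
a drug's target (HMGCR for statins, PCSK9 for PCSK9 inhibitors, NPC1L1 for
ezetimibe) shift LDL-C for life, in a way that is randomized at conception
and — under the instrumental-variable assumptions — independent of the
confounders that plague observational pharmacoepidemiology. `targetmr`
implements the full two-sample summary-statistics pipeline: cis-instrument
selection, allele harmonization, a battery of causal estimators, and the
standard sensitivity analyses, together with a seeded synthetic-data
generator so that every stage is testable with known truth and no external
downloads.

Throughout, the per-SNP data are the summary association pairs
$(\hat\gamma_j, \sigma_{xj})$ of variant $j$ with the exposure (SD units of
LDL-C per effect allele) and $(\hat\Gamma_j, \sigma_{yj})$ with the outcome
(log-odds per effect allele), taken from two non-overlapping GWAS.

## Instrument selection

`select_instruments()` applies, in order:

1. **cis window** — variants within the gene body ±100 kb (`flank_bp`);
   1-based inclusive coordinates.
2. **significance and frequency** — exposure $p < 5\times10^{-8}$ and minor
   allele frequency $> 1\%$, both strict, read literally from the usual
   phrasing of these thresholds.
3. **greedy LD clumping** — iterate by ascending exposure $p$ (ties: larger
   $|\hat\gamma|$, then lexicographic id), keep the index variant, discard
   anything with $r^2 >$ `r2_max` (default 0.3) against it. The $r^2$
   matrix is an input; the package never computes LD from genotypes.
4. **instrument strength** — per-SNP $F = (\hat\gamma/\sigma_x)^2 > 10$.
   The variance-explained form $F = R^2(n-2)/(1-R^2)$ with
   $R^2 = 2\,\mathrm{maf}(1-\mathrm{maf})\hat\gamma^2$ is available via
   `f_statistic(method = "r2")` for tables with untrusted standard errors.
5. **confounder screen** — variants reported in a local trait-association
   table (a PhenoScanner-style export) as associated with a confounder or
   with the outcome at $p < 10^{-5}$ are removed.

The cascade order follows the narrative order in which these filters are
conventionally described; each stage logs counts so that
`input = retained + removed` is verifiable at every step. The cascade is a
pure function of its inputs, and clumping is invariant to input row order
because the tie-break makes the priority ordering total.

## Harmonization and orientation

`harmonize()` matches exposure and outcome records by variant id and aligns
the outcome effect to the exposure's effect allele: swapped alleles negate
$\hat\Gamma$ and reflect the frequency; alleles that match only after strand
complement are complemented first; palindromic variants (A/T, C/G) are
resolved by frequency concordance, or dropped when either frequency lies in
$0.5 \pm 0.08$ (`palindrome_window`, the common two-sample convention —
strand is genuinely unidentifiable from alleles there). Matching is by id
only; no positional fallback, no LD-proxy imputation.

`orient_exposure()` sets the reporting scale. The default,
`per_sd_decrease`, negates every $\hat\gamma_j$ so estimates read as the
effect of *lowering* the exposure — the drug-mimicking direction, under
which a beneficial lipid-lowering drug shows OR < 1 against coronary
disease. This is a convention, exposed as a flag; flipping it exactly
negates every causal log-OR.

## Estimators

With Wald ratios $\hat\beta_j = \hat\Gamma_j/\hat\gamma_j$:

* **IVW** — weighted regression of $\hat\Gamma$ on $\hat\gamma$ through the
  origin, weights $\sigma_{yj}^{-2}$. The default standard error is
  multiplicative random-effects, inflating the fixed-effect SE by
  $\max\{1, \sqrt{Q/(J-1)}\}$; this is the common default in two-sample MR
  software and never reports less uncertainty than the fixed model.
  Normal p-values.
* **MR-Egger** — the same regression with a free intercept, after jointly
  re-orienting each SNP so $\hat\gamma_j > 0$. The intercept estimates the
  mean directional pleiotropic effect; slope and intercept use $t_{J-2}$
  p-values (small-$J$ honesty) and the same multiplicative overdispersion
  floor.
* **Weighted median** — order the $\hat\beta_j$ with normalized weights
  $w_j = \hat\gamma_j^2/\sigma_{yj}^2$, interpolate the cumulative-weight
  midpoints $p_j = \sum_{k\le j} w_k - w_j/2$ at $p = 0.5$. With equal
  weights this reduces to the sample median. Consistent when ≥ 50% of
  weight is valid.
* **Simple and weighted mode** — Gaussian-kernel density over the
  $\hat\beta_j$ with bandwidth $h = \phi \cdot 0.9\,
  \min(\mathrm{sd}, \mathrm{IQR}/1.349)\,J^{-1/5}$ ($\phi = 1$ by default),
  argmax on a 512-point grid spanning $[\min - 3h, \max + 3h]$. If the IQR
  degenerates to zero the SD term alone sets the bandwidth; if all ratios
  coincide the common ratio is returned directly.

Median and mode standard errors come from a seeded parametric bootstrap:
$\hat\gamma_j^* \sim N(\hat\gamma_j, \sigma_{xj})$,
$\hat\Gamma_j^* \sim N(\hat\Gamma_j, \sigma_{yj})$, re-estimate, take the SD
over `n_boot` replicates (default 1000). Identical seeds give identical
SEs. All estimators are invariant to SNP order and to jointly negating any
single SNP's $(\hat\gamma_j, \hat\Gamma_j)$ — an allele recoding, not a data
change.

Instruments clumped at $r^2 = 0.3$ are not fully independent; following
standard practice for this design the estimators treat them as such. The
residual correlation is mild at this threshold and the stricter rerun
(below) removes most of it when it matters.

## Sensitivity analyses

* **Cochran's Q** (`cochran_q()`): $Q = \sum_j ((\hat\Gamma_j -
  \hat\beta\,\hat\gamma_j)/\sigma_{yj})^2$ against $\chi^2_{J-1}$, with the
  fixed-effect IVW slope as the reference by default.
* **Egger intercept test** (`egger_intercept_test()`): intercept $t$-test;
  $p > 0.05$ is conventionally read as no directional pleiotropy. Because
  of the overdispersion floor the test is deliberately conservative when
  pleiotropy variance is negligible relative to outcome noise; its nominal
  calibration is the property of the regime where pleiotropic effects
  actually contribute overdispersion (checked in the test suite with
  balanced direct effects at the outcome-SE scale).
* **MR-PRESSO** (`mr_presso()`): the observed residual sum of squares,
  each SNP's residual taken against the leave-one-out IVW slope, is ranked
  within `n_sim` parametric simulations under the no-pleiotropy model (with
  leave-one-out slopes recomputed per simulation, as in the published
  algorithm); per-SNP outlier p-values are Bonferroni-multiplied by $J$;
  when outliers are found, a distortion test compares the
  outlier-removal shift with removals of random same-size subsets, and the
  corrected estimate is IVW on the non-outliers. P-values use
  $(1 + \#\{\cdot\})/(1 + n_\mathrm{sim})$, so they are never exactly zero.
* **Leave-one-out** (`leave_one_out()`): $J$ re-estimates plus the all-SNP
  row; rows whose CI excludes the all-SNP point estimate are flagged.

## Pipeline and the stricter-LD rerun

`run_pair()` chains selection → harmonization → estimators → sensitivity
for one target-outcome pair. When the pair shows heterogeneity or
directional pleiotropy (Cochran's Q p ≤ 0.05 *or* Egger intercept p ≤ 0.05
— the trigger is a disjunction because either finding alone undermines the
homogeneous-instruments reading), the pair is automatically re-analysed
with clumping tightened from $r^2 = 0.3$ to $r^2 = 0.1$ and both sets of
rows are reported, the rerun flagged. Tightening the threshold can only
shrink the instrument set, so rerun rows never use more SNPs than the
original.

`run_study()` iterates targets × outcomes, runs a positive-control outcome
first when one is named (flagging targets whose control IVW CI includes 1),
emits a transparency-only Bonferroni column across pairs (no verdict uses
it, since none of the standard analyses of this design apply one), and
writes estimate/sensitivity/forest tables plus a full-precision JSON
report. Pairs with no surviving instruments become explicit
`not_estimable` rows; pairs with one or two instruments report Wald/IVW
only, with a warning. Given fixed inputs and one master seed the whole
study is bit-reproducible: every stochastic component (bootstraps,
MR-PRESSO, per-pair analyses) receives a deterministic sub-seed.

## The synthetic-data generator

`simulate_dataset()` emulates the two-sample design: minor allele
frequencies uniform on (0.05, 0.5); true per-allele exposure effects
$\gamma_j \sim N(0, 0.05^2)$ (SD-unit scale, resampled until the implied
$F \ge 10$ by default, since cis instruments are pre-screened for
strength); exposure sampling SE $1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})\,n}$
with $n = 173{,}082$; binary-outcome SE
$1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})\,n_\mathrm{eff}\,v}$ with
$v = \phi(1-\phi)$ the case-fraction factor — the standard logistic score
approximation, adequate for desk-scale testing. Outcome defaults are a
nephropathy-sized GWAS scaled down tenfold (411 cases / 30,854 controls)
to keep per-SNP noise realistic while simulations stay fast;
`full_scale = TRUE` restores 4111 / 308,539. Exclusion-restriction
violations are parameterized by a pleiotropy fraction, mean and SD; LD
enters as a block-diagonal $r^2$ matrix (metadata for clumping — effect
noise is drawn independently); a configurable fraction of variants gets
palindromic alleles; grossly pleiotropic variants ($|\alpha_j| > 3\sigma_\alpha$,
or any $\alpha_j \ne 0$ when $\sigma_\alpha = 0$) are advertised in the
trait-association table so the confounder screen has true positives.

One deliberate subtlety: with effect alleles coded at random, a *constant*
direct effect $\mu_\alpha$ is not detectable by MR-Egger — re-orienting
every SNP to a positive exposure effect turns it into a balanced one. The
generator therefore offers `effect_coding = "exposure_increasing"`, and
directional-pleiotropy simulations use it.

What the generator does **not** emulate: realistic LD decay (blocks are
uniform), correlation between effect sizes and frequency, sample overlap
between the two GWAS, population stratification, and winner's-curse
selection into the exposure GWAS. Passing tests therefore demonstrate the
estimators' statistical behaviour under the stated model, not robustness
to those real-data pathologies.

## Numerical and design choices

* Problem sizes in the shipped tests: oracle equivalence on 100 random
  sets ($J \in [3,30]$, relative error $< 10^{-10}$); recovery over 500
  replicates at $J = 20$; calibration over 2000 replicates per condition;
  MR-PRESSO detection over 100 replicates at `n_sim = 500`; clumping versus
  a recursive oracle over 200 random instances ($J \le 10$). The
  acceptance script recomputes the same quantities at slightly smaller
  replicate counts.
* Thresholds are strict comparisons throughout; flip-side conventions can
  be had by adjusting the threshold by machine epsilon, but the defaults
  match the literal phrasing used in the field.
* Weighted-median weights are the first-order
  $\hat\gamma^2/\sigma_y^2$ form; delta-method refinements change little at
  cis-instrument strength and are not included.
* The p/|z| consistency check on input tables warns rather than errors:
  published summary statistics routinely carry rounded p-values.
* `derive_seed()` maps (master seed, component offset) through a fixed
  affine map modulo $2^{31}-1$, so sub-streams are reproducible and
  independent of execution order.
* Degenerate inputs: a single instrument falls back to the Wald ratio; two
  instruments disable Egger/median/mode; an empty instrument set is an
  explicit not-estimable result, never a silent drop.

## Limitations

The package analyses summary statistics only: no genotype-level QC, no LD
estimation, no liftover between genome builds (coordinates are whatever
build the inputs use — the shipped HMGCR/PCSK9/NPC1L1 windows are GRCh37
conveniences and should be replaced for GRCh38 data). Exact replication of
published instrument counts for these targets depends on the specific
exposure GWAS release and trait-lookup snapshot used, which is why the test
surface is built on synthetic truth rather than on reproducing particular
published tables. A generalized-least-squares IVW against the LD matrix was considered and
deliberately not included: the clumping input is an $r^2$ matrix, which
carries no correlation *sign*, and a GLS weighting built on unsigned
correlations is ill-defined. The stricter-LD rerun is the package's
correlated-instrument mitigation; users with signed LD estimates can fit
GLS externally on the harmonized table.
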