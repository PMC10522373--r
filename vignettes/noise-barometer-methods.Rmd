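---
title: "Methods: clock fail-tests and the epigenetic noise barometer"
author: "methnoise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clock fail-tests and the epigenetic noise barometer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

DNA-methylation age clocks are elastic-net (EN) regressions that map an
Illumina array's beta values (per-CpG methylation estimates in $[0,1]$,
probes $\times$ samples) onto a numeric response — usually chronological
age. They predict well at the whole-population level, but two questions
matter for anyone who wants to read biology out of a clock:

1. **Are the selected CpGs biomarkers?** If the clock's probes were
   age-informative in some privileged way, the selected set should be
   stable when uninformative probes are perturbed, and a probe's weight
   should relate to how strongly its methylation tracks age.
2. **Is there a *measurement* (rather than prediction) of biological
   age in the same data?** A candidate is epigenetic noise: CpGs whose
   mean methylation is constant across life but whose dispersion grows
   with age.

`methnoise` implements both analyses end to end, together with a
synthetic 450K-style cohort generator that plants known probe classes, so
every claim can be scored against ground truth at desk scale.

## Clock model

Training minimizes the elastic-net cost on a standardized design
($n$ samples, $p$ probes):

$$C(X, y, w, \alpha, \rho) \;=\; \frac{1}{2n}\lVert Xw - y\rVert_2^2
  + \alpha\rho\lVert w\rVert_1
  + \frac{\alpha(1-\rho)}{2}\lVert w\rVert_2^2 .$$

`train_clock()` uses a random 80/20 train/test split, standardizes each
probe on the *training* samples only (the scaler is stored and reused
verbatim on any out-of-sample data), and picks $\alpha$ by 10-fold
cross-validation from a 10-point log-spaced grid anchored at the data's
maximal penalty (the smallest $\alpha$ that zeroes every weight); the grid
descends three decades from there. Defaults: $\rho = 0.5$, tolerance
$10^{-3}$, at most 5000 coordinate-descent iterations. The solver is
glmnet's cyclic coordinate descent; `elastic_net_cost()` exposes the
objective so a fit can be audited against what it claims to minimize (the
test suite checks $C(\hat w) \le C(0)$ and $C(\hat w) \le C(w_{OLS})$ on
every training run, and that EN coincides with OLS as $\alpha \to 0$).

Everything downstream treats the response as an opaque numeric series.
That is deliberate: one of the audits trains a clock on a population-size
series indexed by birth year and shows it predicts as well as an age
clock, which is the clearest demonstration that EN prediction does not
certify biological meaning.

Performance metrics are Pearson's $r$ and the median absolute error, plus
cohort-level residual summaries (mean, SD and Welch two-sided p-values of
predicted-minus-actual per cohort, optionally within age bins) — the
analysis a biomedical study would run instead of a single pooled
correlation.

## Fail-tests

* **`remove_and_retrain()`** — train a clock (model 0), delete its active
  probes from the universe, retrain with the identical seed and split
  (model 1). On redundant data model 1 recovers nearly the same accuracy
  on a disjoint probe set.
* **`nonclock_removal_scan()`** — independently remove a uniform-random
  fraction of the *non*-clock probes (fresh draw from the original
  non-clock list per fraction; a nested mode exists behind a flag) and
  retrain. The reported `unused_fraction` is the share of the original
  active set that the new model abandons, with the original active-set
  size as denominator. At fraction 0 the retrain is bit-identical, so
  `unused_fraction` is exactly 0 — a determinism check.
* **`rank_vs_age_signal()`** — for each active probe, $R^2$ of beta
  regressed on age, against the probe's rank by $|w|$ (rank 1 = largest).
  The summary reports the mean $R^2$ (the flat reference line) and the
  Spearman correlation of rank with $R^2$.
* **`rank_vs_sd_change()`** — the same audit with the probe's
  within-age-bin SD regressed on bin midpoints: does the clock select
  probes whose *noise* changes with age?
* **`binned_correlations()`** — predicted-vs-actual $r$ inside closed-open
  age bins; range restriction makes within-bin correlations weaker than
  the whole-range figure, and the audit quantifies by how much.

## The noise barometer

For a selected probe set, with reference means
$\mu_j = \frac{1}{N}\sum_i \beta_{ij}$ (all samples by default), the
per-sample, per-probe noise contribution is the absolute difference from
the mean, $\bar x_{ij} = |\beta_{ij} - \mu_j|$. The young-cohort
normalizer is $\zeta = \frac{1}{m}\sum_{k \in \text{young}} \sum_j \bar
x_{kj}$, and each sample's noise score is

$$\sigma_i = \frac{1}{\zeta}\sum_j \bar x_{ij},$$

so the young reference cohort averages exactly 1 by construction (an
invariant the tests assert to $10^{-12}$). "Young" is ages 25–28
inclusive; when a dataset has no such samples the youngest occupied
4-year window is used with a warning.

Three selection procedures find noise-detector probes:

1. **Approach 1** (single dataset): keep probes with $|r(\beta, \text{age})|$
   strictly inside $(0.02, 0.05)$ — near-invariant in mean but not the
   exact zeroes typical of flat artifacts — then keep those whose ADM
   correlates with age at $r \ge 0.2$.
2. **Approach 2** (multi-dataset consensus): per dataset, young/old mean
   difference below $10^{-3}$ beta units *and* $|r|$ inside the same
   window; intersect across datasets. `stratify_by_young_sd()` then
   splits survivors by young-cohort dispersion (absolute or
   mean-relative SD against thresholds such as 0.015 and 0.3); the
   direction (`most_regulated` keeps SD $\le$ threshold) must be stated
   explicitly because it is part of the scientific claim.
3. **Approach 3** (heteroscedasticity screen): White's test per probe —
   fit $\beta \sim \text{age}$, regress squared residuals on
   $(\text{age}, \text{age}^2)$, refer $nR^2_{aux}$ to $\chi^2_2$ — at
   $p < 0.05$, then require the old-group (67+) SD to exceed the
   young-group SD by at least 20%. A two-group variance F-test variant
   is available behind a flag.

`summed_sd_curve()` aggregates: per age bin (closed runs of 4 consecutive
integer years, "25-28", "29-32", ..., configurable), the sample SD
($n-1$ denominator; population mode available) of each selected probe
across the bin's samples, summed over probes, optionally normalized by
the youngest valid bin. `fit_noise_curve()` fits a least-squares
polynomial (default degree 3 — the lowest degree that can express a
plateau-then-rise shape; configurable 1–5) over bin midpoints, and
`map_biological_age()` inverts it: the noise value is set equal to the
polynomial and the real root inside the age domain is returned.

Root selection: the barometer's construct is that noise rises with age,
so with several in-domain roots the root on the longest
monotone-increasing branch of the polynomial is returned and a
`multiple_roots` flag is raised; with no in-domain root the nearer domain
endpoint is returned with a `clamped` flag. Multiplicity is always
surfaced, never silently resolved. The mapping round-trip
$|{\rm map}({\rm poly}(a)) - a|$ is exact (up to root-finder tolerance)
precisely when the fitted polynomial is strictly monotone on the domain;
a cubic fitted to a curve with a long flat plateau can lose monotonicity
near the edges, in which case edge values clamp. The round-trip test uses
a knot at 35 years, inside the observed 35–45-year plateau band, where
the degree-3 fit stays monotone.

`compare_cohorts()` computes healthy and disease curves over the same
probes with a *shared* young normalizer (healthy young bin) so disease
elevation is visible; `batch_resilience()` reports each dataset's
absolute deviation from the across-dataset median curve.

## The synthetic cohort generator

`simulate_cohort()` draws ages uniformly on the configured range (default
25–85 years) and beta values from Beta distributions parameterized by an
age-dependent mean and SD. Beta sampling — not a clipped Gaussian — keeps
values in $[0,1]$ without biasing means near the boundary; near-boundary
SDs are capped at distributional feasibility. Four planted classes:

| class | mean | dispersion |
|---|---|---|
| `drift` | slope 0.001–0.003 beta/yr, random sign | constant |
| `invariant_quiet` | flat | constant (young SD 0.02) |
| `invariant_noisy` | flat | grows by factor $1+\gamma$ over the range ($\gamma = 1$: SD 0.02 $\to$ 0.04) |
| `boundary_methylated` | 0.985 or 0.015 | half the baseline SD (tightly regulated loci) |

Dispersion growth is linear in age by default; an optional knot profile
(flat until a knot age, default 45, then linear) emulates the young-adult
low-noise plateau. Disease cohorts add a +0.01 mean shift on a random 5%
of probes and multiply noisy-probe dispersion by 1.3 — enough to separate
cohort curves without overwhelming the age structure. Batch structure is
a per-dataset, per-probe additive mean offset (SD 0.01). All draws flow
from one seed through name-keyed substreams, so a cohort regenerates
bit-identically and multi-batch designs share one probe truth.

**Drift redundancy.** Drift probes load on a small number of shared
latent processes (default 10 factors; per-probe shared noise SD is
$|s_j| \cdot \text{span} \cdot 0.3$). This mirrors co-methylation blocks
and shared aging processes (e.g. blood-composition shift) on real
arrays, and it matters for the audits: with conditionally *independent*
drift probes an elastic net's weight rank simply tracks each probe's
marginal age $R^2$ (Spearman near $-0.6$), because marginal and partial
signal coincide. With shared factors, probes within a block are
interchangeable, the weights are distributional accidents of the
optimizer, and the rank-vs-signal audit is null (|Spearman| typically
$< 0.1$ on the equal-slope redundant design) while a slope-weighted
positive control stays strongly coupled. Only the redundant design
reproduces what the fail-tests are about.

**What the generator does not emulate:** probe cross-hybridization,
SNP-under-probe artifacts, cell-type deconvolution structure,
non-Gaussian batch effects, and array-wide normalization coupling.
Passing recovery tests on this generator therefore shows the procedures
do what they claim under their stated assumptions; it does not certify
performance on real arrays, where technical noise is richer.

## Numerical choices and degenerate inputs

* Probes are rows, samples are columns everywhere (series-matrix
  convention).
* Missing-value policy is sample-drop: a sample with any missing beta
  among retained probes is removed at `align()` (probe-drop available
  for exploration).
* Invariance windows use $|r|$; invariant probes have near-zero $r$ of
  either sign. A signed mode is a flag.
* The young/old mean filter reads "less than 0.1% difference" as
  $|\Delta\text{mean}| < 0.001$ in absolute beta units (0.1% of the unit
  interval); a relative mode is a flag.
* Probes with zero training variance are dropped before clock fitting
  with a warning; constant probes in rank audits record $R^2 = 0$ with a
  flag; a White auxiliary regression with zero residual variance returns
  $p = 1$ flagged `degenerate`.
* The 80/20 split is unstratified by default (stratification by age
  quartile behind a flag).
* Sample SD uses the $n-1$ denominator throughout.

## Known limitations

* **The invariance window is a rarity filter, not a detector.** For a
  probe whose true $r(\beta,\text{age})$ is 0, the empirical $r$ is
  sampling noise of scale $1/\sqrt{n}$; the window $(0.02, 0.05)$
  captures it with probability well below 1 (about a third at $n = 300$),
  and a six-dataset intersection captures it with probability near zero —
  with growing $n$ the empirical $r$ shrinks *below* the lower bound, so
  sensitivity vanishes asymptotically. Tiny survivor sets (hundreds out
  of hundreds of thousands) are therefore the expected behaviour of
  approaches 1 and 2, and the package scores them on specificity and
  class enrichment, not on recall.
* **Per-probe error control degrades under correlated noise.** With
  shared drift factors, White tests of same-factor probes are positively
  dependent; an unlucky factor draw can admit a cluster of false
  positives, so the realized false-discovery proportion of approach 3
  fluctuates around its nominal level (0.02–0.15 across seeds at the
  default conditions) even though sensitivity stays at 1.
* The polynomial inverse is only as good as monotonicity of the fit (see
  above); degree 3 is a pragmatic default, not a model of aging.
* Elastic-net retraining instability is demonstrated, not explained: the
  scan quantifies how the selected set reshuffles, it does not map the
  optimizer's solution landscape.

## Problem sizes

The shipped analyses and tests run at desk scale, chosen so each stage
completes in seconds while keeping group sizes statistically meaningful:
cohorts of 300–500 samples over 600–2000 probes; six-batch designs with
300 samples per batch; 1000 replicates for White-test calibration
($n = 200$ null, $n = 500$ alternative); five seeds for trend checks.
The same code runs unchanged on full 450K matrices read with
`read_beta_matrix()`.
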