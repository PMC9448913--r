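---
title: "Methods: bump hunting and joint mother-child DMR analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bump hunting and joint mother-child DMR analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadDMR)
```

## The model

`dyadDMR` searches for differentially methylated regions (DMRs) in two
paired methylation-array cohorts — mothers and their children, each split
into an affected (neglect) and a control group — and asks which regions
are significant in both, and whether methylation in those regions tracks
the mother's adversity score.

The per-cohort engine is a bump-hunting procedure. Its model is a
probe-wise linear one: for probe $j$ and sample $i$,
$$\beta_{ij} = \mu_j + \theta_j\, g_i + \gamma_j^\top x_i + \varepsilon_{ij},$$
where $\beta_{ij}\in[0,1]$ is the beta methylation value, $g_i$ the
group indicator (positive $\theta_j$ = affected group more methylated),
and $x_i$ nuisance covariates (epithelial cell proportion, ages,
education). The scientific assumption that makes this a *region* method
is that true condition effects are spatially coherent: $\theta_j$ varies
smoothly along the genome within clusters of nearby CpGs, while probe
noise does not. Smoothing the estimated $\hat\theta_j$ within clusters
and scoring contiguous excursions by area therefore concentrates
evidence for multi-probe effects and dilutes isolated flukes.

Inference is by residual bootstrap rather than probe-wise tests:
whole-sample residual vectors from the covariates-only null model are
resampled with replacement, which preserves the cross-probe correlation
structure the area statistic exploits. Per-probe resampling would
destroy it and make the null too light-tailed.

The two cohorts are then combined without any cross-fitting: candidate
regions are matched by genomic overlap, and a region is called a shared
DMR when its bump p-value is below $\alpha$ in both cohorts. Because
the cohorts are analysed independently, the chance level of a matched
null pair passing both tests is $\alpha^2$ — with $\alpha = 0.01$, one
in ten thousand — which is the multiplicity control used in place of an
explicit correction. The p-to-z conversion $z = \Phi^{-1}(1-p)$ exists
so the *full* candidate lists can also be compared threshold-free
through the Pearson correlation of matched z-statistics.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `max_gap` | 1000 | bp | gap that splits CpG clusters |
| `pick_cutoff_q` | 0.95 | quantile | cutoff on the absolute smoothed profile |
| `n_bootstrap` (B) | 1000 | iterations | bootstrap null size (tests use 50–200) |
| `smoothing` | `loess_by_cluster` | — | local quadratic; `running_mean`, `none` |
| `smooth_span_bp` | 1000 | bp | tricube bandwidth of the smoother |
| `min_probes_smooth` | 7 | probes | clusters below this pass through |
| `alpha` | 0.01 | level | per-cohort significance; joint level $\alpha^2$ |
| `min_overlap_bp` | 1 | bp | least overlap for matching regions |

`max_gap`, `pick_cutoff_q`, B and the smoother family are the standard
settings for this analysis; the smoother's *bandwidth* and the minimum
cluster size are not dictated by the method and are set to 1000 bp and
7 probes — the bandwidth matching the cluster scale set by `max_gap`,
and 7 probes being the smallest cluster where a local quadratic with a
tricube window is meaningfully different from the raw profile.

One behaviour of `pick_cutoff_q` deserves emphasis: the cutoff is a
genome-wide quantile of the |smoothed| profile, so it presumes true
signal occupies well under $1-q$ of probes. If planted (or real) signal
approaches 5% of the genome at $q = 0.95$, the cutoff climbs onto the
signal itself, null excursions vanish, and the bootstrap null empties
(the engine then warns and reports p = 1). Simulations in this package
therefore keep planted probes at ≤ 2–3% of the genome.

## What the generator emulates — and what it does not

`sim_config()` / `simulate_dataset()` produce an EPIC-like dataset at
reduced scale: two paired cohorts with the study's group sizes (51/87
mothers, 40/75 children by default), probe annotations with
geometric-gap spacing on a few chromosomes, planted multi-probe DMRs
(shared, mother-only, child-only; ≥ 7 probes each), covariate effects,
contaminant probes, detection failures, and SREI adversity scores.

Generative model: each probe gets a baseline beta in [0.05, 0.95];
each sample's value is
$\mathrm{logit}^{-1}(\mathrm{logit}(b_j) + \delta_j\,[\text{affected}] +
\gamma^\top x_i + \varepsilon)$, $\varepsilon \sim N(0, \sigma^2)$ on
the logit scale. The logit-normal noise keeps values bounded with
variance largest mid-range, as in real beta data. The planted shift
$\delta_j$ is computed exactly so the affected-group beta exceeds the
control beta by `effect_size` *before* noise (verified to 1e-6 in
tests). Values are converted to M/U intensities with fixed total
$M+U = 10{,}000$, so the +100 offset in $\beta = M/(U+M+100)$ is
exercised while the round-trip stays exact.

Deliberate idealisations, so ground truth is recoverable by design:
planted regions are generated as their own `max_gap` clusters (flanking
gaps > 1000 bp, internal gaps ≤ 900 bp), contamination flags and
detection failures land only on filler probes, and noise is independent
across probes. SREI totals are drawn per group as rounded truncated
normals at the study's group moments (neglect 16.76 ± 8.65, control
11.59 ± 7.70) and then decomposed into 16 items scored 0/1/3 — sixteen
*independent* items cannot reach a total SD of 8.65 (the maximum is 6),
so a totals-first construction is the only one consistent with those
moments. Children inherit their mother's SREI total through the dyad
link.

Consequently, passing tests demonstrate the *algorithms* — calibration
of the bootstrap null, recovery of planted effects, correct joint
logic — not robustness to what real arrays add: probe-type chemistry
differences, spatially correlated noise, batch structure beyond a plate
label, cell-composition variation beyond a single proportion, or
partially overlapping DMRs between cohorts.

## Numerical choices

- **Quantiles** use linear interpolation between order statistics
  (R type 7), for both the cutoff and null summaries.
- **Smoothing is a linear map.** The cluster-wise local quadratic
  (tricube weights, fixed bp bandwidth, adaptively widened so at least
  four probes carry weight; degree lowered on singular fits) is
  materialised once as a sparse block-diagonal hat matrix. Every
  bootstrap iteration is then one sparse matrix product, which is what
  makes B = 1000 affordable. Exactness on constant, linear and
  quadratic profiles and the absence of cross-cluster leakage are
  tested.
- **Bootstrap.** Null-model residuals are rescaled by
  $\sqrt{n/(n-k_0)}$ so their variance matches the error variance;
  without this the null areas are slightly too small and bump p-values
  anti-conservative (the pooled-null Kolmogorov–Smirnov test catches
  it). The observed cutoff is held fixed across iterations; null areas
  are pooled across all iterations and clusters into one empirical
  null, and p-values use the plus-one rule
  $(1 + \#\{A_0 \ge A\})/(1 + N)$, so no p is ever exactly 0.
- **Degenerate inputs.** An empty bootstrap null yields p = 1 with a
  warning; p = 1 is clipped just below 1 (half the bootstrap
  resolution) before the z-transform so z stays finite; a zero-variance
  z vector makes the correlation `NA` with a warning rather than an
  error.
- **Ties and ordering.** Bumps are ordered by p, then descending area,
  then genomic position. Region matching is one-to-one greedy by
  descending overlap with ties broken by leftmost start — chosen
  because "shared" does not define multiplicity handling; the greedy
  rule is deterministic and symmetric in the cohort order (tested).
- **Counts from percentages.** Printed percentages are reconstructed as
  counts by round-half-up; for multi-category rows the rounding residual
  is assigned to the last (smallest) category so columns sum to the
  known group size. 2×2 tables use the Yates continuity correction,
  larger tables plain Pearson — the combination that reproduces the
  reference statistics from printed data.

## Design decisions on genuinely open points

- **Area statistic**: the sum of |smoothed coefficient| over member
  probes (not the area above the cutoff). Monotonicity of p in area is
  tested; the alternative convention would only shift all areas by a
  cutoff-dependent amount within a run.
- **Intersection threshold**: the methods narrative and the results of
  the reference analysis differ (0.001 vs 0.01); the default is
  $\alpha = 0.01$, matching the reported DMR counts and the
  $\alpha^2 = 10^{-4}$ joint level, and both are configurable.
- **z convention**: one-sided magnitude $z = \Phi^{-1}(1-p)$ by
  default, since region evidence is scored by |area|; a signed
  two-sided variant is available because shared regions do carry a
  per-cohort sign pattern (+/+, −/+, …) that is reported separately.
- **Probe detection filtering across cohorts**: pooled ("joint") by
  default in the pipeline, since both cohorts share one probe set; a
  per-cohort mode exists.
- **SREI association design**: the group indicator stays in the design
  when SREI is the tested variable (SREI and group are correlated, so
  dropping group would attribute group differences to adversity); a
  flag allows dropping it.
- **Dye bias**: an optional simplified per-sample per-channel median
  rescaling is provided (off by default); full dye-bias calibration
  algorithms are out of scope.

## Problem sizes used by the test-suite experiments

Calibration uses 20 replicate null datasets of 2,000 probes with 30+30
samples per cohort at B = 100 (pooled bump p-values within the binomial
95% band around 0.01; joint null hits ≤ 3 across all matched pairs).
Recovery uses one 10,000-probe dataset with twenty 10-probe shared
regions (shift 0.1, logit noise 0.3, 50+50 and 40+40 samples, B = 100);
adversity-slope recovery uses 50 replicates of an 800-probe,
100-mother design with a −0.005 beta-per-point slope at B = 60. These
sizes keep planted signal ≤ 2.5% of the genome (see the cutoff note
above) and give each check enough events to be statistically meaningful.

## Known limitations

The engine is designed for 10³–10⁵ probes; genome-scale (850k) inputs
would need chunked smoother construction. IDAT parsing, normalization
(quantile/functional), cell-type deconvolution and external genomic
annotation are out of scope — detection p-values, cell proportions and
gene labels are taken as inputs. The bootstrap assumes exchangeable
residual vectors across samples; strong heteroscedasticity across
samples would call for a wild bootstrap. And as with any
joint-significance intersection, the $\alpha^2$ chance level applies to
each matched pair, not family-wise across all pairs.
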