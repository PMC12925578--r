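---
title: "Methods: CTC marker dynamics and single-cell expression pipelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CTC marker dynamics and single-cell expression pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcdyn)
```

## The analysis problem

Index sorting deposits single circulating tumor cells (CTCs) while recording
each cell's fluorescence in every channel, so per-cell EpCAM and PSMA median
fluorescence intensities (MFI) can be linked to patient, treatment cycle and
clinical response. Raw MFIs are not comparable across sorter runs: laser and
detector drift introduce a multiplicative session effect, and instrument
baseline subtraction leaves a small additive artifact that can push dim
cells below zero. The flow pipeline models the measurement as

\[
\mathrm{MFI}_{ic} \;=\; \mu_{g(i),t(i),c}\; \beta_{s(i),c}\; \varepsilon_{ic} \;-\; \delta_{ic},
\]

where \(\mu\) is the biological group/cycle/channel level, \(\beta\) the
per-session per-channel batch factor, \(\varepsilon\) multiplicative
lognormal cell noise, and \(\delta \ge 0\) the baseline-subtraction
artifact. Each session carries a bright C4-2 control well measured under the
same \(\beta\); dividing every event by the session-matched control median
cancels \(\beta\) exactly, which is the package's normalization invariant
(verified in the tests by rescaling a session and checking the normalized
output is unchanged).

All location comparisons use rank statistics (Mann-Whitney U), so they are
invariant to monotone transforms; log-transformation affects reported
medians, not p-values. Subpopulation splits are tested with χ² statistics.

## Flow-pipeline stages and their parameters

* **Control QC** — per-session control medians; cross-session grand median,
  MAD and MADM (MAD of the per-session medians). The MAD scale constant
  defaults to 1.0 because these are descriptive QC quantities; 1.4826 makes
  them normal-consistent estimates of a standard deviation. Duplicated
  control rows (same session and channel values) are removed before
  summarizing.
* **Normalization** — division by the session-matched control median per
  channel; events from sessions without controls are a hard error, because a
  silently unnormalized session would corrupt every downstream comparison.
* **Outcome filter** — samples from patients whose treatment outcome is
  unknown are excluded and logged; they cannot enter a two-group test.
* **Imputation** (`imputation_config`) — negative or zero normalized values
  are replaced by the mean of `n_draws = 2` values drawn without replacement
  from the `draw_set_size = 10` lowest strictly positive normalized values
  of that channel, dataset-wide. Drawing from the low tail keeps imputed
  cells at the detection floor; averaging two distinct members avoids
  duplicating an existing value. Every imputed value therefore lies inside
  the closed range of the drawing set and, with the defaults, in the 45
  possible pair means — the property the acceptance suite enumerates.
  Imputation precedes outlier filtering and never touches positive values.
* **Outlier filter** (`outlier_rule`) — per channel, events farther than
  `k = 3` MADs from the median of log10 MFI are removed (flagged on either
  channel ⇒ removed). The rule is scale-free and symmetric; `k` trades
  robustness against retention. If the MAD is zero all values are identical
  and nothing is removed.
* **Thresholds** — per channel, the minimum over samples of the per-sample
  median normalized MFI. Of the plausible readings of a "minimum median"
  gate (over events, patients or samples) the per-sample reading matches a
  single gating line per channel that sits at or below every sample's
  typical level; it is also the most conservative choice that still uses
  only retained events. Channel positivity uses `>=`, so a cell exactly at
  threshold is positive — an arbitrary but fixed boundary convention the
  tests pin down.
* **Dynamics** (`cycle_dynamics`) — cycles where either response group has
  fewer than `min_cells_per_cycle = 5` cells are dropped entirely. Five is
  the smallest sample a rank test can reject at α = 0.05 two-sided against a
  comparable group, and it excludes the sparse late-cycle tail the simulator
  plants (3 Responder cells, 0 Nonresponder cells at cycle 4).
* **Distribution tests** — the Responder/Nonresponder split of each
  subpopulation is tested against the overall group proportions by default,
  which accounts for unequal group sizes; an `"equal"` expectation is
  available when a balanced design is the null of interest.

## The statistics module

`mann_whitney_u` uses the exact null distribution of U for tie-free samples
with \(n_1+n_2 \le 16\) (the null distribution is symmetric, so the
two-sided p is twice the smaller tail), and otherwise a normal approximation
with tie and continuity corrections; the approximation agrees with
`wilcox.test(exact = FALSE, correct = TRUE)` to machine precision, and the
exact branch is checked against full enumeration of all labelings for every
rank configuration with \(n_1+n_2 \le 10\). The exact rejection probability
of the approximate branch at \(n_1 = n_2 = 20\), α = 0.05 is 0.0491, which
the null-calibration test brackets empirically.

`spearman_corr` correlates midranks. For tie-free samples with
\(n \le 9\) it uses the exact permutation distribution of ρ (cached per
\(n\)); beyond that, the t approximation with \(n-2\) degrees of freedom.
The exact domain was set to 9 — the same bound base R's `cor.test` treats
exactly — because the measured worst-case discrepancy between the t
approximation and enumeration is 0.024 at \(n = 8\), too coarse for a test
that asserts agreement with enumeration, while at \(n \ge 10\) full
enumeration (10! orders) stops being practical and the approximation error
falls off. ρ = ±1 returns p = 0 from the t branch (the continuous limit);
the exact branch reports the attainable \(2/n!\)-scale value.

χ² statistics are assembled directly from their definitions with p-values
from the χ² survival function, and `bonferroni_adjust` is `min(1, p·m)` with
`m` at least the number of tests supplied.

## What the simulator emulates — and what it does not

`cohort_config()` defaults are the study conditions:

* 10 patients per response group over cycles 0–4, plus a 10% fraction with
  unknown outcome to exercise the exclusion rule;
* per-sample sorted CTC counts from a truncated negative binomial
  (dispersion 2) calibrated so group medians are 2 (Responder) and 8
  (Nonresponder);
* planted normalized marker medians per group/cycle/channel from
  `default_marker_medians()` — Nonresponder EpCAM starts near 0.83 against
  Responder 0.33, Responder PSMA declines 0.192 → 0.118 → 0.045 → 0.019,
  Nonresponder PSMA starts low (0.068); unprinted cells of the grid are
  flat or interpolated continuations of those trajectories;
* within-sample lognormal MFI noise with σ = 0.25 on the natural-log scale,
  chosen a priori so that the planted between-group and cycle contrasts are
  within the power of a rank test at the cohort's per-cycle cell counts
  (the weakest planted contrast, PSMA at cycle 1, is a 1.34-fold ratio);
* session batch factors with lognormal σ = 0.15 (cancelled by
  normalization), and a half-normal detection-floor artifact with σ = 0.5
  raw units against a raw control median of 50, which makes a few percent
  of dim PSMA events negative so imputation has work to do.

The generator emulates structure, not biology: no spillover or
compensation, no doublets, no sorter optics, no within-patient correlation
beyond the shared sample median, and the lognormal within-sample form is an
assumption (flow MFIs are strictly positive and right-skewed
pre-subtraction, but the true distributional form is unknown). The
detection-floor subtraction biases the smallest medians downward by roughly
its half-normal mean (≈ 0.4 raw units, i.e. ≈ 0.008 normalized), visible as
a mild shrinkage of the recovered late-cycle PSMA medians. Passing the
recovery tests therefore shows the pipeline recovers planted effects under
this noise model at these sample sizes — not that it would do so on any
real cohort.

The count simulator (`counts_config()`) draws negative-binomial counts
(gene-level size 5, moderate overdispersion) over 2,000 genes × 120 cells in
two clusters, with 100 planted differential genes at |log₂FC| = 1.5 (85%
up), a 50-gene mitochondrial block pinned at ~6% of reads, and planted
low-quality cells (8% shallow libraries below the count threshold, 8% with
an 80-fold inflated mitochondrial block) so QC filters are exercised on both
sides. Planted differential genes are drawn from genes with base mean ≥ 5
counts: below that depth a two-fold shift is outside the power of a
rank test at 60 cells per cluster, so planting there would measure the
simulator, not the method. With 2,000 genes the `max_genes = 7,800` rule
cannot fire in the fixture; the QC boundary suite instead builds an
8,000-gene matrix directly. Gene-set score matrices are generated by a
Gaussian copula on the midranks of a planted gene's normalized expression,
so the population Spearman correlation equals the target (a monotone
transform — the expression itself — when the target is 1).

## Single-cell stage conventions

* QC removal uses strict inequalities (`< 4,000` counts, `< 1,000` or
  `> 7,800` genes, `> 75%` mitochondrial reads), so boundary cells are
  retained; the mitochondrial fraction is computed on raw counts.
* `lognormalize` is `ln(1 + 10^4 · count / total)` — plain depth removal
  feeding rank tests; variance-stabilizing transforms, embeddings and graph
  clustering are deliberately out of scope, and cluster labels come from
  metadata.
* log₂FC is the ratio of cluster means of back-transformed normalized
  expression with pseudocount ε = 1e−9; the ranking score
  log₂FC × (−log₁₀ p_adj) floors the adjusted p at 1e−300 so a p rounded to
  zero cannot produce an infinite score.
* The hub rule is a conjunction: ρ ≥ 0.2 with Spearman p < 0.05 for the same
  (gene, gene set) in at least two distinct scoring methods, and membership
  in the significant DEG set. The "rank-correlation score" is taken to be
  Spearman's ρ itself. Passing in two different gene sets with one method
  each does not qualify.

## Pooling arithmetic

Molarity uses the standard 650 g/mol per base pair of double-stranded DNA.
Ties at the cohort median are assigned to the below-median group (used
neat); the default per-sample contribution is the median molarity × 1 µL,
so a sample at the median contributes exactly 1 µL. The plan is
scale-invariant: multiplying all molarities by c divides all volumes by c.

## Problem sizes and determinism

The test suite runs the full flow pipeline at 10 patients per group
(~500–600 events) across 50 seeds for effect-direction recovery, 2,000
null replicates for rank-test calibration, exhaustive enumeration for the
exact branches, and 21 count fixtures (2,000 genes × 120 cells) for
differential-expression recovery and family-wise error control — sizes at
which the whole suite completes in about a minute while keeping every
Monte-Carlo margin wide. Every random stage draws from a substream derived
from one master seed (`derive_seed`), stages can be regenerated
independently, and a rerun with the same configuration is byte-identical,
including the serialized summary.

## Known limitations

* The study's patient-level p-values cannot be reproduced: the underlying
  FCS files and sequencing data are not publicly deposited, so all
  quantitative claims here are about recovery of planted truth under the
  stated noise model.
* The imputation rule assumes at least ten positive values per channel and
  that negatives are artifacts rather than biology.
* The Wilcoxon DGE stage tests medians per gene independently; it inherits
  the usual compositional bias of depth-normalized fold changes when many
  genes shift in one direction (visible as mild shrinkage of planted
  log₂FC).
* `chi_squared_independence` has no continuity or small-expected-cell
  correction; margins with expected counts under ~5 should be interpreted
  with care.
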