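# ctcdyn

Analysis pipelines for index-sorted **circulating tumor cells (CTCs)** from
patients with metastatic castration-resistant prostate cancer undergoing
PSMA-targeted radionuclide therapy. The package covers the two computational
arms of such a study and a seeded synthetic cohort generator that makes every
stage testable without patient data:

1. **Flow-cytometry marker dynamics.** Per-cell EpCAM and PSMA median
   fluorescence intensities (MFI) from index sorting are normalized by
   session-matched C4-2 control medians, negative baseline-subtraction
   artifacts are imputed from the channel's ten lowest positive values,
   robust outliers are removed, cells are classified into
   EpCAM⁺PSMA⁻ / EpCAM⁺PSMA⁺ / EpCAM⁻PSMA⁺ subpopulations by
   minimum-median thresholds, and marker levels are compared between
   Responders and Nonresponders and across treatment cycles with
   Mann-Whitney U and χ² tests.
2. **Single-cell RNA-seq downstream analysis.** Plate-based (Smart-seq2-like)
   count matrices are filtered on total counts, detected genes and
   mitochondrial fraction; differential expression between two cell clusters
   uses per-gene Wilcoxon rank-sum tests with Bonferroni correction and a
   two-fold-change filter; genes are ranked by
   log₂FC × (−log₁₀ p_adj); hub genes are those correlating (Spearman
   ρ ≥ 0.2, p < 0.05) with per-cell gene-set scores in at least two scoring
   methods while being significant DEGs.

A small third module computes sequencing-library pooling plans from
fragment-analyzer summaries (molarity = c·10⁶ / (L·650) nM for concentration
c in ng/µL and fragment length L in bp; sub-nanomolar libraries are
discarded, above-median libraries diluted to the median, and equal
femtomole amounts pooled).

The core statistics (exact/approximate Mann-Whitney U, χ² goodness-of-fit
and independence, Spearman correlation with an exact small-sample branch,
Bonferroni adjustment, median/MAD/MADM summaries) are implemented in the
package and verified against brute-force enumeration oracles and the base R
reference implementations in the test suite.

## Worked example

```r
library(ctcdyn)

mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
#> exact test: statistic = 0, p = 0.1 (n1 = 3, n2 = 3)

bundle <- run_pipeline(pipeline_config(seed = 1))
f <- bundle$summary$flow
cat(sprintf("retained CTC events: %d of %d simulated\n",
            f$n_retained, f$n_events_simulated))
#> retained CTC events: 483 of 519 simulated
cat(sprintf("CTC counts/sample: Responder median %.1f, Nonresponder median %.1f (p = %.2g)\n",
            f$ctc_count_median_responder, f$ctc_count_median_nonresponder,
            f$ctc_count_p))
#> CTC counts/sample: Responder median 3.0, Nonresponder median 8.0 (p = 1e-06)

subset(bundle$flow$dynamics$PSMA, group == "Responder",
       c(cycle, n, median_mfi, p_vs_baseline))
#>  cycle  n median_mfi p_vs_baseline
#>      0 29 0.19216818            NA
#>      1 33 0.12433954  4.403056e-07
#>      2 27 0.03429443  1.442424e-10
#>      3 28 0.01185499  9.622906e-11

s <- bundle$summary$scrna
cat(sprintf("DEGs: %d significant (%d up, %d down); hub genes: %s\n",
            s$n_significant_degs, s$n_up, s$n_down,
            paste(s$hub_genes, collapse = ", ")))
#> DEGs: 97 significant (82 up, 15 down); hub genes: GENE0004, GENE0009
```

The Responder PSMA trajectory declines from a baseline median of ~0.19 to
~0.03 (cycle 2) and ~0.01 (cycle 3) with strongly significant
cycle-vs-baseline rank tests — the planted antigen-loss signal the simulator
encodes. `write_report(bundle, "out/")` writes the tables (classification,
dynamics, differential expression, pooling plan), a text report and the
summary JSON.

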