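# refstab

Reference-gene (housekeeping-gene) stability evaluation for RT-qPCR
normalization.

Relative quantification by RT-qPCR divides a target gene's signal by that of
internal reference genes assumed to be constitutively expressed. When the
experimental condition itself perturbs those references — as extracellular
acidosis (pH ≈ 6.5 vs 7.4) does to commonly used housekeeping genes in
osteosarcoma cells, the motivating application — normalized results are
silently biased. `refstab` takes a samples × genes matrix of raw
threshold-cycle (Ct) values and answers three questions: *which candidate
reference genes are stable, how many are needed, and what do normalized fold
changes look like once you use them?*

## What it computes

Five stability estimators, all lower-is-better:

* **geNorm**: comparative-Ct linearization `q = E^(Ct_min − Ct)`, stability
  `M_j = mean_k sd_i(log2 q_ij/q_ik)`, stepwise exclusion ranking, pairwise
  variation `V_n/n+1 = sd log2(NF_n/NF_{n+1})` between nested normalization
  factors, and the V ≤ 0.15 rule for the optimal number of reference genes;
* **NormFinder-style model-based scoring**: ANOVA-type decomposition of
  log2 expression with per-gene residual variances (small-panel corrected)
  and, with condition groups, empirical-Bayes-shrunken gene-by-group
  deviations;
* **BestKeeper**: Ct descriptives, the 1.0-cycle dispersion cutoff, and each
  gene's Pearson correlation with the geometric-mean index;
* **comparative ΔCt**: mean SD of pairwise Ct differences;
* **coefficient of variation**: sd(Ct)/mean(Ct).

On top of those: a geometric-mean-of-ranks **consensus** with a recommended
reference set, **ΔΔCt relative expression** (`2^−ΔΔCt`) against single- or
multi-gene normalization factors, a one-tailed Mann–Whitney comparison of
normalizer precision, and a **seeded synthetic Ct generator** reproducing the
two-condition, three-cell-line, three-replicate study design with published
per-gene means/SDs (`hkg_reference_panel()`), so the whole pipeline is
testable without laboratory data.

## Worked example

```r
library(refstab)

es <- simulate_ct(default_synthetic_config(seed = 42))
es
#> <ct_set> 18 samples x 15 genes
#> groups:  pH6.5 (n=9), pH7.4 (n=9)

res <- analyze_subset(es, grouped = TRUE)   # both-pH analysis
head(res$consensus$table[, c("gene", "normfinder", "genorm", "bestkeeper",
                             "delta_ct", "cv", "geo_mean_rank")], 3)
#>       gene normfinder genorm bestkeeper delta_ct cv geo_mean_rank
#> 1    YWHAZ          1    1.5          3        3  1      1.682933
#> 2 18S rRNA          4    3.0          1        1  7      2.425805
#> 3   RPL13a          3    1.5          4        2  6      2.930156

res$genorm$m_values[c("YWHAZ", "TBP")]
#> YWHAZ   TBP
#> 1.585 3.450
```

Each row shows one gene's rank under the five methods and the geometric mean
of those ranks; the consensus sorts that statistic ascending, so here YWHAZ
is the most reliable reference in this simulated study while TBP — whose
configured summaries carry both the largest dispersion and the largest
pH-dependent shift — lands last (geometric-mean rank 15.0) and far above the
M = 1.5 instability flag. The per-sample multi-gene normalization factor for
downstream ΔΔCt is then:

```r
nf <- normalization_factor(es, c("YWHAZ", "GUSB", "GAPDH", "18S rRNA"))
round(head(nf, 3), 4)
#> pH6.5_HOS_r1 pH6.5_HOS_r2 pH6.5_HOS_r3
#>       0.2030       0.3689       0.2864
```

`run_stability_pipeline(es, "outdir")` writes the full report: per-gene
condition summaries, per-method score/rank tables for each condition subset,
the V series, consensus tables, and a JSON manifest.

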