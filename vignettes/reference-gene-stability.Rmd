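---
title: "Evaluating reference-gene stability from RT-qPCR Ct data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating reference-gene stability from RT-qPCR Ct data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

Relative quantification by RT-qPCR reports a target gene's expression as a
ratio against one or more internal reference ("housekeeping") genes. The whole
construction rests on the references being constitutively expressed: if a
reference responds to the experimental condition, every normalized measurement
inherits that response with opposite sign. Conditions that broadly reprogram
transcription — such as the extracellular acidosis (pH ≈ 6.5) of the tumor
microenvironment, the motivating application here — are exactly the settings
where commonly copied reference genes fail quietly.

`refstab` evaluates a candidate panel from a samples × genes matrix of raw
threshold-cycle (Ct) values. Ct is inversely proportional to log2 template
abundance; one cycle is approximately a twofold change in input. Because no
single stability criterion is uncontroversial, the package implements the
five estimators in common use, a rule for how many references are needed, and
a consensus that aggregates the five rankings.

## The five stability estimators

All methods score *lower = more stable*.

**geNorm.** Ct values are first linearized per gene by the comparative-Ct
transform, $q_{ig} = E^{\min_{i'} Ct_{i'g} - Ct_{ig}}$, with amplification
base $E$ (default 2) and the sample with the lowest Ct as calibrator, so
$\max_i q_{ig} = 1$. For genes $j,k$ the pairwise variation
$V_{jk} = \mathrm{sd}_i\!\left(\log_2 q_{ij}/q_{ik}\right)$ measures how far
the two genes move in parallel; the stability measure
$M_j = \frac{1}{k-1}\sum_{k \ne j} V_{jk}$ averages it over all partners.
Ranking proceeds by stepwise exclusion: the highest-M gene is removed and M
recomputed until two genes remain; that pair is intrinsically unresolvable by
a pairwise measure and is reported tied (both rank 1.5). M above 1.5 is
flagged as conventionally unacceptable.

**Number of references.** With genes ordered by the geNorm ranking,
$NF_n$ is the per-sample geometric mean of the $n$ most stable genes'
quantities and $V_{n/n+1} = \mathrm{sd}_i \log_2 (NF_n / NF_{n+1})$. A small
$V_{n/n+1}$ means the $(n{+}1)$-th gene no longer changes the normalization
factor; the smallest $n$ with $V_{n/n+1}$ at or below 0.15 is recommended. A
tolerance of 0.005 is added by default so that values such as 0.155 count as
reaching the cutoff, matching how the rule is applied in practice;
`tolerance = 0` restores the strict reading. If nothing qualifies the full
panel size is returned with a warning.

**NormFinder (model-based).** On $y = \log_2 q$, the model decomposes
variation into per-sample effects (loading, RT efficiency), per-gene levels,
and gene-specific residual noise. Ungrouped, the matrix is double-centered
and the per-gene residual mean square $s^2_g$ is corrected for the leakage of
every gene's noise into the per-sample average:
$\hat\sigma^2_g = \frac{k}{k-2}\left(s^2_g - \frac{\sum_h s^2_h}{k(k-1)}\right)$,
which is unbiased under heteroscedastic gene variances (the package's tests
verify recovery of an injected variance by simulation). Stability is
$\sqrt{\max(\hat\sigma^2_g, 0)}$; the flooring is needed because the
correction can produce small negative estimates for very quiet genes.
With condition groups, residual variances are estimated within groups the
same way, and the gene-by-group deviation $d_{g\gamma}$ (the gene's group
mean of sample-centered expression minus its overall mean) captures
systematic condition dependence — precisely what disqualifies a reference.
Across genes, $d$ is shrunk toward zero by the empirical-Bayes factor
$\hat\tau^2 / (\hat\tau^2 + \hat\sigma^2_{g\gamma}/n_\gamma)$, with
$\hat\tau^2$ the method-of-moments estimate of the true interaction variance;
the stability value averages $|\tilde d_{g\gamma}|$ plus the posterior
sampling SD over groups, so both systematic shift and noise count against a
gene. The classical "best two-gene combination" output is out of scope.

**BestKeeper.** Descriptive statistics on raw Ct: geometric and arithmetic
means, range, and the classical dispersion "ST.DEV [±CP]", implemented as the
mean absolute deviation about the arithmetic mean (the legacy spreadsheet
convention; `sd_method = "sd"` switches to the sample SD). Genes with
dispersion above 1.0 cycle are flagged unstable. The BestKeeper index is the
per-sample geometric mean of Ct across candidates, and each gene's Pearson
correlation with the index (two-sided t-based p) is reported. Ranking is by
dispersion ascending, with the correlation shown alongside, since dispersion
is what the 1.0-cycle exclusion rule acts on.

**Comparative ΔCt.** For every gene pair, the SD across samples of
$Ct_{ij} - Ct_{ik}$; a gene's score is the mean of its pair SDs. Like geNorm
it is invariant to global per-sample shifts, but it skips linearization and
stepwise exclusion.

**Coefficient of variation.** $\mathrm{sd}(Ct)/\mathrm{mean}(Ct)$ per gene
within the analyzed sample set. Unlike the ratio-based methods it is
sensitive to per-sample global shifts and to the absolute expression level;
it is included because it is routinely reported and contributes an
independent, if crude, view.

Throughout, "SD" is the sample SD ($n-1$ denominator): panels of three
biological replicates per cell line are small, and that is the convention of
the qPCR literature.

## Consensus and the recommended set

Each method contributes a tie-averaged rank vector (1 = most stable; geNorm's
final pair enters as 1.5/1.5). The comprehensive ranking orders genes by the
geometric mean of their ranks across the five methods; ties are broken by
arithmetic mean rank, then name, and logged. The recommended reference set is
the top `optimal_n` consensus genes, with `optimal_n` from the pairwise
variation rule. Exactly the five estimator rankings enter the geometric mean;
the gene-count analysis determines how many genes to take, not their order.

One property worth noting: geometric-mean aggregation is *not* invariant to
entering the same method twice (duplication reweights that method and can
reorder genes); it is invariant to adding a fully tied, uninformative
ranking. The test suite pins down the latter.

```{r}
ranks <- hkg_reference_ranks("combined")
methods <- lapply(c("normfinder", "genorm", "bestkeeper", "delta_ct", "cv"),
                  function(m) stability_result(m, ranks = setNames(ranks[[m]],
                                                                   ranks$gene)))
head(comprehensive_ranking(methods)$table, 4)
```

## ΔΔCt normalization against the selected references

`normalization_factor()` returns the per-sample geometric mean of the
selected references' relative quantities. `relative_expression()` computes
$2^{-\Delta\Delta Ct}$ folds for a target, where the reference Ct entering
$\Delta Ct$ is the arithmetic mean over the selected genes — algebraically
identical to dividing by the geometric mean of their linear quantities. The
calibrator may be a single sample (its fold is exactly 1) or a group label,
in which case the group's mean ΔCt is the baseline; the group default suits
treatment-versus-control designs, where "fold relative to the control
condition" is the quantity of interest. `compare_normalizer_precision()`
contrasts the fold lists produced by two normalizers via their standard
errors and a one-tailed Mann–Whitney test (exact when untied), the usual way
a noisy normalizer is shown to inflate apparent variability.

## The synthetic study generator

Replicate-level Ct data for the motivating osteosarcoma experiment are not
public; the generator stands in for them with the same design: 15 candidate
genes, two pH conditions (6.5/7.4), three cell lines × three biological
replicates per condition (9 samples per condition, 18 total). Per-gene
per-condition means and SDs default to the published panel summaries
(`hkg_reference_panel()`), spanning means from ~9.6 (18S rRNA) to ~30.4
cycles (G6PD) and SDs from 0.7 to 3.1 cycles.

The noise model is additive Gaussian on the Ct scale — i.e. log-normal
abundance noise, the regime every estimator here assumes — independent across
genes, plus an additive per-cell-line offset shared by all genes of a sample
(global input-amount differences) and an optional shared per-sample offset
(`sample_offset_sd`) emulating loading/RT variation, which the ratio-based
methods should cancel. Each gene draws from its own substream derived from
the root seed and the gene's name, so results are reproducible and adding or
removing a gene never perturbs the other genes' draws.
`spike_unstable_gene()` shifts one gene's mean under the second condition,
planting ground-truth instability for recovery tests.

What the generator deliberately does not model: amplification-efficiency
variation between assays, technical-replicate structure, censoring at the
maximum cycle (Ct > 40), and gene–gene correlation beyond the shared sample
offset. The published SDs also conflate between-cell-line and residual
variance; the default attributes everything to residual noise (offsets 0)
since no separate components were reported. Consequently, passing tests on
synthetic data demonstrate correct estimator behavior under the assumed
model, not robustness to efficiency artifacts or correlated co-regulation.
One visible consequence: with genes independent by construction, the
pairwise-variation series declines more slowly than on real data, where
shared biology correlates candidates, so the synthetic optimal gene count is
typically larger than the 4 genes the rule yields on the real study.

## Numerical and design choices

* **Efficiency fixed at 2** unless overridden: per-assay efficiencies were
  not available, and the transform is monotone in any base > 1.
* **Calibration within the analyzed subset**: each condition analysis
  linearizes its own samples, so every analysis is self-contained and
  per-gene maxima are exactly 1 within it.
* **geNorm removal ties** are broken toward the gene with larger
  log-expression SD, then alphabetically, and logged — stepwise exclusion
  must be deterministic for reproducible reports.
* **Negative NormFinder variance estimates are floored at 0** before the
  square root; variances are nonnegative and flooring is the established
  behavior of model-based scoring.
* **Missing Ct** is carried explicitly as `NA` (never silently zero),
  dropped pairwise in summaries with reduced-n warnings, and rejected with a
  clear error by the linearization step, which cannot average over holes.
* **NormFinder grouping**: single-condition analyses run ungrouped; the
  combined two-condition analysis uses condition as the group factor. Cell
  line is not used as a group by default — its additive effect is already
  absorbed by per-sample centering.
* **Recovery-test design**: parameter-recovery simulations use a
  homoscedastic variant of the panel (equal condition means, 1-cycle SDs) so
  that a spiked condition shift is the unique ground truth. On the panel's
  own summaries that experiment would be confounded: TBP's configured
  dispersion (2.2–3.1 cycles) plus its intrinsic 1.4-cycle condition shift
  make it the true least-stable gene, so a moderate spike elsewhere *should
  not* displace it — and does not.
* **Problem sizes in the test suite**: oracle-equivalence checks run 100
  random 5–6-gene instances per statistic at 1e-12; Monte-Carlo recovery
  uses 100 seeded studies of the 18-sample design; variance recovery uses
  200 simulations at n = 60. These sizes keep every stochastic bound at
  least ~3 Monte-Carlo SEs wide.

## Limitations

The estimators are reimplementations from their published definitions, not
wrappers of the original tools, and digit-level agreement with legacy
software (particularly spreadsheet-era BestKeeper and the original NormFinder
add-in) is not guaranteed where those tools' conventions were undocumented;
the binding contracts here are the definitional brute-force oracles and
parameter recovery on simulated ground truth. The CV and BestKeeper methods
operate on raw Ct and therefore conflate expression level with stability for
very high- or low-expressed genes (18S rRNA's large CV despite reasonable
ratio-stability is the canonical example). No multiple-testing correction is
applied to BestKeeper correlation p-values. The pairwise-variation cutoff
0.15 is a convention, not a test statistic.
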