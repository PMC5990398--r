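# sevcargo

Analysis of small-extracellular-vesicle (sEV) miRNA cargo in cellular
senescence: which miRNAs do senescent cells *selectively* package into the
vesicles they secrete, and which do they hold back?

The package is aimed at groups profiling vesicular miRNAs with qPCR panels
(Ct values, spike-in controls, a hard detection limit near Ct 38–40) while
measuring the matching intracellular miRNAs by small-RNA sequencing
(counts/TPM). The experimental design it targets is a donor-blocked
two-condition comparison: fibroblasts from several donors, quiescent
controls (Q) versus stress-induced premature senescence (SIPS), sampled at
two time points (D7, D21), with the complication that senescent cultures
start from roughly 10-fold fewer viable cells while secreting about 4-fold
more vesicles per cell.

## What it computes

**QC and normalization**

* spike-in robustness: ΔCt_r = max − min Ct of each control across samples,
  robust when ΔCt_r < 1 cycle; detection binning of average Ct
  (<31, 31–35, 35–38, >38/ND) and donor-overlap counts
* per-cell normalization of vesicular Ct: Ct′ = Ct + log2(cells/ref), the
  exact Ct-space equivalent of dividing linear abundance by cell input
* global-mean (MCR) normalization: ΔCt_i = Ct_i − mean(Ct of detected
  miRNAs in the sample), isolating per-vesicle composition
* TPM with abundance filtering (≥ 5 TPM in every sample of at least one
  donor)

**Differential analysis** — per-miRNA least squares of
`value ~ donor + day + condition` (or per-day subsets), empirical-Bayes
variance moderation with a method-of-moments prior on log s², moderated t
on d + d₀ degrees of freedom, Benjamini–Hochberg FDR and volcano
classification (|log2FC| > 1, p < 0.05).

**Selective-secretion scoring** (the core method) — after filtering to the
co-measured miRNA set, abundances are averaged per condition and compared
across compartments two independent ways:

* *rank method*: Δrank = rank_intra − rank_extra per condition
  (rank 1 = most abundant), ΔΔrank = Δrank_SIPS − Δrank_Q
* *ratio method*: Ct is mapped to arbitrary units (AU = 10·2^(40−Ct), so
  Ct 40 ↦ 10 AU), Δratio = AU_extra / TPM_intra per condition,
  ΔΔratio = (Δratio_SIPS / Δratio_Q) normalized to its global mean

A miRNA is called **secreted** when it exceeds the 75th percentile of both
ΔΔrank and ΔΔratio, **retained** when it is below both 25th percentiles,
otherwise neutral. Spearman correlation and top-20 overlaps quantify the
concordance of the two methods.

**EV metrics** — NTA size histograms and X50 (median diameter), particles
secreted per cell as fold change versus the (Q, D7) reference, Annexin/PI
apoptosis arithmetic.

**Synthetic data** — `simulate_experiment()` generates Ct matrices with
spike-ins and censoring at Ct 40, negative-binomial count matrices, sample
sheets, NTA tables and planted ground truth (packaging bias, per-vesicle
composition changes, intracellular DE) under the study design above, so the
whole pipeline is testable offline; `truth_report()` scores recovery.

## Worked example

```r
library(sevcargo)

sim <- simulate_experiment(generator_config(seed = 7))

# vesicles per cell: SIPS vs Q
fold <- particles_per_cell_fold(sim$particles, sim$sheet)
mean(fold$fold[fold$condition == "SIPS"])
#> [1] 4.236014

# selective secretion scoring
sec <- secretion_pipeline(sim$ct, sim$counts, sim$sheet)
sec$filter$steps
#> after_intersect  after_quartile  after_zero_tpm        after_nd
#>             375             288             288             288
table(sec$scores$class)
#>  neutral retained secreted
#>      175       59       54
sec$concordance$rho
#> [1] 0.8982564

# recovery of the planted truth
tr <- truth_report(sim$truth, data.frame(mirna = sec$scores$mirna,
                                         class = sec$scores$class))
tr[, c("class", "n_true", "tp", "sensitivity")]
#>      class n_true  tp sensitivity
#> 1 secreted     34  30   0.8823529
#> 2 retained     34  34   1.0000000
#> 3  neutral    307 258   0.8403909
```

The fold change recovers the planted 4× secretion multiplier; the filter
chain reports the miRNAs surviving each cut; the class table shows the
~24% non-neutral fraction that the dual 25/75-percentile rule produces; and
`rho` is the rank/ratio concordance. `run_report()` (or the
`exec/sevcargo report` CLI) runs the same chain on a dataset directory and
writes all tables plus `summary.json`.

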