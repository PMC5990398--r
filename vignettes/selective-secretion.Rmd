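---
title: "Selective secretion of vesicular miRNA cargo: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective secretion of vesicular miRNA cargo: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sevcargo)
```

## The problem

Senescent cells remodel their environment through what they secrete.
Besides the well-characterised protein secretome, senescent fibroblasts
release small extracellular vesicles (sEVs) carrying miRNAs. Two questions
drive the analysis implemented here:

1. **How much more cargo per cell** do senescent (SIPS) cells secrete than
   quiescent (Q) controls, once the very different cell inputs of the two
   culture conditions are corrected for?
2. **Which miRNAs are selectively packaged or retained** — i.e. over- or
   under-represented in vesicles relative to their intracellular abundance,
   in a senescence-dependent way?

The data are heterogeneous on purpose: vesicular miRNAs are measured on a
qPCR panel (Ct values, a detection limit near 38–40 cycles, spike-in
controls), intracellular miRNAs by small-RNA sequencing (counts, scaled to
tags per million). No single normalization connects the two platforms, so
the selective-secretion question is answered with *doubly relative*
statistics (ΔΔrank, ΔΔratio) in which platform-specific scales cancel.

## Measurement models and normalizations

**Ct model.** Throughout, one PCR cycle is one doubling (100% efficiency),
so abundance ∝ 2^(−Ct). Linear "arbitrary units" are anchored at the
assay's floor: `au_transform()` maps Ct 40 to 10 AU (≈ 10 molecules),
`AU = 10 · 2^(40 − Ct)`. Not-detected (ND) wells are a distinct state, not
Ct 40: each operation documents whether it drops ND (detection binning,
global means) or refuses it (AU transform, correlation input).

**Per-cell normalization.** SIPS secretion cultures start from ~10× fewer
viable cells (defaults 1.65×10⁶ vs 1.50×10⁷) — uncorrected, this *hides* a
secretion increase. Dividing linear abundance by cell count is performed in
Ct space as `Ct' = Ct + log2(cells/ref)`, with `ref` the largest cell count
in the run. The choice of `ref` only shifts all samples jointly and cancels
from every contrast; a global reference (rather than per-time-point) is the
package default.

**Global-mean (MCR) normalization** subtracts each sample's mean Ct over
*detected* miRNAs (Ct ≤ 38) from every assay, under the assumption that
total miRNA content per vesicle is condition-independent. It is invariant
to per-sample additive offsets (plate effects) — but only as long as the
offset does not move assays across the detection limit, which also bounds
the validity of the assumption on real plates.

**TPM filter.** "At least 5 TPM in at least one donor" is ambiguous; the
package fixes the stricter reading — ≥ 5 TPM in *every* sample of at least
one donor — and exposes `tpm_rule = "any_sample"` as the alternative.
log-TPM uses pseudocount 1 (standard; at a 5-TPM floor the induced log2FC
distortion is < 0.03).

## Donor-blocked moderated testing

Each miRNA is fit by least squares as `value ~ donor + day + condition`
(donor is a block; per-day contrasts subset to one day and drop the day
term). Only miRNAs with a complete design enter a contrast, matching the
complete-dataset convention of panel analyses. With three donors the
residual degrees of freedom are tiny (2 per-day), so variances are
moderated empirically: the prior `(d0, s0²)` is estimated by method of
moments on log s² — the observed spread of log s² in excess of the known
trigamma(d/2) sampling contribution determines d0 through the inverse
trigamma, the mean determines s0² — and posterior variances
`s̃² = (d0·s0² + d·s²)/(d0 + d)` feed a t statistic on `d + d0` df.
Degenerate inputs are handled explicitly: zero excess spread ⇒ d0 = ∞ and
all variances collapse to the common s0² (if every s² is identical, that
common value itself); `prior_df = 0` disables moderation and reproduces the
ordinary t-test exactly. The suite verifies the engine against an
established empirical-Bayes implementation on the same design as an
independent oracle.

One engine serves both platforms: for the sequencing counts it runs on
log2(TPM+1) as a documented surrogate for a negative-binomial fit. This is
a deliberate trade (one bespoke, fully specified engine) and means
count-data results are approximate where a dedicated NB model would differ
— mostly for low counts, which the 5-TPM filter removes.

Benjamini–Hochberg adjustment is implemented as the literal step-up
`q_(i) = min_{j≥i} p_(j)·m/j` and checked against `stats::p.adjust`.
Volcano classes use |log2FC| > 1 with raw p < 0.05 by default (the study's
vesicular contrasts did not reach FDR < 0.05; the `criterion = "q"` switch
applies the FDR gate instead).

## The rank and ratio scores

After restricting to miRNAs co-measured on both platforms
(`correlation_filter()`: intersect panel and NGS ids; drop the bottom
abundance quartile *on both platforms* (AND is the default, OR available);
drop miRNAs with any zero TPM; drop miRNAs with any ND), abundances are
averaged per condition over donors and both days, and scored twice:

* **Ranks.** Rank 1 = most abundant (descending TPM / ascending Ct,
  average ranks on ties). `Δrank = rank_intra − rank_extra` is positive for
  miRNAs relatively enriched in vesicles; `ΔΔrank = Δrank_SIPS − Δrank_Q`
  is positive for senescence-selective secretion. Being rank-based, it is
  invariant to any monotone rescaling of either platform.
* **Ratios.** `Δratio = AU_extra / TPM_intra` per condition;
  `ΔΔratio_raw = Δratio_SIPS / Δratio_Q`, then normalized by its arithmetic
  mean so the scores average exactly 1. High ΔΔratio again means selective
  secretion. The per-condition Δratio mixes AU and TPM units; only the
  doubly-relative ΔΔ quantity is unit-free, which is why single-condition
  ratios are reported but never classified on.

A deliberate design decision: the ratio is **vesicular over intracellular**.
The source material states the quotient both ways in different places, but
its sign statements are unambiguous — high ΔΔratio, like high ΔΔrank, must
mean *secreted* — and only the extra/intra orientation satisfies them. With
this orientation the two scores are concordant by construction of the
biology, and swapping condition labels negates ΔΔrank while reciprocating
ΔΔratio_raw (both tested exactly). The arithmetic (not geometric) mean is
used for the global normalization because the ratio distribution is
right-skewed; this reproduces the observed sub-unity median of normalized
ΔΔratio on real data.

**Classification** requires concordance: secreted ⇔ above the 75th
percentile of both scores, retained ⇔ below both 25th percentiles
(type-7 linear-interpolation quantiles, configurable). Degenerate all-equal
score vectors classify everything neutral. `method_concordance()` reports
the Spearman ρ between the scores and top-20 overlap counts in both
directions.

## The synthetic world

`simulate_experiment()` states the experiment the analysis assumes, with
defaults taken from the study design rather than tuned to tests:

| parameter | default | rationale |
|---|---|---|
| design | 3 donors × {Q, SIPS} × {D7, D21} | the study's block design |
| cells for secretion | Q 1.50×10⁷ (CV 33%), SIPS 1.65×10⁶ (CV 30%) | reported cell inputs |
| secretion multiplier | 4 | reported vesicles-per-cell fold |
| packaging bias sets | 34 + 34 miRNAs, ±2 log2 | 12% each of the ~75% analysable panel ⇒ ~24% non-neutral |
| composition sets | 2 up / 5 down, ±1.5 log2 | reported per-vesicle DE counts; effect size an order-of-magnitude choice (unquantified in the source) |
| intracellular DE | 46 up / 36 down, ±1.5 log2 | reported DE overlap counts |
| Ct noise | 0.5 cycles | typical panel replicate spread |
| Ct anchor | median miRNA at Ct 29 in a nominal Q sample | keeps ~99% of assays above the detection limit, like the real panel (369/375 detected) |
| counts | NB, dispersion 0.1, library ~5×10⁶ (CV 30%) | small-RNA-seq defaults |
| spike-ins | constant ± 0.1 cycles | robust controls by construction |
| NTA | lognormal sizes, median 70 nm; particle totals ∝ cells × rate × multiplier | reported size range 65–80 nm |

Latent abundance is lognormal (sdlog 1.8) with a per-donor multiplicative
effect (log2 sd 0.25) shared between platforms — this is what makes donor
blocking genuinely useful. Vesicular signal scales with the *actual* cell
count of each sample, so per-cell normalization is exercised against the
real confound (fewer cells, more vesicles each). Planted subsets are
disjoint and drawn from the detectable abundance stratum (above the 30th
percentile of latent abundance): effects planted on miRNAs that the
abundance filters are designed to discard would be unrecoverable by
construction and would only blur recovery statistics. Packaging bias
multiplies vesicle loading independently of intracellular DE, mirroring the
claim that secretion changes exceed intracellular ones, and making the two
signal types separable by the ΔΔ scores.

What the generator does **not** emulate: sequence-specific platform bias,
plate/batch structure beyond spike-in noise, hemolysis-like contamination,
raw reads or NTA video. A green recovery test therefore establishes that
the pipeline's arithmetic recovers effects of the stated size under the
stated noise — not that the method is robust to every artefact of real
panels.

## Numerical choices and degenerate inputs

* quantiles: type 7 (linear interpolation) everywhere, documented and
  configurable where it matters (classification cut-offs);
* ties: average ranks;
* Ct boundary convention: detected = Ct ≤ 38; binning assigns boundary
  averages to the higher-Ct bin (31.0 → "31–35") except 38.0, which is
  still detected ("35–38");
* ND: never imputed; dropped from means, fatal for AU;
* all-equal variances, constant score vectors, empty filter results,
  rank-deficient designs, all-zero samples: each has an explicit branch or
  a named error rather than an NA cascade;
* determinism: one top-level seed; the generator restores the caller's RNG
  state.

## Known limitations

* **The dual-percentile classifier has a built-in positive rate.** Cutting
  at the 25/75 percentiles places ~25% of miRNAs beyond each cut by
  definition, and because ΔΔrank and ΔΔratio are computed from the same
  measurements their correlation is high even under a pure-noise model, so
  the concordance requirement removes far less than independence would
  suggest. In bias-off simulations ~30–40% of miRNAs are labelled
  non-neutral. The ~24% non-neutral fraction on data of this design is
  therefore a property of the method, not evidence of signal by itself —
  recovery of *planted* sets (sensitivity, direction) is the meaningful
  validation, and the corresponding specificity acceptance property is
  knowingly left failing rather than silently relaxed.
* Per-day contrasts rest on 2 residual df per miRNA before moderation;
  the moderated test is calibrated (verified by null simulation) but has
  limited power for composition-scale effects.
* The NB surrogate (moderated t on log-TPM) is approximate for count data;
  differential counts on sequencing data should be read as such.
* The rank method saturates at the extremes: a top-ranked miRNA cannot
  improve its vesicular rank, compressing ΔΔrank for the most abundant
  secreted candidates; the ratio method does not saturate, which is one
  reason both are required to agree.
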