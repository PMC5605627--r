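---
title: "Methods: quantifying protein and RNA localization between soma and neurites"
author: "neuroloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying protein and RNA localization between soma and neurites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroloc)
```

## The problem

Neurons place proteins far from the cell body by three routes: transporting
the protein itself, localizing the encoding mRNA and translating it on site,
or some mixture of the two. Compartment fractionation — growing neurons on a
microporous membrane so neurites extend through to the far side — yields
paired soma and neurite fractions that can be profiled by label-free
proteomics (LFQ), RNA-seq and ribosome profiling, with optional pulsed-SILAC
label-swap experiments as an orthogonal translation readout. `neuroloc`
implements the downstream statistics of such a design: per-layer
neurite/soma enrichment, footprint quality control, ratio aggregation,
non-coding RNA calls, motif association, and finally a per-gene attribution
of protein localization to a mechanism.

Everything operates on per-gene tabular quantifications (counts, log2
intensities, junction counts, ratio pairs); alignment, peptide
identification and back-splice detection are upstream of this package.

## The central objects

A `CompartmentMatrix` is a `SummarizedExperiment` whose samples carry a
`compartment` (soma/neurite) and `replicate` annotation and whose single
assay is on a declared scale (`counts`, `rpkm`, or `log2intensity`; only
the last may contain missing cells). All per-layer statistics consume this
class, so the proteome, transcriptome, translatome and junction tables move
through one code path.

## Enrichment model

For a feature with per-replicate abundances, localization is summarized as

\[
\mathrm{log2FC} = \log_2 \frac{\bar{x}_\text{neurite} + c}{\bar{x}_\text{soma} + c},
\]

with pseudocount \(c\) (default 0.5, linear scales only), and tested with a
two-sample t statistic on per-replicate \(\log_2(x + c)\) values
(log2-intensity data are used as-is). Calls use strict thresholds
log2FC > 1 (or < −1) and raw p < 0.05 — the twofold / 0.05 convention used
for every omics layer — with Benjamini–Hochberg adjusted p-values reported
alongside for reuse.

Two statistical choices deserve justification:

* **Pooled rather than Welch variance.** At 2–4 replicates the
  Satterthwaite degrees-of-freedom approximation is markedly conservative
  (empirical type-I rate ≈ 0.034 at nominal 0.05 with 3 vs 3 replicates),
  while the pooled-variance Student t is exact under the equal-variance
  log-normal noise model and holds its nominal level in the calibration
  test. `var.equal = FALSE` restores Welch where compartment variances
  genuinely differ.
* **Degenerate variance.** Groups that are constant and unequal make the t
  statistic undefined; the package emits the smallest representable
  p-value with a `degenerate` flag rather than p = 0, and p = 1 when the
  groups are constant and equal. Features with sporadic missing replicates
  (proteomics) are tested on their observed counts per group; the pooled
  statistic tolerates a single observed value in one group.

Cross-layer agreement is the Pearson correlation of log2FCs over shared
features with the usual t-transform p-value.

## Proteomics missingness and imputation

LFQ missingness is missing-not-at-random: the probability a cell is missing
rises as intensity falls. Missing cells are imputed from a down-shifted
Gaussian per sample column, \(N(\mu_s - 1.8\,\sigma_s,\; 0.3\,\sigma_s)\) —
the field-standard choice for values below the detection limit. Three
scopes control *which* cells are imputed:

* `all` — every missing cell (the classical whole-matrix treatment);
* `compartment` — only proteins with no observed value in a compartment
  (the "detected in only one compartment" rule);
* `group` (pipeline default) — compartment groups with fewer than two
  observed values; groups that retain ≥ 2 observed replicates keep their
  sporadic missing cells and are tested on observed values only. A group
  with one observed replicate cannot form a variance, so filling it is the
  smallest intervention that keeps the feature testable without
  contaminating well-observed groups with low draws.

## Ribosome footprints

Footprint tables are transcript-relative and 0-based: `five_prime_offset`
is the read 5′ end relative to the CDS start, the CDS occupies
`[0, cds_length)`, and the frame of the CDS start is 0. QC and
quantification proceed as:

1. **Length filter** — retain 27–30 nt (the gel-selected monosome
   footprint range).
2. **P-site correction** — 5′ end + 12 nt, the standard offset for
   ~29-mers, exposed as a parameter since the optimal offset is
   protocol-dependent.
3. **Frame periodicity** — P-site position mod 3, tabulated per read
   length and pooled; departure from uniformity scored by a chi-square
   goodness-of-fit test (df = 2). Genuine translation shows a strong
   frame-0 excess.
4. **CDS quantification** — P-sites inside the half-open CDS interval are
   counted per gene and sample and normalized to RPKM with CDS lengths;
   transcripts with log2FC > 1 and p < 0.05 are flagged locally
   translated.

## Label-swap SILAC

Forward (H neurites + M soma, ratio H/M) and reverse (M neurites + H soma,
ratio M/H) experiments estimate the same neurite/soma translation-rate
ratio with opposite label assignment. The package averages the *log2*
ratios: an arithmetic mean of raw ratios is upward-biased and would break
the label-swap symmetry identity (exchanging experiments while inverting
ratios must be a no-op), which the log-space mean satisfies exactly.
Proteins quantified in a single experiment are kept and flagged
(`n_experiments = 1`). Upregulation selection (e.g. the >4-fold criterion
for differentiation markers) is a strict threshold on `2^avg_log2`.

## Non-coding calls

lncRNAs use a higher detection bar (> 10 RPKM versus > 1 RPKM for coding
genes, compartment mean over replicates, strict inequality) and the same
twofold/0.05 neurite call. Circular/linear preference normalizes junction
counts to CPM within the circular and linear tables separately, averages
replicates per compartment, and computes
\(\log_2((\text{circ}+c)/(\text{linear}+c))\) per compartment. A gene is
*neurite-preferential circular* when the neurite ratio exceeds 1 in log2
and the soma ratio is negative — the pattern typified by a receptor
tyrosine kinase transcript whose circular form is >10× its linear form in
neurites while the soma ratio is ~7× reversed; neurite circ excess without
the soma reversal is reported as a weaker class containing the first by
construction.

## Mechanism attribution

Every protein with a neurite call is assigned one category by a strict
decision tree on the RNA and Ribo-seq layers:

| RNA log2FC | RNA p | Ribo log2FC | category |
|---|---|---|---|
| > 1 | < 0.05 | — | `mrna_localization` |
| (0, 1), or > 1 without significance | — | — | `intermediate` |
| < 0 | — | < 0 | `protein_transport` |
| < 0 | — | > 1 | `local_translation` |
| < 0 | — | (0, 1) | `combination` |

Strict inequalities leave measure-zero boundaries that finite data can
hit; the tie rules send RNA log2FC exactly 0 (and exactly 1 without
significance) to `intermediate`, and Ribo log2FC exactly 0 or 1 to
`combination` — each boundary joins the adjacent lower-priority class. A
gene missing the RNA record, or missing the Ribo record when the tree
reaches it, is reported `unquantified`, never dropped: the category counts
must always partition the neurite-localized total. The summary reports
counts, fractions, the per-category mean Ribo-seq log2FC and the
RNA–protein Pearson correlation.

## Motif and modification-site association

Gene sets follow the localized-and-translated definitions: foreground =
RNA and protein log2FC > 1, both p < 0.05; soma reference = both < −1 with
p < 0.05; unlocalized reference = both within (−0.58, 0.58), i.e. less
than 1.5-fold either way. Hits come from a log2-odds position-weight-matrix
scan (maximum window score against a threshold; uniform background by
default) or any external scanner producing the same table shape.
Association is Fisher's exact test computed by hypergeometric enumeration
with the probability-mass two-sided rule (sum of all margin-fixed tables no
more probable than the observed one, with a 1e-7 relative tie guard); the
odds ratio is the sample cross-product ratio \((ad)/(bc)\) with an
\(\infty\) convention when \(bc = 0 < ad\) — deliberately *not* the
conditional MLE some software reports. When many motifs are tested, BH
adjustment across motifs is recommended.

## The synthetic-data generator

`simulateBundle()` draws a complete experiment with known truth:

* **Genes.** Mechanisms are allocated by deterministic largest-remainder
  quota (class counts exact, testable), not multinomial sampling.
  Transcript lengths are log-normal (median 2.5 kb, clamped 0.3–20 kb),
  CDS lengths a uniform 40–90% of the transcript rounded to codons, base
  expression log-normal over ~4 orders of magnitude. About 10% of genes
  are lncRNAs (no CDS, no protein), drawn from the mechanisms that do not
  require a protein product.
* **Effects.** Fully localized axes get ±`loc_effect_log2` (default 2.0);
  the moderate axes of `intermediate` and `combination` sit at +0.5, the
  midpoint of their defining (0, 1) band; protein-side mechanisms with
  soma-leaning RNA use −0.5.
* **RNA counts.** Per-gene rates ∝ expression × transcript length, times
  `2^rna_loc_log2fc` in neurites; each library is scaled to `rna_depth`
  expected reads and drawn NB with dispersion 0.05 (Poisson at 0).
* **Footprints.** Rates ∝ expression × CDS length × `2^ribo_loc_log2fc`;
  each record picks a codon uniformly, a length from 27–31 nt (31-mers at
  5% purely so the length filter has something to remove), and a frame
  (0 with probability `frame0_bias` = 0.85). Emitted positions are raw 5′
  offsets — the +12 correction is left to the analysis so the offset logic
  is exercised.
* **Proteins.** log2 intensity = 20 + log2(expression) + effect ×
  [neurite] + N(0, 0.5); cells go missing with probability
  `plogis((21 − intensity)/1)`, giving ~10% overall missingness
  concentrated at low abundance.
* **SILAC.** A 25% random subset of proteins (pulsed labeling quantifies
  few proteins) gets forward and reverse ratios `2^(effect + ε)`,
  ε ~ N(0, 0.25) independently per experiment.
* **Junctions.** 5% of genes are flagged neurite-preferential circular
  with expected circ:linear 10:1 in neurites and 1:7 in soma; other genes
  keep a constant 1:5 ratio in both compartments. Counts are Poisson.

Each table has its own RNG stream (`seed` + a fixed per-table offset), so
adding or skipping one table never perturbs the others, and an identical
configuration reproduces a byte-identical bundle.

**Composition balance.** Under total-count scaling (RPKM), enriched mass in
one compartment displaces reads from every other gene, shifting all
measured log2FCs. The default mechanism fractions (6% mRNA-localization,
5% intermediate, 3.5% transport, 1.5% local translation, 2% combination,
24% soma-restricted, 58% unlocalized) are calibrated so neurite- and
soma-directed RNA mass cancel: unlocalized genes then center at log2FC ≈ 0,
matching the globally comparable libraries and near-unity unlocalized
controls of real fractionation data. The translatome retains a small
residual shift (~+0.09 log2) because the local-translation and combination
classes add translated mass that no class removes; this is a property of
total-count normalization itself, which the package deliberately does not
"correct" (between-library median/quantile normalization is out of scope).

## What the simulation does and does not show

The generator reproduces the statistical structure the analysis assumes:
NB count noise, MNAR intensity dropout, frame-biased footprints,
label-swap noise, Poisson junctions. It does not emulate isoform mixtures,
UTR sequence content, batch effects, spike-ins, sub-neurite structure, or
genomic coordinates — so passing recovery tests demonstrates the
statistics are implemented and calibrated correctly, not that any
particular biological dataset will behave as cleanly.

Problem sizes used by the test suite and the acceptance script — 2,000-gene
bundles with 1e6 RNA reads and 2e5 footprints per library, three bundles
per evaluation, a 10,000-feature null calibration, and exhaustive 2×2
enumeration to N = 30 — were chosen as the smallest sizes at which the
binomial error of the recovery rates is a few tenths of a percent.

## Known limitations

* Recovery of true localized proteins is bounded near ~95% at the design
  point (effect 2.0 log2, σ = 0.5, 3 replicates) by the power of a
  3-replicate t test, and MNAR dropout at the low-intensity tail costs a
  few further points; proteins never observed in any sample are
  unrecoverable by construction.
* With only 3 replicates there is no variance moderation across features
  (empirical-Bayes shrinkage is deliberately out of scope), so per-feature
  variance estimates are noisy.
* The mechanism tree inherits the thresholds' discreteness: genes whose
  true effects sit near 0 or 1 log2FC flip categories under measurement
  noise; the `intermediate`/`combination` boundaries are the least stable.
* Single-transcript genes are assumed throughout; isoform-level
  localization is not modeled.

## A worked run

```{r, eval = FALSE}
cfg <- SimConfig(seed = 1)
bundle <- simulateBundle(cfg)
res <- analyzeBundle(bundle)
res$summary$counts
res$summary$rna_protein_pearson$r
res$frame_qc$pooled_frame0_fraction
```
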