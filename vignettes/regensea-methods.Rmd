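---
title: "Methods: enrichment analysis and conserved regulator gene sets"
author: "regensea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enrichment analysis and conserved regulator gene sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regensea)
```

## The problem this package addresses

A classic route to candidate regulators of an induced cell state — here,
proliferation of a normally quiescent sensory epithelium after a
pharmacological stimulus — is to compare expression between treated and
control samples and then ask which *regulator-defined gene sets* shift
coordinately: sets of genes sharing a conserved transcription-factor
motif in their promoters (if the factor is active, its targets move
together) and sets sharing a 3'-UTR microRNA seed match (if the miRNA is
induced, its targets are coordinately repressed, so they enrich on the
control side of the ranking). `regensea` implements that full chain —
expression filtering, probe collapse, differential expression, a gene
set enrichment engine, construction of the motif-derived gene sets, and
the downstream qPCR/count validation arithmetic — together with seeded
generators that produce every input with known planted truth.

## Differential expression

The pipeline ingests an already-normalised, linear-scale intensity
matrix (GCT) with a two-class phenotype (CLS).

* **Filtering.** `filter_by_expression()` keeps a row if, in at least
  `min_samples` samples, its value reaches that sample's 20th
  percentile. The percentile is the order-statistic (inverse-ECDF)
  quantile, so on a sample holding values 1..100 the 20th percentile is
  exactly 20. Two published phrasings of this filter exist — a
  percentile band and a fraction-of-maximum rule — and they are not the
  same operation; the percentile semantics is the default and the
  fraction-of-max rule is available via `method = "fraction_of_max"`.
* **Probe collapse.** Redundant probes for one gene symbol are collapsed
  per sample by their median (`collapse_probes_to_genes()`); an even
  probe count takes the mean of the central pair. The probe-to-gene map
  is an explicit two-column input, never guessed from probe names.
  Upper-cased gene symbols are the join key everywhere.
* **Testing.** `differential_expression()` runs a per-row unpaired
  t-test on the linear intensities — Welch by default, matching
  expression-analysis convention; pooled Student available — followed by
  Benjamini–Hochberg adjustment (`bh_adjust()`, a validated wrapper over
  `stats::p.adjust`). Selection uses an inclusive fold-change cutoff
  (>= 2 or <= 1/2) and a strict adjusted-p cutoff (< 0.05). Zero
  variance in both classes is reported as p = 1 for equal means and
  p = 0 otherwise.

Testing on the linear scale mirrors the published pipeline, but t-tests
on skewed linear intensities are mildly conservative at n = 6 per class
(we measure a null rejection rate of ~0.035–0.045 at alpha = 0.05). The
`log2_transform` option exists for synthetic calibration studies, where
the generator's noise is Gaussian in log2 and the nominal level is then
exact; the package's own type-I calibration test uses it for that
reason.

## The enrichment engine

`run_gsea()` orchestrates four stages.

1. **Ranking.** Genes are ordered by the signal-to-noise ratio
   `s(g) = (mu_pos - mu_neg) / (sd_pos + sd_neg)`, with each class's
   sample standard deviation floored at `max(0.2 |mu|, 0.2)` so
   zero-variance genes cannot dominate; this floor follows the reference
   GSEA implementation. Rank ties break lexicographically by symbol, so
   rankings are identical across platforms.
2. **Set restriction.** Each set is intersected with the ranked
   universe; sets ending outside [15, 500] members are dropped (both
   bounds configurable).
3. **Scoring.** The classic (unweighted) running sum adds `1/Nh` at a
   member and subtracts `1/(N-Nh)` elsewhere; the enrichment score (ES)
   is the signed value at the maximum absolute deviation from zero, so a
   set clustered at the bottom of the ranking gets a negative ES. The
   sum always terminates at zero. If the maximum deviation is attained
   with equal magnitude on both sides — possible only on small lists
   with rational increments — the earlier extremum wins; this tie is the
   one point where the ES sign convention is arbitrary, and the
   antisymmetry properties below hold away from it.
4. **Significance.** The null reassigns phenotype labels (class sizes
   preserved), recomputes the ranking and all scores per permutation
   (1,000 by default; exhaustive enumeration of all `choose(n, n_pos)`
   labelings for small designs), and yields: `NES = ES / mean(|null ES|
   of the same sign)`; nominal p as the same-sign null tail fraction;
   and the FDR q from the pooled same-sign null NES — `q = (fraction of
   pooled null NES at least as extreme) / (fraction of observed NES at
   least as extreme)`, clipped to [0, 1], with a suffix-minimum cleanup
   per sign side so q never decreases as |NES| shrinks. Sets lacking
   any same-sign null sample receive the boundary estimate
   `p = 1/(n_null + 1)` and are flagged. A set is called significant at
   p < 0.05 *and* q < 0.25, both strict; `enriched_class` names the
   treated class for ES > 0, the control class otherwise, and is
   invariant to swapping the orientation of the contrast.

The identity labeling is retained in the random null (standard
practice), and random sampling draws labelings with replacement;
exhaustive mode enumerates each labeling once.

### What the q < 0.25 rule does and does not promise

On fully null data with homogeneous, independently drawn sets, the
joint rule "p < 0.05 and q < 0.25" behaves per sign side like
Benjamini–Hochberg at level 0.25: the chance that *some* set is flagged
in a given run is roughly the level itself. In our negative-control
simulations (two same-distribution groups, 60 null sets) about half of
runs flag at least one set, and raising the permutation count does not
change this — it is what a 25% false-discovery tolerance means, not a
defect. Real collections behave more quietly because heterogeneous,
internally correlated sets make the pooled-null FDR estimate
conservative; a single clean control-vs-control run on real data is
therefore unsurprising but is not a guarantee the procedure can
reproduce on independent synthetic nulls. The package reports the
negative-control clean-run fraction honestly rather than tuning the
estimator to suppress it.

## Conserved motif gene sets

`build_tf_genesets()` rebuilds regulator target sets from primary
inputs: TRANSFAC-format count matrices, a TSS table, and pairwise
(reference/other species) promoter alignments in MAF dialect.

* **Scoring.** Frequencies are information-weighted as in the MATCH
  algorithm: `I(i) = sum_B f(i,B) ln(4 f(i,B))`; a window scores
  `Current = sum_i I(i) f(i, b_i)`, min-max normalised to the matrix
  similarity score (mss); the core similarity score (css) applies the
  same formula over the 5 consecutive positions maximising the
  information sum (leftmost on ties — core provenance is a database
  annotation we do not have, so a fixed convention replaces it). Windows
  containing non-ACGT characters are skipped, never smoothed.
* **Cutoffs.** The published per-matrix cutoffs ("minimise false
  positives plus false negatives") live in proprietary profile files
  that cannot be redistributed, so cutoffs are inputs: global defaults
  (core 0.75, matrix 0.85) with a per-matrix override table.
* **Windows.** The scanned region is the 2 kb promoter window
  `[tss - 1000, tss + 1000)`, 0-based half-open, extracted from the
  alignment blocks covering it; minus-strand genes are
  reverse-complemented so scanning is promoter-sense. Hits must lie
  fully inside the window. Uncovered genes are listed in a coverage log,
  and reverse-strand reference blocks are rejected outright rather than
  silently flipped.
* **Conservation.** A reference hit is conserved only if no gap column
  intersects its aligned span in either row and the other species' bases
  at exactly those columns, in the same orientation, also clear both
  cutoffs — no positional slop, and the same cutoffs apply to both
  species (the paper does not say otherwise; one convention is chosen
  and stated). Conserved hits are by construction a subset of reference
  hits. Sets are emitted as `V$<matrix_id>` in GMT; empty sets are
  omitted.

`build_mirna_seed_genesets()` forms a set per seed motif (7-mers, e.g.
`TGAATGT` for the miR-181 family) by exact forward-strand substring
search over 3'-UTR sequences — the convention of motif-derived target
collections, deliberately not a thermodynamic pairing model.

## Validation statistics

* `ddct_fold_change()` implements relative quantification: technical
  replicates averaged per sample, `dCt = Ct_target - Ct_ref` (18S by
  default), `ddCt` the treated-minus-control difference of group means,
  fold `2^-ddCt`. The paper does not state how its 95% interval was
  formed; we use the two-sample t-interval on ddCt (pooled Student by
  default, matching the stated statistics; Welch available),
  exponentiated — a monotone transform, so the "CI excludes 1"
  significance rule is unaffected by the back-transformation. Folds
  below 1 display as `1/x`.
* `ttest_from_summary()` reconstructs an unpaired Student t-test from
  printed mean/SEM/n triples (`sd = sem sqrt(n)`), and
  `ttest_from_counts()` routes raw counts through the same arithmetic,
  so the two paths agree exactly. The published proliferation
  comparisons recompute from their printed summaries to p = 0.008 and
  p = 0.005 (pooled, rounded to the printed precision). One published
  contrast (control vs miR181a, printed p = 0.001) is not recovered
  from its printed summaries by either pooled (~0.004) or Welch (~0.003)
  arithmetic; we record the discrepancy rather than force a convention
  to match it.

## The synthetic-data generators

Every generator is a pure function of its parameters and a seed, and
writes a machine-readable truth manifest; recovery tests read planted
truth only from the manifest.

* **Expression.** Per gene a log2 baseline ~ Normal(8, 2), per sample
  log2 noise ~ Normal(0, 0.5), matrix emitted linear (`2^x`) on a 6v6
  design — the scale and design of the study the pipeline targets.
  Planted regulator sets (10 up, 10 down, 30 members each) draw their
  members from a shared 40-gene pool per direction, all shifted by a
  coordinated 1 log2-unit class effect. The shared pool mirrors real
  motif collections, where same-family sets are near-duplicates, and
  keeps the differential fraction of the transcriptome realistic (~8%);
  fully disjoint planted sets would force 60% of genes differential,
  which distorts the mid-list null geometry and is not a regime any
  enrichment method is meant for. 180 size-matched null sets draw from
  the remaining genes. Coordinated (not random-sign) shifts are used
  because the enrichment logic under test is directional. Optional
  redundant probes (shared gene value plus probe noise) exercise the
  median collapse.
* **Promoters.** Per gene one alignment block: i.i.d. uniform reference
  row, independently drawn other row (so chance cross-species
  conservation is negligible), ~5% gap columns that never alter the
  reference coordinate system (deletions blank the other row; insertions
  add reference-gap columns). Planted genes carry the matrix consensus
  at an aligned, gap-free position in both rows; decoys carry it in the
  reference only — the partner site is mutated at its most informative
  positions until it drops below cutoff, or a gap column is inserted
  inside the site — so the conservation filter must reject them. A
  fraction of genes sits on the minus strand to exercise promoter-sense
  extraction.
* **UTRs.** Planted members contain each seed motif at least once;
  non-members are rejection-sampled to contain none, with a bounded
  attempt count so a motif guaranteed to occur by chance raises an
  error instead of looping.
* **qPCR.** Reference Ct ~ Normal(10, 0.1) per sample, a fixed control
  dCt, the treated dCt shifted by `-log2(true fold)`, and triplicate
  technical noise (0.2 cycles by default). With zero replicate noise
  the estimator recovers the true fold exactly, because the per-sample
  reference level cancels in dCt.
* **Counts.** Poisson per-explant counts at the group means (negative
  binomial behind a dispersion option), sized for the BrdU comparisons.

What these generators deliberately do not emulate: probe-level
hybridisation artifacts, gene–gene correlation, batch structure, and
heavy-tailed noise. Passing the planted-recovery and calibration tests
therefore demonstrates the correctness and calibration of the
*machinery* under its stated model, not robustness to every property of
real microarray data.

## Problem sizes and numerical conventions

The package's tests run the enrichment engine at the study design
(1,000 genes, 6v6, 200 sets) with 200 permutations and 5 seeds for the
recovery/calibration checks, 100–1,000 permutations for the negative
control, exhaustive enumeration for 3v3 oracle checks, and reduced
scales elsewhere; these sizes were chosen so the full suite is a
coffee-break run on a laptop while leaving Monte-Carlo margins wide.
Determinism rules: all randomness flows through explicit seeds;
rankings break ties lexicographically; running-sum extremum ties take
the earlier point; coordinates are 0-based half-open; gene symbols are
upper-cased at every ingestion point; parse errors always carry file
and line.

## Known limitations

* Weighted (p = 1) enrichment scoring, gene-tag permutation, and
  leading-edge analysis are out of scope; the engine implements the
  classic statistic with phenotype permutation only.
* Designs other than two classes with >= 2 samples each are rejected.
* Multi-species (> 2) alignments are not supported; the conservation
  filter is strictly pairwise.
* The FDR q is the standard plug-in estimate; under a global null it
  flags something in a substantial fraction of runs at q < 0.25 (see
  above), so downstream users should treat isolated hits near the
  threshold accordingly.
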