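---
title: "Methods: integrative epigenetic and miRNA characterization of drought-responsive genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative epigenetic and miRNA characterization of drought-responsive genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis

Drought stress-responsive genes (DRGs) of rice have been catalogued by
several expression studies, but how many of them sit under epigenetic or
small-RNA control is a separate question. The analysis this package
implements answers it by integration: DNA methylation read intervals
(from methylcytosine immunoprecipitation sequencing) are overlaid on the
DRGs' genic spans and promoter windows, miRNA-target predictions and
chromatin-gene (ChromDB-style) annotations are attached, and each DRG is
then placed in a rule-based cluster tree:

* **D** — all DRGs; **DU** / **DD** — up- / down-regulated;
* **E** — DRGs with at least one of: genic methylation read, promoter
  methylation read, miRNA target, chromatin-gene membership; **NE** —
  DRGs with none;
* **EU**, **ED**, **NEU**, **NED** — the four mutually exclusive leaves
  crossing E/NE with direction.

The clusters are definitional, not data-driven: no fitting is involved,
and `validate_partition()` checks the implied algebra (DU + DD = D,
E + NE = D, EU + ED = E, NEU + NED = NE, leaves disjoint) on every
classification. Clusters are then characterized by enrichment statistics
and descriptive analytics.

## Feature mapping

The genic region is the full span from the transcriptional start site
(TSS) to the gene end; no exon structure is used. A read is assigned to a
gene when the two intervals share at least `min_overlap = 50` bases
(1-based, inclusive on both ends); a read overlapping two genes counts
for both. The promoter is the 1 kb window immediately upstream of the
TSS: `[start - 1000, start - 1]` for a `+` gene, `[end + 1, end + 1000]`
for a `-` gene. The 50-base rule is stated only for genic reads in the
source analysis, so promoter assignment defaults to *any* overlap
(`min_overlap = 1`), configurable back to 50. Promoter windows are
strand-aware; because "upstream of the TSS" is a strand-defined notion,
we treat this as the correct reading, but `ignore_strand = TRUE`
reproduces a strand-naive variant. Two sub-window counts are carried per
gene with the same thresholds as their parent regions: reads within the
first 1000 genic bases from the TSS, and promoter reads within 200 bases
of the TSS.

Interval overlap is computed with `GenomicRanges::findOverlaps()`, whose
`minoverlap` argument counts shared positions exactly as defined above;
the test suite verifies every random instance against an all-pairs
oracle.

## Enrichment statistics

**Monte Carlo z-score.** The source analysis reports feature enrichment
of the DRG set "compared to a random set of 5000 genes" without stating
the exact computation. We implement the natural Monte Carlo reading: the
background pool is every non-TE, non-pseudogene gene model (DRGs are
retained in the pool — removing them would bias the background); B
size-matched gene lists are drawn without replacement (B = 1000 by
default, seeded); and

\[ z = \frac{\mathrm{observed} - \overline{X}_B}{s_B}, \]

with the B−1 denominator in \(s_B\) and a two-sided normal p-value. A
closed-form binomial z (prevalence \(p_0\) in the pool,
\(z = (k - np_0)/\sqrt{np_0(1-p_0)}\)) is computed alongside as a
cross-check; the two agree as B grows, which the tests assert at
B = 10^4. When every draw returns the same count (feature prevalence 0
or 1) the result is flagged degenerate rather than given an infinite z.

**Term enrichment.** GO-style term enrichment per cluster uses the
one-sided Fisher exact (hypergeometric upper-tail) test against the
eligible-pool background, Benjamini–Yekutieli FDR correction (valid
under arbitrary dependence; `stats::p.adjust(method = "BY")` behind
`by_adjust()`), and a minimum of five mapped entries per term. The
filter is applied to the query-set count *before* testing, so the
multiple-testing universe is the set of surviving terms of that one
query; there is no cross-cluster pooling and no propagation of
annotations to ancestor terms. The hypergeometric tail is verified
against exhaustive enumeration for every table with N ≤ 60.

**G statistic.** Contingency enrichment (e.g. Pfam-bearing share in E vs
NE) uses the likelihood-ratio statistic \(G = 2\sum O \ln(O/E)\) with
1 df and no correction by default; the Williams correction is available
as a flag. Recomputing G from the published count tables reproduces the
printed values to about 1–2%, which is as close as those tables allow.

## The synthetic-data generator

`simulate_dataset()` emits every input the pipeline consumes, with
planted effects and recorded ground truth. Its defaults are the study
conditions: 55986 gene models on 12 chromosomes (29% TE, 2% pseudogene),
5468 DRGs with 43.7% upregulated, and a 5000-gene background list.

* **Gene placement.** Sequential per chromosome with exponential
  inter-gene gaps (mean 3000 bases) plus a 2000-base floor; lengths are
  lognormal around 3000 bases (clamped at 150). The gap floor of twice
  the promoter length keeps every promoter window inside its own
  intergenic space, so planted genic and promoter reads cannot
  cross-contaminate neighbouring genes and realized enrichments track
  the planted factors. Multi-gene read assignment is still exercised by
  dedicated mapping fixtures.
* **Feature planting.** Per-gene Bernoulli on "carries ≥ 1 instance"
  with non-DRG base rate \(p_0\) and DRG rate \(\min(1, \rho p_0)\);
  instance counts are conditionally geometric, so multiplicity
  histograms are non-trivial. The base rates and enrichment factors are
  calibration choices (the source reports prevalences, not effect
  sizes): \(p_0\)/ρ of 0.20/2 (genic), 0.06/2 (promoter), 0.12/2.7
  (miRNA), 0.009/1.8 (chromatin) reproduce the reported DRG prevalences
  of ≈40%, 12%, 32% and 1.6%.
* **Fold changes.** Lognormal per direction with planted means 15 (up)
  and 3 (down), matching the reported ordering of cluster-average
  absolute fold changes (up-clusters well above down-clusters).
* **Annotation tables.** TF families, Pfam families and pathways are
  assigned with rank-weighted (Zipf-like) family choice; a handful of GO
  terms are spiked into the feature-positive upregulated genes (the
  EU-like set) at rate 0.3 vs 0.02 elsewhere, giving the term-enrichment
  stage a known positive. PPI edges are denser among down-regulated DRGs
  (2 expected edges per gene) than up-regulated ones (0.7), mirroring
  the reported degree asymmetry; scores are uniform on \[0, 1\].
* **Determinism.** One global seed expands into fixed per-table
  substreams, so adding a table to the generator never perturbs earlier
  tables, and identical seeds give byte-identical bundles.

What the generator does *not* emulate: sequence content (no FASTA/FASTQ),
spatial autocorrelation of chromatin state, correlated annotation
structure between feature types, and GO-graph hierarchy. Passing tests
on synthetic bundles therefore demonstrate correctness of the
computations and recoverability of planted effects, not biological
validity of any particular threshold on real data.

## Validation strategy and problem sizes

The suite validates at four levels, with sizes chosen to keep the whole
run inside a few minutes on one core:

1. **Oracle equivalence** — interval mapping vs an all-pairs oracle on
   200 random instances; Fisher p vs exhaustive enumeration on all
   N ≤ 60 grids; G and BY vs independently coded oracles.
2. **Null calibration** — 400 seeded bundles at ρ = 1 (2000 genes, 400
   DRGs, B = 200): the |z| > 1.96 rejection rate must lie in the exact
   binomial 99% interval around 0.05. The Monte Carlo z is slightly
   t-like at B = 200, so the empirical rate sits a little above 0.05,
   well inside the interval.
3. **Power and recovery** — at ρ = 4 the planted genic enrichment is
   detected (z > 1.96) in ≥ 95% of 20 seeds; the realized DRG/non-DRG
   prevalence ratio recovers ρ ∈ {1, 2, 4} within 15% on average.
4. **Structural invariants** — partition algebra, zero feature counts in
   NE-derived clusters, four-set overlap regions summing to the union,
   strand-flip invariance of mapping, and byte-identical outputs across
   reruns with one seed.

## Numerical and design choices

* Internal coordinates are 1-based inclusive everywhere (GFF3
  convention); only the BED reader/writer converts, and the conversion
  is self-inverse.
* Readers are strict: a malformed row is a fatal error naming its line,
  with an explicit `skip_bad_rows` opt-out that logs counts. TE and
  pseudogene status must be declared by the annotation (attribute or
  column), never inferred from identifiers.
* PPI edges are undirected simple graphs: endpoints ordered, self loops
  dropped, duplicate edges collapsed to their maximum score. Degrees
  count within-cluster edges only. Combined scores are confidence-like
  in most PPI exports but the source text reads them as p-value-like, so
  the filter direction (`ge` vs `le`) is a required, explicit choice
  rather than a default.
* Genes reported with conflicting directions by different source studies
  stay in D (and E/NE) but receive no direction or leaf label; the
  partition checks account for this. Multiple fold changes per gene
  reduce to the maximum absolute value by default (configurable to the
  mean).
* Per-cluster percentages are always recomputed from raw counts and
  cluster sizes at reporting time; empty sets yield `NA`, never 0.
* Top-k degree lists break ties lexicographically by gene id, making
  every output deterministic.

## Known limitations

* The published z-scores cannot be reproduced from the printed counts
  under any closed form we tried; the random-draw procedure behind them
  is not recoverable. The package's z-scores are therefore validated by
  calibration and power on planted truth instead of by matching those
  printed values.
* Two published cluster-size tables disagree on DD (3080 vs 3238); the
  partition algebra enforced here implies a single consistent DD, and
  the G-statistic fixtures use the count variant that reproduces the
  printed G values.
* The published percent-reduction statement about gene lengths (a "57%
  reduction" from 4725 to 2735 bases) is not consistent with any
  percent-change reading (≈42%); `length_summary()` reports raw means
  only.
* Annotations are used exactly as given: no GO ancestor propagation, no
  protein-model/gene disambiguation beyond one-protein-per-gene.
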