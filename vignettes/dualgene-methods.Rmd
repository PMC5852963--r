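---
title: "Methods: profiling dual-role cancer genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profiling dual-role cancer genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualgene)
```

## The problem

Some genes act as oncogenes in one cellular context and as tumor
suppressors in another. `dualgene` compares these dual-role genes (POTSFs,
"proto-oncogenes with tumor-suppressor function") against plain oncogenes
(ONC), tumor suppressors (TSG) and non-cancer-related genes (NCRG) on
three axes: somatic mutation burden, expression level, and position in the
protein–protein interaction (PPI) network. The working hypothesis the
tooling is built to examine: dual-role genes accumulate mutations like
oncogenes, are expressed like tumor suppressors, and sit at network hubs
under strong purifying selection.

## Gene-set assembly

The universe is partitioned from three inputs: an oncogene list, a
tumor-suppressor list, and a curated list of dual-role genes drawn from the
overlap of the first two. Labels are assigned one per gene: `POTSF` if
curated; `ONC`/`TSG` if in exactly one parent list; `NCRG` if in neither;
and `UNRESOLVED` for overlap genes that were never curated either way.
`UNRESOLVED` genes are excluded from all four comparison sets — the
conservative reading when a candidate's dual role was examined but not
confirmed. Symbol matching is exact after uppercasing and whitespace
stripping; no alias resolution is attempted, and the packaged curated
table deliberately keeps its source's verbatim `WT` token rather than
guessing an intended symbol.

The packaged table (`load_potsf_table()`) carries 83 curated dual-role
genes in three functional classes: 41 transcription factors, 13 kinases
and 29 others. Association tallies (`tally_associations()`) deduplicate
(gene, label) pairs before counting; per-label percentages are stored at
full precision (they sum to exactly 100) and rounded to one decimal place
only for display.

## Mutation profiling

MAF-like tables are mapped onto a closed ten-class vocabulary (missense,
nonsense, silent, in-frame and frameshift insertions/deletions,
splice-site, nonstop, non-coding RNA). Records with tokens outside the
standard MAF classification (e.g. `Translation_Start_Site`) are skipped
and tallied rather than guessed at. The non-silent filter retains exactly
the eight protein-altering classes and removes silent and RNA records.

The rate statistic is

$$\text{rate} = \frac{n_\text{mutations} / n_\text{cases}}{L}$$

with $L$ the gene length in base pairs and $n_\text{mutations}$ counting
both silent and non-silent records (the burden comparison, by contrast,
uses non-silent counts only). Gene length is taken from the user-supplied
universe table; no particular length definition is imposed, so users should
supply the definition (exonic, CDS, transcript) consistent with their
mutation calls. Per-cohort case numbers default to the distinct sample ids
observed in the cohort, with an override table for published cohort sizes
(`load_cohort_sizes()` ships eleven pan-cancer labels, colon and rectal
merged into one cohort).

Variant classes also map onto potential functional-impact groups:
truncating and splice-disrupting classes (nonsense, frameshifts,
splice-site, nonstop) as potential loss-of-function, the remaining
protein-altering classes (missense, in-frame indels) as potential
gain-of-function. This is a coarse convention, not a per-variant
prediction, and the mapping is an argument users can replace.

## Expression normalisation

Two routes mirror the two data types the analysis targets:

* **Cancer matrices (RSEM-style):** each sample column is divided by its
  median over genes with positive values, making the positive-gene median
  exactly 1. Zeros are excluded from the median (a median dragged to zero
  by dropouts would be meaningless as a scaling factor) and stay zero.
  The operation preserves within-sample ranks and is idempotent.
  Cohort-level values are arithmetic means over samples, taken after
  normalisation.
* **Organ RNA-seq (exon coverage):** per-gene RPKM uses summed exon counts
  over summed exon lengths against the sample's total mapped reads;
  replicate samples of an organ are averaged. Values are then
  log2-transformed with a pseudocount of 1 (configurable; zero RPKM maps to
  zero) and standardised within each organ to mean 0, sd 1 (sample sd,
  $n-1$). A zero-variance organ column is an error, not a silent NaN.

With pseudocount 0 the Z-scores are exactly invariant to rescaling the
RPKM matrix by any positive constant; with the default pseudocount 1 this
invariance is approximate (exact only in the limit of large values), which
is the usual price of handling zeros.

## Network analysis

Interactomes are ingested as two-column edge lists into simple undirected
graphs: self-loops dropped, duplicate and reversed-duplicate edges merged,
scores discarded (the analysis is unweighted). Degree and the local
clustering coefficient $C(v) = 2T(v)/(k(k-1))$ come from igraph, with
$C = 0$ assigned to nodes of degree < 2 so that set-level averages are
defined. The dual-role neighborhood network keeps every POTSF node plus
its direct neighbors, induced on that node set by default (a star-only
variant is available, since published node/edge counts for such networks
rarely state which construction was used).

### Dense-module detection

The MCODE-style procedure is re-implemented from its published
description:

1. **Vertex weighting.** For each node, take the subgraph induced on its
   closed neighborhood, find the highest k-core of that subgraph, and set
   `weight = k_max × density(core)`. Nodes with degree < 2 get weight 0.
2. **Seeded growth.** Process seeds in decreasing weight order, ties
   broken by lexicographic gene id (this makes the output invariant to
   vertex input order). From each unseen seed, add neighbors breadth-first
   whose weight is at least `(1 − vwp) × seed weight` (default
   `vwp = 0.2`); nodes already assigned are never reused.
3. **Post-processing.** The haircut (default on) iteratively removes nodes
   singly connected within the complex, leaving its 2-core; emptied
   complexes are discarded. Fluff (default off) optionally adds
   high-density fringe neighborhoods. Complexes are ranked by
   `score = density × size`.

On a 4-clique the weighting gives every vertex weight 3 (core k = 3,
density 1), and a planted clique attached to a path is returned as the top
complex — the two hand-checkable cases in the test suite.

### dN/dS

`dnds_nei_gojobori()` implements Nei–Gojobori (1986) pathway counting:
synonymous site fractions per codon position, equal-weight averaging over
all mutational pathways between codons differing at multiple positions,
and the Jukes–Cantor correction $d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$
applied to both proportions. Two conventions are fixed and documented
because implementations differ: changes that would create a stop codon are
counted as nonsynonymous (so synonymous + nonsynonymous sites always sum
to three per codon), and pathways passing through a stop codon are
excluded whenever a stop-free pathway exists. $p \ge 3/4$ raises a typed
saturation error; $\omega$ is undefined (`NA`) when $d_S = 0$. The
counting method itself is a stated choice — the interface returns all site
and difference counts so alternative corrections can be layered on top.

## Set comparisons

Three tests are exposed: two-sided Kolmogorov–Smirnov (mutation patterns),
Wilcoxon rank-sum (expression; KS is also available since figure legends
and methods sections often disagree on which was used), and Pearson
chi-square without continuity correction (category proportions).
Small-sample behaviour: exact p-values when `min(n, m) ≤ 10` (and, for
Wilcoxon, tie-free), asymptotic otherwise; fully tied Wilcoxon data return
p = 1 with a warning. The reported Wilcoxon statistic is the rank-sum of
the first sample. `compare_sets()` runs every unordered pair, flags
significance at α = 0.05, and names the *higher* set — defined as the set
with the greater mean, the rule used to place stars on distribution
panels. No multiple-testing correction is applied by default, matching the
raw-α convention of the analyses this package reproduces; a
Benjamini–Hochberg option is provided.

The chi-square route deserves one note: testing the 2×10 table formed by
the packaged top-10 cancer-type percentage vectors (dual-role-associated
vs global 2012 shares, percentages used directly as counts, no continuity
correction) yields X² = 20.196, df = 9, p = 0.0167 — computed at run time
by the acceptance script, with the test asserting significance at α = 0.05.
Most expected cells in that construction are below 5, which the function
reports as a warning fraction; the percentage-as-count construction is a
direction check, not a calibrated test.

## Synthetic data: what it emulates and what it does not

The generators produce data with the statistical structure the analysis
assumes, at desk scale:

* `simulate_universe()` — set sizes default to the curated 83/1320/952
  plus 1000 non-cancer genes; lengths are log-normal (median 1500 bp,
  sdlog 0.6, floored at 90 bp), a reasonable shape for coding lengths.
* `simulate_mutations()` — per gene × cohort Poisson counts with mean
  `base_rate × multiplier(set) × length × n_cases`. The default
  `base_rate = 6e-6` per bp per case reproduces the pan-cancer scale
  (~0.009 mutations per gene per case at 1.5 kb); default multipliers
  3 / 2.5 / 1.2 / 1 (POTSF/ONC/TSG/NCRG) encode the elevated dual-role and
  oncogene burden. Class probabilities default to the published per-class
  count proportions, renormalised (the published counts famously exceed
  their own published total; only relative weights are usable).
  `simulate_class_fixture()` instead pins exact totals — 617,354 records,
  134,635 silent, 10,659 RNA — allocating the remaining 472,060 across the
  eight non-silent classes by largest-remainder rounding of those same
  proportions.
* `simulate_expression()` — `2^N(location(set), σ)` with σ = 2 log2 units
  (typical spread of log-expression across genes) and a +1 default
  location shift for TSGs, the qualitative normal-organ pattern.
* `simulate_network()` — growth with preferential attachment times a
  set-specific attractiveness (default 4 / 2 / 2 / 1, mirroring the
  observed mean-degree ordering). The `degree + 1` offset keeps new nodes
  attachable. Edge count is exactly `choose(m,2) + (n − m)·m`.
* `simulate_codon_pair()` — one proposal round per nucleotide site at
  probability `t` (default 0.05, a primate-scale synonymous divergence);
  synonymous proposals always accepted, nonsynonymous with probability ω,
  stops never. Under this construction the synonymous proportion
  approximates `t` and the nonsynonymous proportion `ω·t`, so the
  Nei–Gojobori estimator recovers ω with a small (few percent) downward
  bias from the asymmetric Jukes–Cantor correction and from
  stop-proposal rejection; at ω = 0.2 the mean estimate over 50 seeds is
  ≈ 0.18–0.19, comfortably inside the ±0.05 recovery band the tests
  assert.

Every generator is a pure function of its arguments and a seed, and every
artifact round-trips through its module's reader.

What the synthetic data does **not** capture: trinucleotide mutation
signatures and hotspots, copy-number events, expression correlation
between genes, batch structure, the heavy right tail of real PPI degree
distributions beyond what preferential attachment produces, and codon
usage bias. Passing recovery tests therefore demonstrates that the
pipeline measures what it claims on data satisfying its model assumptions
— not that real TCGA/interactome data satisfy those assumptions.

## Numerical and design choices

* Median normalisation excludes zeros from the median; an all-zero sample
  is an error naming the sample.
* Z-scores use the sample (n−1) standard deviation.
* The log2 pseudocount is 1, configurable.
* KS/Wilcoxon exact-vs-asymptotic switch at `min(n, m) ≤ 10`. Both
  asymptotic p-values are conservative at moderate n — measured null
  rejection at α = 0.05 is ≈ 0.035–0.045 rather than 0.05 — which the
  calibration tests run at n = 50 per sample, where the rate sits closest
  to nominal.
* MCODE ties broken lexicographically; "default parameters" mapped to
  degree cutoff 2, node score cutoff (vwp) 0.2, k-core 2, haircut on,
  fluff off.
* Un-curated overlap genes: `UNRESOLVED`, excluded from comparisons (a
  duplicate-membership mode was considered and rejected — it would break
  the one-label-per-gene invariant every downstream count relies on).
* Duplicate identical mutation rows are kept (no dedup rule is imposed by
  the formats involved); exact-duplicate removal is left to the caller.

## Problem sizes used by the test suite

The suite exercises recovery properties at sizes chosen to give the
assertions high power while keeping the default run in tens of seconds:
200 genes per set × 100 cases × 100 replicates for the 3× rate-multiplier
recovery; 500 genes per set for the ±1 log2-unit expression shift;
500-node networks × 100 replicates for the hub-bias property; 1,000 codons
× 50 seeds for ω recovery; 1,000 replicates per test for null calibration;
and the full 617,354-record class fixture for the non-silent filter.

## Limitations

* The dN/dS estimator is the equal-pathway Nei–Gojobori form; no
  transition/transversion weighting or codon-frequency correction.
* The mutation-rate statistic inherits whatever length definition the
  universe file carries.
* Significance annotation uses raw p-values at α = 0.05 by design;
  6 pairwise tests per panel would survive any reasonable correction in
  the strongly separated cases the tooling targets, but users testing many
  cohorts should enable the BH option.
* The chi-square direction check treats percentage vectors as counts;
  its p-value should be read qualitatively.
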