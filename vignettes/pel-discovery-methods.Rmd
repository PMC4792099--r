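---
title: "PEL discovery: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PEL discovery: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelscan)
```

## The procedure and its assumptions

`pelscan` implements a genotype-first strategy for locating genomic loci that
are recurrently mutated in phenotypically similar patients. The unit of
evidence is the *overlap* of copy-number variants: two patients are taken to
be genetically related at a locus when a CNV of one shares at least one base
pair with a same-class CNV (both gains, or both losses) of the other. The
assumptions this encodes are worth stating:

* **Overlap is symmetric genetic evidence.** No weighting by overlap length,
  gene content or recurrence: a single shared base pair makes an edge. This
  is deliberately permissive; specificity is recovered later by the clique
  filter and the statistics.
* **A cluster of patients is a clique.** Requiring *all pairwise* overlaps,
  not merely connectivity, protects against the transitivity artefact of
  long CNVs (A overlaps B, B overlaps C, but A and C are disjoint).
* **A clique is only meaningful at a common locus.** Pairwise overlap does
  not imply a shared region when patients carry several CNVs, so each clique
  is swept for genomic positions covered by a same-class CNV of every
  member. When every member carries a single CNV on the chromosome this
  always succeeds (the 1-D Helly property: pairwise-intersecting intervals
  on a line share a point); multi-CNV cliques can genuinely fail and are
  rejected. Rejected maximal cliques are *not* re-split into qualifying
  sub-cliques; the rejected count is reported so the size of that choice is
  measurable.
* **Phenotype similarity lives in an ontology.** Patient annotations are
  propagated to all ancestors before counting, so enrichment can be detected
  at whatever level of description clinicians happened to co-annotate. A
  switch (`pel_config(propagate = FALSE)`) restores raw counting; general
  terms can then no longer accumulate counts from specific annotations.

The discovery funnel is: network → maximal cliques (≥ 3 members, no upper
cap, deduplicated) → common-locus filter → per-clique hypergeometric
enrichment → case–control Fisher association → Benjamini–Hochberg across all
candidate associations → penetrance estimation.

## Statistics

The enrichment p-value is the exact hypergeometric upper tail
`P(X >= k)` for `k` annotated members in a clique of `n`, against `K`
annotated patients among `N` in the annotated cohort; `N` is the cohort
*after* removal of patients without phenotype annotations, since those never
enter the test. The one-sided Fisher exact p of the case–control table is
computed from the same kernel (the conditional distribution of the top-left
cell given the margins), which the tests verify against both exhaustive
enumeration and an independent implementation.

Three selection thresholds are applied per clique–term pair: adjusted
p < 0.05, at least 3 annotated members, and annotated members ≥ 50 % of the
clique. Two readings were genuinely open:

* **Adjusted vs raw thresholding.** The enrichment threshold is applied to
  the per-clique Bonferroni-adjusted p by default — the conservative
  reading — with `threshold_on = "raw"` available.
* **Bonferroni family.** The family is the set of terms actually carried by
  the clique being tested (terms carried by no member are not tested and do
  not inflate the family).

The Fisher test is one-sided in the cases-enriched direction, since the
question is whether patients are *more* frequently mutated at the locus than
healthy controls; `fisher_alternative = "two.sided"` is available. The BH
family is all candidate clique–term associations of the run jointly.

## Penetrance and the baseline prevalence

Penetrance is a frequency-ratio estimate: with case carrier frequency
`f_case = k_case / N_case`, control frequency `f_ctrl = m_ctrl / N_ctrl` and
a baseline phenotype prevalence `pi`,

    penetrance = 100 * f_case * pi / (f_case * pi + f_ctrl * (1 - pi))

It is exactly 100 when no control carries the locus and collapses to
`100 * pi` when case and control frequencies are equal. The default
`pi = 0.053` was fixed by a consistency analysis: on a 6,564-case /
5,072-control population, the three reduced-penetrance values that this
estimator family is known to produce for carrier counts 10, 9 and 8 with one
control carrier (30.2 %, 28 %, 25.7 %) are mutually consistent at a single
prevalence, and solving each of the three pairs for `pi` gives 0.0530 every
time (the package tests re-derive this). The value is a configurable
parameter (`pel_config(prevalence = )`), not a constant of the method.

## Null models

Five permutation designs, each preserving a stated set of marginals exactly
(asserted programmatically on every repetition in the tests):

| kind | randomizes | preserves |
|---|---|---|
| `dgv_cnvs` | case CNVs replaced by control variants (without replacement) | patient ids, per-patient CNV counts, phenotypes |
| `case_location` | case CNV starts, uniform on the chromosome | lengths, chromosome counts, ownership, classes |
| `control_location` | control variant starts | lengths, chromosome counts, sample ids |
| `rewire_patient_cnv` | patient–CNV assignment | global CNV multiset, per-patient counts |
| `shuffle_phenotypes` | phenotype profiles across patients | whole profiles, hence exact term frequencies |

Location shuffling keeps each CNV on its own chromosome — the least
assuming scheme that preserves both the length distribution and chromosome
frequencies. Phenotype shuffling permutes whole profiles rather than
individual term–patient pairs, the only reading that preserves term
frequencies exactly while keeping realistic within-patient term
co-occurrence. Repetition seeds derive deterministically from the master
seed, so a (kind, seed) pair reproduces a run bit for bit.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` emulates the structure that makes the method work on
real repositories:

* heavy-tailed log-normal CNV lengths, with case CNVs (mean ≈ 3 Mb) about
  two orders of magnitude longer than control variants (mean ≈ 30 kb);
* patients carrying one or a few CNVs (Poisson, topped up to one) and
  sparse phenotype profiles (Poisson leaf noise, topped up to one term, so
  roughly half of patients carry a single term);
* a dense control population (default 98 variants per sample — the
  per-sample rate of large population catalogues) whose genome-wide
  coverage is what lets the Fisher stage reject chance loci;
* implanted ground-truth loci: carriers receive a CNV covering the full
  locus extended by exponential flanks (variable breakpoints are what makes
  the minimal common intersection hug the implant), and carry the implant
  term with a set penetrance. Controls receive no implant-covering variants
  unless `leak_rate > 0`.

Scale choices, made once: 200 patients / 500 controls on an 8 × 125 Mb
genome, with a 259-term toy ontology (depth 3, branching 6). These were
calibrated to the *relative* densities of real studies — per-term annotation
frequencies around one percent of the cohort and a background network
density within an order of magnitude of large real patient networks — while
keeping a full discovery run under a second, so that multi-hundred-rep null
studies and twenty-seed recovery benchmarks complete in minutes. The test
suite runs null designs at 20–50 repetitions and the acceptance script at
20; the production default is 1000.

What it does **not** emulate: non-uniform placement of control variants
(real population catalogues cluster in polymorphic hotspots; the synthetic
background is near-uniform). One measurable consequence: relocating
near-uniform control variants (`control_location`) is
distribution-preserving, so that null's discovery count matches the real
count instead of falling below it as the other four designs do. A gap
between real data and this null therefore reflects control-side spatial
structure, which must come from real control catalogues, not from this
generator. Also not modelled: recombination hotspots, GC/gap-aware
placement, and any interaction between inheritance labels and CNV length —
the inheritance column is drawn independently at realistic proportions and
carries no signal.

## Numerical and representational choices

* **Coordinates** are 0-based half-open internally; published tab-separated
  formats are read/written 1-based inclusive and BED output 0-based
  half-open. Half-open arithmetic makes the ≥ 1 bp overlap test
  (`a.start < b.end && b.start < a.end`) and the intersection
  (max start, min end) exact, with abutting intervals sharing nothing.
* **Isolated patients** are not network nodes (they cannot join a clique);
  they are counted and reported. The diameter is computed on the largest
  connected component; shortest-path statistics average over ordered
  connected pairs.
* **CNV assignment tie-break**: when a clique member has several CNVs
  overlapping the common region, the longest, then leftmost, is assigned —
  deterministic, and maximizing the chance of a non-degenerate
  intersection. A clique may legitimately yield several loci (different
  chromosomes, classes, or disjoint common regions); each is carried
  forward independently.
* **Redundancy pruning tie-break**: among enriched terms of one clique
  related as ancestor–descendant, the lower p survives; on exact ties the
  deeper (more clinically specific) term wins. Depth is the shortest
  distance to a root; the ontology may be a DAG (multiple parents), and
  ancestor sets reached along several paths are deduplicated.
* **Degenerate inputs**: an edgeless graph is an error for topology
  statistics and yields an empty (but well-formed) association table from
  the pipeline; empty association sets write header-only tables; recovery
  scoring reports precision 1 with an explicit flag when there are no
  significant associations to score.
* **Control population size** defaults to the number of distinct sample
  ids (or record count without a samples column) and is overridable —
  population catalogues are explicit that their sample counts do not map
  one-to-one onto individuals.

## Known limitations

* Near-duplicate PELs (loci differing by one or two patients) are reported
  separately, not merged; identifiers are assigned by ascending adjusted p
  then genomic order, so duplicates sit adjacently in the output.
* Patient identity is the `patient_id` string; reconciling multiple
  submissions of one individual is upstream curation.
* The common-locus filter does not re-examine sub-cliques of rejected
  maximal cliques; the rejected count quantifies the potential loss.
* With small cohorts and a sparse control set the one-sided Fisher test is
  nearly always significant once enrichment is; the control population must
  be dense enough to cover the genome for the association stage to add
  discrimination (the default generator is).
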