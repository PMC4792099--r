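# pelscan

Discovery of **Phenotypically Enriched Loci (PELs)** from patient networks of
copy-number variants (CNVs).

## The problem

Clinical repositories collect, per patient, a handful of rare CNVs (genomic
gains and losses) and a sparse set of standardized phenotype annotations
(Human Phenotype Ontology terms). Individually these profiles are too thin to
characterize a syndrome; collectively they contain recurrent locus–phenotype
associations. `pelscan` finds them with a genotype-first network strategy:

1. **Patient network** — patients are nodes; an edge connects two patients
   whenever a CNV of one overlaps a CNV of the other by ≥ 1 bp on the same
   chromosome and with the same class (both gains or both losses).
2. **Cliques** — maximal cliques of ≥ 3 patients are enumerated. Because a
   long CNV can bridge patients that do not mutually co-localize, each clique
   is filtered by a coordinate sweep: it is kept only if some genomic region
   is covered by a same-class CNV of *every* member. The candidate locus is
   the minimal common intersection (max start, min end) of one assigned CNV
   per member.
3. **Phenotype enrichment** — annotations are propagated through the ontology
   (a patient annotated with a specific term also counts for its ancestors).
   Each term carried by a clique is scored with the exact hypergeometric
   upper tail

   P(X ≥ k) = Σ<sub>i≥k</sub> C(K, i) · C(N − K, n − i) / C(N, n)

   with *n* the clique size, *k* its annotated members, *K* the annotated
   patients cohort-wide and *N* the annotated cohort size. A term is kept
   when the per-clique Bonferroni-adjusted p is < 0.05, at least 3 members
   carry it and they make up at least 50 % of the clique; ontologically
   redundant survivors are pruned to the most significant representative.
4. **Case–control association** — each enriched locus is tested against a
   healthy-population structural-variant catalogue with a one-sided Fisher
   exact test on [[k<sub>case</sub>, K<sub>case</sub> −
   k<sub>case</sub>], [m<sub>ctrl</sub>, N<sub>ctrl</sub> −
   m<sub>ctrl</sub>]], where m<sub>ctrl</sub> counts distinct control samples
   with a same-class variant overlapping the locus by ≥ 1 bp.
   Benjamini–Hochberg adjustment is applied across all candidate
   associations; survivors at adjusted p < 0.05 are the pathogenic PELs.
5. **Penetrance** — per association, a frequency-ratio estimate
   100 · f<sub>case</sub>π / (f<sub>case</sub>π + f<sub>ctrl</sub>(1 − π))
   with baseline prevalence π (default 0.053), which is 100 % whenever no
   control carries the locus.

Five permutation null models (control-CNV substitution, case and control
location shuffling, patient–CNV rewiring, phenotype-profile shuffling)
quantify how far real discovery counts exceed chance, and a seeded synthetic
cohort generator with implanted ground-truth loci makes the whole pipeline
testable without access-controlled patient data.

## Worked example

```r
library(pelscan)

sim <- simulate_cohort(cohort_spec(seed = 7))   # 200 patients, 500 controls,
                                                # 3 implanted loci
res <- find_pels(sim$cohort, sim$ontology, sim$controls)
summary(res)
```

```
PEL discovery
  cohort: 200 patients (0 dropped without phenotypes)
  network: 130 nodes / 327 edges (70 isolated patients excluded)
  cliques: 16 maximal (>= 3 members), 1 without a common region, 15 qualified loci
  associations: 3 candidate -> 3 significant (BH p < 0.05) across 3 PELs

Top associations (of 3 significant):
 pel_id class chrom    start      end    term_id k_case n_clique m_ctrl
   PEL1  gain  chr2 49983986 50602034 HP:0000151     12       12     13
   PEL2  loss  chr1 29998244 30825259 HP:0000044     11       15     29
   PEL3  loss  chr3  9995339 10500678 HP:0000259     11       12     20
 p_fisher_bh penetrance_pct
    3.25e-16           11.4
    2.77e-12            5.0
    6.55e-12            7.1
```

The three significant PELs coincide with the three implanted loci: each locus
is the minimal common intersection of the carrier CNVs (hence the starts just
inside the implanted breakpoints), and `k_case/n_clique` shows 11–12 clique
members carrying the enriched term (penetrance 0.9, plus occasional clique
hangers-on). `m_ctrl` counts the control samples whose variants happen to
overlap the locus — the dense control background (~98 short variants per
sample) means even true loci collect a few chance carriers, which is what
drags the penetrance estimate below 100 %; a locus with `m_ctrl = 0` would
read exactly 100.

```r
evaluate_recovery(res, sim$truth, sim$ontology)[c("recall", "precision")]
#> $recall    [1] 1
#> $precision [1] 1
```

A command-line front end covering the same workflow (subcommands `simulate`,
`run`, `nulls`, `stats`) is installed under `exec/pelscan`.

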