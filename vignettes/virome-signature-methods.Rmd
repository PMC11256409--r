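---
title: "Methods: dual-modality gut virome signature discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-modality gut virome signature discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virosig)
library(dplyr)
```

## The problem

Case-control studies of the human gut virome face two compounding
difficulties. First, no single sequencing strategy sees the whole virome:
virus-like-particle (VLP) enrichment favours free phage particles (and
strongly over-captures small ssDNA families such as *Microviridae*), while
bulk whole-community metagenomes favour integrated prophages and actively
replicating viruses (*Myoviridae* and other tailed phages). Second, most of
the statistical machinery operates on noisy intermediate products — contig
catalogs of mixed viral/bacterial origin, per-base read depths, protein and
CRISPR-spacer hits — whose processing rules materially change the result.

`virosig` implements the full downstream analysis as a tested pipeline:
viral contig triage, species-level clustering into viral operational
taxonomic units (vOTUs), robust abundance profiling, taxonomic and host
annotation, diversity statistics, dual-modality differential-abundance
signature calling, and random-forest validation. Because real cohorts are
large and external, every stage is exercised against a seeded synthetic
cohort generator with planted disease signatures, so that the pipeline's
operating characteristics (sensitivity, false-call rate, calibration) are
measured rather than assumed.

## Viral triage

Each assembled contig carries an evidence record: CheckV-style viral and
host gene counts, a DeepVirFinder-style score/p-value, a VIBRANT-style
boolean call, the number of bacterial universal single-copy orthologs
(BUSCOs) among its genes, and completeness/contamination estimates. Rules
fire in a fixed order; the first disqualifying rule decides:

1. length screen — only contigs **strictly longer than 2,000 bp** enter;
2. host-like exclusion — more than 10 host genes *and* more than five
   times the viral gene count (the conjunctive reading; a config flag
   switches to the disjunctive variant, since the prose rule admits both);
3. candidate call — more viral than host genes, **or** detector score
   > 0.90 with p < 0.01, **or** a positive VIBRANT-style call;
4. contamination — BUSCO ratio (BUSCOs / total genes) **>= 5%** removes
   the candidate; the comparison is exact (1 of 20 genes triggers it);
5. completeness — the final viral set requires completeness **strictly
   above 50%**.

These boundaries are deliberately strict/inclusive exactly as listed; the
test suite pins each one and checks the whole engine against an
independent truth-table oracle on 1,000 random evidence rows.

## vOTU clustering

Viral genomes are dereplicated at the species level: **95% average
nucleotide identity over 70% coverage**, both inclusive. Design choices
where the criterion alone underdetermines an algorithm:

* *Coverage denominator* — the shorter sequence of the pair. This is the
  permissive convention of standard viral dereplication and is
  configurable.
* *Fragmented alignments* — segments are projected onto the shorter
  sequence and their interval union taken; identity is the
  alignment-length-weighted mean of segment identities.
* *Algorithm* — greedy longest-first centroid clustering (ties broken by
  lexicographic id). A sequence joins the first centroid it matches,
  otherwise founds a cluster. Because centroids are founded in decreasing
  length order, the representative (the vOTU reference) is the longest
  member *by construction*, which is the defining property we need.
* Clusters co-built with an external reference catalog are kept only when
  they contain at least one study genome.

Greedy centroid clustering is order-dependent by nature; fixing the order
(length, then id) makes it deterministic, and an independent
reimplementation walking the same order is the test oracle.

## Abundance model

The relative abundance of a vOTU in a sample is computed in three steps:

1. **trimmed depth** — per-base depths (zero positions included) are
   sorted and `floor(0.1 * L)` positions removed from each end before
   averaging. The floor convention never removes more than 10% and leaves
   vectors shorter than 10 positions untrimmed; trimming is stable under
   permutation of positions.
2. **confirmation** — a vOTU's depth is zeroed in samples where an
   independent read classifier assigned it no reads at all, suppressing
   mismapping-driven false positives.
3. **closure** — depths are divided by the per-sample total. All-zero
   rows are retained (not dropped) so sample sets stay aligned across
   modalities, and are flagged as having no viral signal.

The virus-to-bacterium ratio divides genome-length-normalised read counts
("cell counts"), summed over viruses, by the same sum over bacteria.

## Annotation

Protein hits are filtered at identity >= 30%, query and subject coverage
>= 50%, bit score >= 50 (all inclusive, matching the search tool's
semantics). Family assignment is by protein voting with a size-dependent
quorum: genomes with fewer than 30 genes need strictly more than one
fifth of their proteins matched to the winning family; genomes with 30 or
more genes need at least 10. A protein with hits to two families votes
once for each; ties for the best family are conservatively left
unclassified. A shipped static table maps families to eukaryotic or
prokaryotic viruses (unknown families map to `unknown`, never an error).
Hosts are assigned from CRISPR spacer matches at bit score >= 45 or
genome alignments at >= 90% identity covering >= 30% of the viral genome;
roughly a fifth of synthetic vOTUs get no host evidence, mirroring the
dark fraction of real catalogs.

## Diversity and ordination

Alpha diversity (observed richness and Shannon in natural-log units) is
computed per kingdom subset, renormalising abundances within the subset —
the same proportion handling as standard diversity routines. Beta
diversity is Bray-Curtis on square-root transformed abundances; PCoA is
classical metric scaling (only positive-eigenvalue axes are reported,
variance fractions relative to the positive spectrum). PERMANOVA uses the
one-way decomposition

$$R^2 = 1 - \frac{SS_\text{within}}{SS_\text{total}},\qquad
F = \frac{SS_\text{between}/(k-1)}{SS_\text{within}/(N-k)},\qquad
p = \frac{1 + \#\{F_\pi \ge F\}}{1 + n_\pi}$$

with 999 label permutations by default. The permutation stream is drawn
after sorting samples by id, so the result is invariant to input row
order given one seed — a property we test. The implementation is checked
against `vegan::adonis2` for the observed F and R², and its type-I error
is calibrated by simulation (200 null datasets). Ordination plots draw
95% confidence ellipses; published virome analyses are inconsistent about
80% vs 95% regions, and we standardise on 95%.

## Signature calling

Per modality, every vOTU present in at least 10% of that modality's
samples (a configurable prevalence filter; excluded vOTUs are reported as
`not_tested`, never silently as negative) is tested case vs control with
the two-sided Wilcoxon rank-sum test — exact by enumeration when the
combined n is at most 12 without ties, otherwise the tie-corrected normal
approximation with continuity correction. P-values are
Benjamini-Hochberg adjusted **within each modality**; a vOTU is a
signature only when q < 0.05 in *both* modalities with the *same*
direction (sign of the case-minus-control mean). Direction uses means
rather than medians to match fold-change semantics; a 1e-9 pseudocount
enters fold-change reporting only. Cross-modality agreement is summarised
by Fisher's exact test on the 2x2 membership table of
differential-in-VLP against differential-in-bulk. The odds ratio we
report is the sample cross-product (a·d)/(b·c) — a closed form that an
enumeration oracle can check — not the conditional-MLE estimate that
`fisher.test` prints, which differs for extreme tables. The conservative
AND-rule drives the null false-call rate well below the per-modality
FDR level: under a fold-1 null the fraction of vOTUs called is about
0.1% across 20 seeds (bounded at 1% in the acceptance suite).

Functional comparisons between signature groups use per-function 2x2
Fisher tests on occurrence (a vOTU either carries the function or not),
BH-adjusted across functions at q < 0.05.

## Random-forest validation

Classifiers are random forests with 500 trees and default feature
subsampling, the named implementation's defaults. Intra-dataset
performance is five repeats of stratified five-fold cross-validation;
each of the 25 held-out folds is scored by the out-of-fold predicted
case probability, and AUC is the Mann-Whitney probability with ties
counted 1/2 (exact, computed from mid-ranks). Feature importance is the
permutation mean decrease in accuracy (MDA), averaged over all 25 folds
to rank vOTUs; the reduced model unions each dataset's top-5 features
(the realised union size is reported, not assumed). Cross-dataset AUC
trains on one full dataset and scores another; leave-one-dataset-out
(LODO) trains on the concatenation of all other datasets. All of it is
bit-reproducible given data and seed.

## The synthetic cohort generator

The generator's defaults *are* the study conditions used throughout the
tests: 30 cases and 30 controls, each subject contributing one VLP and
one bulk sample; 50 vOTUs of which 10 are planted case-enriched and 10
control-enriched at fold 4.

* **Base abundances** are log-normal(0, 1) per (subject, vOTU), then
  closed (compositional). Heavy-tailed multiplicative noise is the
  standard microbiome abundance model and makes the rank-based test the
  appropriate one. A `carriage_prob` parameter can introduce
  subject-level absences; its default is 1 because the base model has no
  occupancy component, and occupancy zeros measurably dilute rank-test
  power (worth studying, but not part of the reference conditions).
* **Modality coupling** — VLP and bulk samples of a subject share one
  latent abundance vector; VLP samples multiply whole families by capture
  factors (default *Microviridae* x5, *Myoviridae* x0.3, the direction
  and rough magnitude of the VLP/bulk family shifts seen in real paired
  datasets) before re-closure. This separates modalities in ordination
  while keeping case-control signatures concordant. No quantitative model
  of the true capture bias exists; these factors are free parameters, not
  estimates.
* **Depths** are per-base i.i.d. Poisson with mean proportional to
  sample abundance times `mean_depth` (default 10 reads/bp at average
  abundance). Genome lengths are uniform on 2–10 kb — the catalog's entry
  floor up to small tailed-phage size, keeping depth vectors cheap enough
  that whole-cohort simulations run in seconds.
* **Dropout** — with probability `dropout_rate` (default 0.02) a truly
  absent vOTU receives spurious low depth (5% of `mean_depth`) and a zero
  classified-read count, so the confirmation step has real work to do.
* **Evidence tables** — every planted vOTU gets a contig record passing
  triage, plus eight decoy contigs exercising each rejection verdict and
  five near-duplicate contigs (96–99.5% identity, 80–95% coverage) that
  the clustering stage must collapse. Protein hits meet the family-voting
  quorum for the planted family (sub-threshold hits only for
  "dark-matter" vOTUs); host evidence splits ~60/20/20 between spacer
  matches, genome alignments, and none.
* **Determinism** — one master seed fans out to per-component child
  seeds by stable hashing of (seed, component id), so any sample's data
  is independent of generation order, and regeneration is byte-identical.

What the generator does **not** emulate: real sequence content (genomes
are random nucleotide strings), read-level artifacts (chimeras, strain
mixtures, GC bias), phylogenetic correlation between vOTUs, covariate
structure (age, medication), or batch effects between cohorts. Passing
tests therefore demonstrate that the *algorithms* are correct and
calibrated under the declared statistical model — not that the model
captures every property of real viromes.

## Numerical choices and degenerate inputs

* All-zero abundance rows are kept and flagged; Bray-Curtis between two
  all-zero samples is defined as 0 with a warning.
* Degenerate 2x2 margins give p = 1 and an undefined odds ratio with a
  warning; infinite cross-product ratios are reported as `Inf`.
* Constant vectors make Spearman's rho undefined (`NA` with warning).
* Compositions are validated to close within 1e-9; family aggregation
  conserves row sums to 1e-12.
* Trimming ties are broken by stable sort, so equal depths never make
  the trimmed mean order-dependent.

## Problem sizes

The bundled verification uses the sizes a desk-scale study of the
pipeline's operating characteristics needs: 1,000-row oracle checks for
the rule engine and trimmed depth, exhaustive Wilcoxon enumeration to
combined n of 10, 500 Fisher tables, 50-genome clustering oracles, one
full recovery cohort plus 20 null cohorts for the signature caller, 200
null datasets for PERMANOVA calibration, and three 60-sample cohorts for
the transfer/LODO analyses. These sizes were chosen to make every
statistical bound sharp enough to be informative while keeping the whole
suite runnable in minutes on a laptop.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 7)
run <- run_pipeline(cfg)
run
glance(run$signatures)
tidy(run$cv$vlp) |> head(5)
autoplot(run$signatures)
```

## Known limitations

* The greedy clustering is a single-linkage-to-centroid heuristic; a
  different visiting order would give different clusters, which is why
  the order is part of the contract.
* BH adjustment spans each modality separately; a joint adjustment
  across modalities would be more conservative still.
* The cross-product odds ratio diverges for perfect concordance; the
  acceptance report therefore also provides a Haldane-Anscombe corrected
  version.
* Random-forest results are reproducible only under the shipped
  fold-assignment scheme; any change to the RNG stream changes fold
  draws and hence fold-level AUCs (the means are stable).
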