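# virosig

Case-control association analysis for the human gut virome, across paired
virus-like-particle (VLP) and bulk metagenomic datasets.

## What it does and for whom

Gut virome studies of inflammatory bowel disease (and other case-control
designs) must identify disease-associated viral species from noisy
intermediate data: assembled contigs of mixed viral/bacterial origin,
per-base read depths, protein and CRISPR-spacer hit tables. No single
sequencing modality sees the whole virome — VLP enrichment favours free
particles, bulk metagenomes favour prophages — so robust signatures must
replicate in **both**. `virosig` is for bioinformaticians building or
auditing such analyses. It provides, as tidyverse-style functions over
data frames:

* **Triage** — rule-based viral contig classification (length > 2000 bp;
  host-like exclusion; gene-count / detector-score / VIBRANT-style
  candidate criteria; ≥5% BUSCO-ratio contamination removal;
  completeness > 50%).
* **Catalog** — greedy longest-first clustering of genomes into vOTUs at
  95% identity over 70% coverage (shorter-sequence denominator), longest
  member as representative, external-catalog integration, quality tiers.
* **Profiler** — the three-step abundance model: 10%-trimmed mean
  per-base depth → classified-read confirmation zeroing → per-sample
  closure; family aggregation; virus-to-bacterium "cell count" ratio.
* **Annotation** — diamond-style hit filtering (30/50/50/50), family
  assignment by protein voting (> 1/5 of proteins for genomes with < 30
  genes, ≥ 10 proteins otherwise), eukaryotic/prokaryotic kingdom lookup,
  host prediction from CRISPR spacers (bit score ≥ 45) and genome
  alignment (≥ 90% identity, ≥ 30% viral coverage).
* **Statistics** — observed/Shannon alpha diversity on kingdom subsets,
  square-root Bray-Curtis, PCoA, a seeded one-way PERMANOVA
  (R² = 1 − SS_w/SS_t, permutation p), Spearman correlation.
* **Signatures** — per-modality Wilcoxon + Benjamini-Hochberg with a
  dual-modality AND-rule (q < 0.05 in both, same direction), Fisher's
  exact cross-modality concordance test, per-function occurrence tests.
* **Validation** — random forests (500 trees) under 5×5 stratified
  cross-validation with MDA feature ranking, top-5 union feature
  selection, cross-dataset AUC matrices and leave-one-dataset-out (LODO).
* **Synthetic cohorts** — a seeded generator of complete studies
  (compositional log-normal abundances, planted fold-change signatures,
  family-specific VLP capture bias, Poisson per-base depths, evidence
  tables) with ground truth, so every stage is tested against planted
  answers.

The core statistic: a vOTU *v* is an IBD-associated signature iff

```
q_VLP(v) < 0.05  AND  q_bulk(v) < 0.05  AND  sign(Δ_VLP) = sign(Δ_bulk)
```

where q are BH-adjusted two-sided Wilcoxon rank-sum p-values over
relative abundances and Δ is the case-minus-control mean difference.

## Worked example

```r
library(virosig)

cfg <- sim_config(seed = 7)   # 30+30 subjects, 50 vOTUs, 10+10 planted at fold 4
run <- run_pipeline(cfg)
run
```

```
virosig pipeline run
  triage: 55/63 contigs viral
  catalog: 50 vOTUs
Dual-modality signature calls (alpha = 0.05 ):
  case-enriched: 10, control-enriched: 10, not significant: 30, not tested: 0
  VLP/bulk concordance: OR = Inf, p = 2.12e-14
  CV AUC: VLP 0.998, bulk 1.000; 6 selected features
```

Reading this: of 63 synthetic contigs, 55 pass the triage rules (the 8
decoys fall to the intended rejection verdicts); the 55 viral contigs
collapse to the 50 true vOTUs (5 near-duplicates merge into their
parents). The dual-modality caller recovers exactly the 10 planted
case-enriched and 10 control-enriched vOTUs with no false calls; the
infinite odds ratio says every VLP-differential vOTU was also
bulk-differential. Random forests on the called signatures separate cases
from controls almost perfectly within each modality.

```r
head(tidy(run$cv$vlp), 5)       # MDA feature ranking
#>   feature mean_mda
#> 1 vOTU020    11.7
#> 2 vOTU015    10.0
#> 3 vOTU019     9.40
#> 4 vOTU014     7.47
#> 5 vOTU007     7.34

run$permanova$modality          # VLP vs bulk community separation
#> PERMANOVA: pseudo-F = 8.864, R2 = 0.0699, p = 0.001 (999 permutations)
```

The modality effect (R² ≈ 7%, p = 0.001) is the generator's VLP capture
bias showing up in ordination space, as it does in real paired datasets.
`autoplot(run$pcoa, groups = ...)`, `autoplot(run$signatures)` and
`plot_transfer_auc(run$transfer_auc)` draw the standard figures; `tidy()`
and `glance()` methods return tibbles for every fitted result.

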