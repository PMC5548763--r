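# tcregnet

Time-course regulatory-network analysis of two-condition expression data
(genes and miRNAs), built for the classic pressure-overload cardiac
hypertrophy design: a treatment condition (transverse aortic banding,
"TAB") versus a control (sham surgery), profiled at an ordered series of
time points (d3, d5, d7, d14, d28) with one array per condition and time
point and three feature classes — transcription-factor (TF) genes, other
genes, and miRNAs.

## What it computes

Given linear-scale intensity matrices, feature-class lists and
regulator–target interaction tables, the pipeline chains:

1. **Preprocessing** — within-array median scaling, replicate averaging,
   a ≥ 1 intensity probe filter, between-sample quantile normalization
   (descending sort, per-rank medians), probe→gene collapse by maximum
   absolute fold-change sum, and a miRNA track (detection-flag filter,
   median probe combine).
2. **Differential expression** — per time point *t*, a feature is called
   up (+1) if its log2(TAB/sham) fold change exceeds
   `mean_t + 2·SD_t` of all same-class fold changes, down (−1) below
   `mean_t − 2·SD_t`; DE = nonzero at ≥ 1 time point. Up-regulated
   features split per time point into first-time (**New+**) and
   previously up (**Old+**) sets.
3. **Transition profile** — after removing extreme-intensity (top/bottom
   1%) and treatment-indifferent (within 1 SD of the difference
   distribution everywhere) features, the Pearson correlation between the
   sham and TAB intensity vectors is tracked over time per class; its
   minimum marks the transition stage.
4. **TF co-expression modules** — DE TFs with TAB-profile PCC ≥ 0.9 form
   an undirected network, partitioned by *iterated bridge bisection*:
   repeatedly cut the bridge with the smallest balancing value (size of
   the larger resulting part) as long as both parts keep > 10 nodes;
   leftovers land in a residual module.
5. **miRNA suppression** — (miRNA, TF, t) events where the pair is in the
   interaction table, the miRNA is up at *t*, and the TF is *not* up at
   *t*.
6. **Integrated signed network and hubs** — TF→target edges
   (|PCC| ≥ 0.9 + table row, sign = sign of PCC), miRNA→target edges
   (PCC ≤ −0.9 + table row), TAB-specific TF→miRNA co-expression edges
   (PCC ≥ 0.9 in TAB, < 0.9 in sham) and suppression edges; per time
   point, regulators first emerging there are ranked by total degree
   (top-5 TFs, top-3 miRNAs), with inward/outward counts split by sign.
7. **Enrichment** — one-sided hypergeometric over-representation of query
   sets against GMT annotation sets over an all-expressed background,
   Benjamini–Hochberg FDR (default 0.05); plus a CV-gene
   (cardiovascular-associated) proportion test among network targets.

A synthetic-data generator (`simulate_dataset`) reproduces the
statistical structure of such a study — log-normal background, TAB-only
effects, three planted TF modules with distinct temporal patterns,
planted DE/regulation/suppression — and records the ground truth, so the
whole pipeline runs and is tested with no download. See the methods
vignette (`vignettes/time-course-regulatory-network.Rmd`) for the model,
parameter and design discussion.

## Worked example

```r
library(tcregnet)

sim   <- simulate_dataset(simulation_config(seed = 1))
dir   <- tempfile()
paths <- write_dataset(sim, dir)
cfg <- pipeline_config(
  genes = paths[["genes"]], mirnas = paths[["mirnas"]],
  tf_genes = paths[["tf_genes"]], cv_genes = paths[["cv_genes"]],
  tf_target = paths[["tf_target"]], mirna_target = paths[["mirna_target"]],
  annotation_sets = paths[["annotation_sets"]])
res <- run_pipeline(cfg, file.path(dir, "out"))
```

which prints (seed 1, default configuration):

```
> res$dataset
expression_dataset: 2300 genes (300 TF) / 150 miRNAs; 5 timepoints (d3,d5,d7,d14,d28); conditions sham vs TAB
> res$partition
module_partition: 3 modules (30/25/15); 0 cuts
> attr(res$transition, "argmin")
nontf    tf mirna
 "d7"  "d5"  "d5"
> res$network
regulatory_network: 159 nodes (gene:65 mirna:26 tf:68), 270 edges (mirna_target:22 suppression:14 tf_mirna:191 tf_target:43)
> head(res$hubs[, c("timepoint","rank","id","class","total","outward","inward")], 6)
  timepoint rank      id class total outward inward
1        d3    1   TF039    tf     7       7      0
2        d3    2   TF044    tf     7       5      2
3        d3    3   TF052    tf     7       7      0
4        d3    4   TF035    tf     6       5      1
5        d3    5   TF031    tf     5       5      0
6        d3    1 miR-072 mirna    30       1     29
```

Reading this: the caller finds 369 DE genes and 29 DE miRNAs; the three
planted TF modules (sizes 30/25/15) are recovered exactly as separate
network components (no bridge cuts needed); the cross-condition
correlation bottoms out mid-course for non-TF genes and at d5 for TFs and
miRNAs; and the d3-emerging hub TFs are planted module regulators. The
enrichment stage flags the three planted module programs at q < 1e-20
while the uniformly drawn CV gene set is (correctly) not enriched.
`run_pipeline` writes every stage's TSV/JSON plus `manifest.json` into
the output directory, byte-identically across reruns.

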