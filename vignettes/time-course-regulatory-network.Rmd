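---
title: "Time-course TF–miRNA–gene regulatory network analysis: models and methods"
author: "tcregnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-course TF–miRNA–gene regulatory network analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcregnet)
```

## The scientific setting

`tcregnet` analyses a classic two-condition time-course design from
transcriptome studies of pressure-overload cardiac hypertrophy: a
treatment group (transverse aortic banding, "TAB") and a control group
(sham surgery) profiled at an ordered series of time points (by default
days 3, 5, 7, 14 and 28 after surgery), with one intensity measurement
per feature, condition and time point. Features fall into three classes —
transcription-factor (TF) genes, other genes, and miRNAs — and the
questions the pipeline answers are, in order:

1. *When does the transcriptome diverge most between conditions?*
   (cross-condition correlation transition profile)
2. *Which features respond, and when do they first respond?*
   (fold-change differential expression and New+/Old+ emergence)
3. *How do the responding TFs organize temporally?*
   (co-expression modules by iterated bridge bisection)
4. *Which miRNAs plausibly suppress which TFs, and when?*
   (three-condition suppression rule)
5. *What does the integrated regulatory wiring look like, and who are the
   stage-specific hubs?* (signed TF–miRNA–gene network, degree-ranked per
   first-emergence time point)
6. *Are interesting gene sets over-represented among the responders or
   targets?* (hypergeometric over-representation with Benjamini–Hochberg
   FDR)

All stages run on a synthetic dataset with recorded ground truth, so the
entire pipeline is testable without any external download.

## Preprocessing model

Input intensities are linear-scale and probe-level. The preprocessing
chain mirrors standard single-channel array practice:

* **Median scaling** (`median_scale`). Each sample is multiplied by one
  scalar so that its median equals a global reference. The reference is
  the median of the sample medians; since any positive reference merely
  rescales all samples by one common factor, downstream fold changes and
  correlations are unaffected. This choice is exposed as the `reference`
  argument.
* **Replicate averaging** (`average_replicates`): arithmetic mean per
  probe across repeated hybridizations of the same sample.
* **Probe filter** (`filter_probes`): a probe is dropped if its intensity
  is negative or below 1 in *any* sample of either condition. This keeps
  every retained value ≥ 1, which guarantees finite log2 ratios
  downstream.
* **Quantile normalization** (`quantile_normalize`). Each sample is
  sorted from highest to lowest; the reference value at each rank is the
  *median* across samples at that rank; each sample's values are then
  re-assigned by rank. Ties are broken by original row order (stable), so
  the operation is deterministic and idempotent, and all samples end up
  with the identical multiset of values.
* **Probe→gene collapse** (`collapse_probes`). When a gene has several
  probes, the probe whose per-time-point absolute log2 fold changes have
  the largest sum over all time points represents the gene. Fold changes
  for this choice are computed *after* normalization.
* **miRNA track** (`mirna_preprocess`): miRNAs flagged undetected
  (flag < 0) in every replicate probe on every chip are removed; replicate
  probes are combined by median; the combined matrix is quantile
  normalized.

Fold changes are `log2(TAB/sham)` per feature and time point
(`fold_changes`, `compute_fold_changes`).

## Differential expression: the 2-SD envelope

With one array per condition and time point there are no replicates, so
DE calling is distribution-based rather than test-based (`call_de`): for
each time point, the mean and standard deviation of *all* features' fold
changes (genes and miRNAs thresholded separately) define an envelope
`mean ± k·SD` with `k = 2`; features above the envelope are labelled
`+1`, below `-1`, otherwise `0`. A feature is DE if any time point is
nonzero. Two conventions are deliberately configurable because the
source method statement is ambiguous:

* `center`: envelope centred at the per-time-point mean (default; the
  mean is computed by the procedure and otherwise unused) or at zero;
* `sd_method`: sample SD with `n − 1` (default, conventional for
  estimated dispersion) or population SD.

Under pure Gaussian noise the expected flag rate per time point is the
two-sided 2-SD tail mass (≈ 4.6%); the acceptance suite checks this
calibration to within three binomial standard deviations over 50 seeds.

First-emergence bookkeeping (`classify_emergence`) splits the
up-regulated set at each time point into **New+** (first time up) and
**Old+** (up before); the two sets are disjoint and exhaust the
up-regulated set, and a feature's *first emergence* is the earliest time
point with any nonzero label. Hub ranking later groups regulators by this
first emergence.

## Transition profile

`filter_for_pcc` removes, per feature class, (i) features whose intensity
reaches the top or bottom 1% of the class's pooled (both-condition)
intensities at any time point — extreme values would dominate the
correlation — and (ii) features whose |TAB − sham| difference stays
within one SD of the per-time-point difference distribution at *every*
time point — features indifferent to the treatment would inflate the
correlation. Interpretations the source leaves open, both fixed here and
config-exposed: the percentile population is pooled per time point over
both conditions with inclusive cut-offs, and the 1-SD reference is the SD
of the differences across the stage-1 survivors.

`condition_pcc` then correlates the sham intensity vector against the TAB
intensity vector across the surviving features at each time point, and
`transition_profile` reports the per-class series and its argmin — the
transition stage of the response.

## TF co-expression modules by iterated bridge bisection

DE TF genes are connected by an undirected edge when the Pearson
correlation of their TAB temporal profiles is at least 0.9
(`build_tf_network`; positive correlation only, zero-variance profiles
produce no edges). The partitioner (`bisect_network`) then:

1. assigns connected components of size ≤ `min_size` (default 10),
   including isolated nodes, to a residual module (id 0);
2. repeatedly takes the largest unfinished partition, finds its bridges
   (`find_bridges`, depth-first search with low-link values), computes
   each bridge's **balancing value** — the size of the larger of the two
   parts its removal creates — and cuts the bridge with the smallest
   balancing value, provided both parts exceed `min_size`; ties are
   broken by the lexicographically smallest edge so the output is
   deterministic;
3. stops when no admissible cut exists anywhere; final modules are
   numbered by decreasing size.

The interpretation that a cut must leave *both* parts larger than
`min_size` reflects the stopping intent (modules must stay large enough
for enrichment testing); the alternative of revisiting non-largest
partitions earlier changes nothing on the graphs this stage sees, because
each cut leaves both parts in the work queue.

## miRNA suppression and the integrated network

A suppression event (`infer_suppression`) is a triple (miRNA, TF, time
point) such that the pair is in the miRNA-target interaction table, the
miRNA is up-regulated (+1) at the time point, and the TF is *not*
up-regulated there — "not up" meaning label 0 or −1, i.e. the rule only
requires absence of up-regulation. The rule uses DE status alone, not
co-expression.

The integrated network (`build_network`) merges three co-expression-
derived edge types, each requiring a supporting interaction-table row
where one exists:

| type | direction | sign | requirement |
|---|---|---|---|
| `tf_target` | TF → gene | sign of PCC | \|PCC\| ≥ 0.9 in TAB, table row |
| `mirna_target` | miRNA → gene | − | PCC ≤ −0.9 in TAB, table row |
| `tf_mirna` | TF → miRNA | + | PCC ≥ 0.9 in TAB **and** < 0.9 in sham |
| `suppression` | miRNA → TF | − | at least one suppression event |

The negative co-expression threshold is taken symmetric at −0.9 (the
source states only the positive threshold); "only in TAB" is
operationalized as treatment-PCC ≥ threshold with control-PCC below it;
TF→target edges do not require TAB-specificity (a
`treatment_specific_tf_edges` flag enables it). Duplicate
(source, target, type) triples collapse to one edge.

`hub_records` counts, per node, outward and inward edges split by sign —
the identities `total = outward + inward`, `outward = outward_pos +
outward_neg` (and likewise inward) hold by construction and are asserted
by the acceptance suite. `rank_hubs` reports, per time point, the top-5
TFs and top-3 miRNAs among regulators whose first DE emergence is that
time point, sorted by total degree. `cv_enrichment` tests
over-representation of cardiovascular-associated genes among network
targets with a one-sided hypergeometric test (the source reports only a
p-value threshold without naming a test; the hypergeometric is the
standard choice for a proportion against a finite background).

## Enrichment

`enrich` is a deliberately generic stand-in for web-based GO tools: a
one-sided hypergeometric upper-tail test of a query set against GMT-style
annotation sets over a declared background, with Benjamini–Hochberg
adjustment across all tested terms. Terms with zero overlap are kept at
p = 1 so the number of tests is stable. For TF-focused enrichment,
`background_excluding_transcription_terms` removes genes annotated to
basal transcription machinery from the background. Ontology structure
(DAG propagation, term grouping) is out of scope.

## The synthetic world

`simulate_dataset` generates the statistical structure the analysis
assumes, with everything planted recorded in a `ground_truth` object:

* **Background.** Per-feature baseline log2 intensity ~ N(8, 2) shared
  between conditions (typical single-channel log2 intensities span
  ~4–14); per-cell noise of SD `noise_sd/√2` in each condition, so the
  log2 fold change carries noise of SD `noise_sd` (default 0.25). This
  parameterization makes "effect = k × noise_sd" statements about fold
  changes, which is how detection strength is naturally quoted.
  Intensities are exponentiated to the linear scale, guaranteeing
  positivity.
* **Effects are TAB-only**; sham remains pure baseline, matching the
  log2(TAB/sham) convention.
* **TF modules.** Default three modules of sizes 30/25/15 (scaled
  proportionally if `n_tfs` differs from 300) with distinct temporal
  patterns: early-up switching off (and dipping) late, late-rising, and
  mid-repressed — echoing the qualitative temporal signatures of the
  motivating study at desk scale. Pattern amplitude is tied to the
  `de_effect` knob (default 2 log2 units, i.e. 4-fold).
* **DE plants.** A fraction `frac_de_genes` (default 0.1) of non-TF genes
  and of miRNAs receive a signed effect of magnitude `de_effect` shaped
  by a sustained ramp with early, mid or late onset. Sustained shapes are
  the realistic default for a stress response — and a temporally *flat*
  effect would carry no co-expression signal at all, which would make
  planted regulation undetectable by construction.
* **Regulation plants.** Half of each interaction table is planted
  regulation (targets inherit their regulator's temporal pattern, sign
  flipped for the ~25% negative TF regulations and always for miRNA
  targets), half is decoy rows among unplanted genes.
* **Suppression plants.** A suppressing miRNA is up-regulated exactly at
  the time points where its target TF's planted effect is ≤ 0; if a TF is
  up everywhere, its effect is withheld at its weakest time point. This
  makes the three-condition rule's ground truth well defined.
* **Determinism.** All randomness flows from `config$seed`; the caller's
  RNG state is saved and restored, and identical configs give
  bit-identical datasets and files.

What the generator does *not* emulate — so green tests do not establish
it: probe-level replicate structure and array spatial artifacts;
mean–variance dependence of real array noise; correlated baseline
structure between functionally related genes; enrichment of CV genes
among true targets (CV flags are drawn uniformly); and any particular
database's interaction-table biases.

## Numerical choices and degenerate inputs

* Pearson correlations with a zero-variance profile are undefined; in
  network construction they yield *no edge* (a DE TF can be flat in one
  condition), while `condition_pcc` raises an error naming the degenerate
  condition, since a zero-variance intensity vector there means the
  filter upstream failed.
* DE calling with fewer than two features is an error (SD undefined);
  a constant fold-change column (SD = 0) yields no calls.
* String ordering uses radix sort (C locale) everywhere, so tie-breaking
  and output ordering are locale-independent.
* All writers emit LF line endings in binary mode; all parsers accept
  CRLF. Numbers are written at 15 significant digits, which round-trips
  doubles in practice.

## Known limitations

* With one array per condition–time point, the 2-SD rule confounds
  biological effect with the per-time-point dispersion of the whole
  transcriptome; a time point with many strong responders has a wider
  envelope and therefore *higher* per-feature calling thresholds. This is
  inherent to the method being reproduced.
* The bridge-bisection partitioner only separates module structure that
  manifests as bridges; densely interconnected modules (no bridge between
  them) stay together. On the synthetic world modules are typically
  separate components, which the partitioner handles trivially.
* Enrichment replaces ranked-list GO tooling with plain
  over-representation analysis; results agree qualitatively, not term by
  term.

## A worked run

```{r example, eval = FALSE}
sim <- simulate_dataset(simulation_config(seed = 1))
dir <- tempfile()
paths <- write_dataset(sim, dir)
cfg <- pipeline_config(
  genes = paths[["genes"]], mirnas = paths[["mirnas"]],
  tf_genes = paths[["tf_genes"]], cv_genes = paths[["cv_genes"]],
  tf_target = paths[["tf_target"]], mirna_target = paths[["mirna_target"]],
  annotation_sets = paths[["annotation_sets"]])
res <- run_pipeline(cfg, file.path(dir, "out"))
res$partition
attr(res$transition, "argmin")
head(res$hubs)
```

The README shows the numbers this prints for the default seed.
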