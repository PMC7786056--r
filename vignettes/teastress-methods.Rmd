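---
title: "Methods: cross-species candidate screening and stress expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species candidate screening and stress expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teastress)
```

## The problem

Tea plant (*Camellia sinensis*) suffers yield losses from both cold and
drought, and the two stresses share an osmotic component. `teastress`
implements a candidate-gene discovery and profiling workflow for this
setting: genes that are strongly cold-upregulated in *both* of two model
species (*Arabidopsis thaliana*, *Solanum lycopersicum*) are treated as
evolutionarily conserved stress responders, mapped to their tea homologs,
merged with literature-curated cold-response genes, scored, networked, and
finally profiled by qRT-PCR under five treatments (Control, Cold, RecCold,
Drought, RecDrought) in the most stress-tolerant genotype of a germplasm
panel, selected by electrolyte leakage.

## Cross-species screening

For each expression dataset, the per-gene fold change is the ratio of mean
stress to mean control expression (`compute_fold_change()`). A pseudocount
(default 0.5) is added to **both** group means only when one of them is
exactly zero; typical values are never perturbed.

Genes are then binned into upregulation quartiles (`assign_quartile_ranks()`):
after sorting by ascending log2 fold change (ties broken by gene id, a stable
and reproducible rule), the gene at position $p$ of $n$ receives rank

$$ r = 1 + \lfloor 4 (p - 1) / n \rfloor \in \{1, 2, 3, 4\}, $$

so the strongest upregulation always lands in rank 4 and each rank class
holds $n/4$ genes (up to rounding). Quartile ranking, not a differential
expression test, is the screening device: it is scale-free and robust to
heterogeneous datasets.

When a species contributes several datasets, per-dataset ranks are aggregated
by **maximum** (`aggregate_species_rank()`). We read "detected in an
upregulated cluster" as an existence statement — one dataset placing the gene
in the top quartile suffices — and the maximum keeps the rank in 1–4.

`intersect_top_sets()` crosses the two species' top-quartile sets through an
ortholog map (a precomputed best-hit table; running BLAST is out of scope)
and reports Venn counts, with shared entries counted as ortholog groups.
`map_to_target()` carries each matched group to its tea homolog; a missing
homolog yields a gap-flagged candidate rather than a silent drop, because
panels assembled from mixed identifier systems otherwise shrink unnoticed.

## The combined relevance score

`combined_score()` is additive over three components:

* **GO component** — 4 points for response to cold (GO:0009409), 3 for
  response to oxidative stress (GO:0006979), 2 for response to stimulus
  (GO:0050896). When several terms are present the **best term counts**
  (maximum, not sum): this is the only combination under which the stated
  1–9 range is attainable (4 + 4 + 1 = 9). Unknown terms contribute 0.
* **Upregulation rank** — the species quartile rank 1–4, or 0 when the
  ortholog was not detected in an upregulated cluster.
* **Literature evidence** — 1 point.

`assemble_panel()` unites interspecies and literature candidates (duplicates
collapse, keeping both source tags), scores them and sorts by score with
gene-id tie-breaks. The packaged panel (`tea_panel_fixture()`) carries 45
genes — 9 interspecies and 36 literature entries; genes whose accession is
not public carry their trivial name with `id_source = "synthetic"`, and a
sidecar table records literature genes screened but not profiled.

## Interaction network

Edge confidence per evidence channel (textmining, experiments, databases)
lies in $[0,1]$; `combine_channel_scores()` merges selected channels by
probabilistic OR, $1 - \prod_i (1 - s_i)$. The source database's prior
correction (prior 0.041) is available behind a flag but off by default —
the plain product keeps the arithmetic transparent and auditable.
`filter_edges()` applies the combined-score threshold **inclusively**
(default 0.15, the "minimum required score" convention), and
`induce_subgraph()` restricts to candidate-internal edges while retaining
isolated candidates, since unconnected genes are themselves informative.
Regulation calls (up/down) are an input annotation supplied by the
expression stage, not computed by the network stage. Export is GraphML
(node attributes `regulation`, `relevance_score`; edge attribute `score`)
for downstream layout tools.

## qRT-PCR quantification

`quantify_panel()` implements the 2^−ΔΔCq method with amplification
efficiency fixed at 2 and no efficiency correction. Replicate-level
ΔCq = Cq_gene − Cq_ref pairs gene and reference wells of the same biological
replicate; ΔΔCq is the difference of mean ΔCq between treatment and control.
The significance test is a two-sided Student t (pooled variance) on the
replicate ΔCq values — ΔCq is the approximately normal scale, whereas
testing fold-change ratios directly is ill-behaved at n = 3. The fold-change
SE is computed on the log2 scale from the replicate-level fold changes and
back-transformed asymmetrically (`se_low`, `se_high`). Cells with fewer than
two replicates in either group are reported untestable (p absent, not
significant) instead of erroring. Multiple-testing correction defaults to
off, with `adjust = "BH"` available.

`classify_response()` reduces the five-treatment profile to one category per
gene with precedence both_up > stress-specific > recovery_elevated > down >
unresponsive; recovery elevation requires the recovery fold change to
*strictly* exceed its stress fold change and to be significant versus
control.

## REC phenotyping

Relative electrical conductivity is `compute_rec(L1, L2) = 100 * L1 / L2`:
conductivity immediately after immersion relative to conductivity after 2 h.
The ratio form is forced by the convention that REC is a leakage percentage
bounded by 100 when $L_1 \le L_2$; $L_1 > L_2$ yields a warning, not an
error, since meters occasionally drift. `select_tolerant_genotype()` ranks
genotypes by mean REC across the stress treatments (lowest = most tolerant),
breaking ties by genotype id and excluding (with a warning) genotypes
missing a stress.

## Downstream statistics

* `ward_cluster()` — agglomerative clustering with Ward linkage (D2 variant)
  on Euclidean row distances, rows **not** rescaled: the magnitude contrast
  between, say, 30-fold and 3-fold responders is part of the signal.
* `pca_pair()` — treatment-pair PCA on the correlation (standardized) matrix,
  because treatments differ strongly in variance scale; with two columns the
  component variances are $1 \pm r$.
* `treatment_correlations()` — per-gene Pearson correlations between
  treatments' replicate vectors, paired by replicate index (the only pairing
  unit the experimental design provides), with the exact two-sided p from
  $t = r\sqrt{n-2}/\sqrt{1-r^2}$. Zero-variance vectors leave the pair
  undefined and flagged.
* `correlation_clusters()` — Ward clustering of genes on the six
  upper-triangle correlations, default k = 3 reflecting the three broad
  co-response regimes such panels show (consistently positive, mixed,
  sign-reversed). Genes with undefined features are excluded with a warning;
  gene order is fixed by id before clustering so results are deterministic.

Untestable profile cells are imputed as log2 fold change 0 and flagged
(`profile_matrix()`), keeping the matrix complete for clustering.

## The synthetic-data generator

All validation runs on generated data with planted truth (`sim_config()` and
the `gen_*` functions); raw Cq tables of the motivating experiments are not
public, so no test claims to reproduce their gene-level results. Defaults
encode the study-like conditions used throughout the tests: 100 genes per
species, 3 control + 3 cold replicates, 9 planted conserved ortholog pairs
at log2 effect 4 against log-scale noise sd 0.3, a 10-genotype REC screen
with the tolerant genotype at 31% REC versus ≥ 39% for the rest, and Cq
noise sd 0.2 cycles.

Design choices worth knowing:

* Expression is generated on the log2 scale (baseline + effect + Gaussian
  noise) and exponentiated, making planted fold changes exact in
  expectation. Emitted values are already normalized; no normalization step
  is modeled.
* Each species' top quartile is filled by *true responders*: the conserved
  pairs plus species-specific upregulated genes whose orthologs are, by
  construction, not co-upregulated. This mirrors the biology the screen
  exploits — real top quartiles are dominated by genuine stress responders,
  and most responders are not conserved across species. Background ortholog
  pairs therefore always involve at least one non-responsive partner; if
  instead null–null ortholog pairs competed for top-quartile slots purely by
  noise, two such genes would co-occur in both top quartiles with
  probability ≈ 3% per pair and exact planted recovery would be impossible
  by construction rather than informative.
* Cq noise is Gaussian per gene well on the cycle scale. The reference gene
  is modeled as perfectly stable by default (`ref_cq_noise_sd = 0`),
  reflecting a validated reference; setting it positive adds a per-replicate
  term shared by all genes of a plate — the realistic common-mode structure
  of a shared reference well, which correlates per-gene quantification
  errors and is deliberately excluded from calibration checks.
* Background interaction edges carry a single low-scoring evidence channel
  (three independent channels at 0.1 would combine to 0.27 and defeat the
  0.15 threshold); module edges carry all selected channels.
* REC data are emitted as raw L1/L2 pairs so the REC formula itself is
  exercised, with measurement noise (default sd 2 percentage points) on the
  planted REC profile.

What the generator does **not** emulate: read-level RNA-seq sampling,
primer efficiencies different from 2, genotype-by-environment interactions
beyond a scalar tolerance ranking, batch structure between experimental
repetitions (an optional batch column is accepted and pooled), and the
dependency structure of a real interaction database. Passing tests therefore
demonstrate correctness of the algorithms under the stated generative model,
not recovery of any particular field result.

## Problem sizes and numerical choices in the test suite

The suite validates, among others: exact agreement of quartile ranking with
an independent position-counting oracle on 1000 random tied instances
(n ≤ 50); exact planted-ortholog recovery (precision = recall = 1) on
≥ 99/100 seeds at the default effect-to-noise ratio; Livak recovery of
planted effects within twice the true sampling SE for ≥ 95% of 200 panel
genes at n = 3, sd 0.2; type-I control of the ΔCq t-test and the correlation
test within [0.03, 0.07] at α = 0.05 over 2000 null genes; Ward merge
heights against a from-scratch Lance–Williams evaluation (n ≤ 6); and
ARI = 1 recovery of two planted profile clusters and three planted
correlation regimes. These sizes were chosen to make the stochastic checks
statistically decisive while keeping the default suite fast; all stochastic
tests run under fixed seeds.

## Known limitations

* GO terms are matched literally; no ontology-graph propagation, so a gene
  annotated only with a descendant of GO:0009409 scores 0 on the GO
  component.
* The quartile screen has no significance notion: with few genes the top
  quartile is occupied regardless of effect sizes, which is why candidate
  confirmation relies on the downstream qPCR stage.
* The 1–9 score is ordinal; differences of one point are not comparable
  across components.
* Correlation analysis at n = 3 replicates has essentially no power; the
  generator's correlation-regime checks use n = 6 for that reason, and real
  designs should too.
* The network stage assembles and filters edges but deliberately implements
  no community detection or layout; export to GraphML hands those to
  dedicated tools.
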