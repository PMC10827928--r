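---
title: "Methods: cross-disease proteomic concordance, enrichment, co-expression and stain quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-disease proteomic concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossproteo)
```

# The problem

Epilepsy and Alzheimer's disease (AD) show a bidirectional clinical
association, and proteomic studies of post-mortem brain tissue suggest they
share molecular changes. A natural way to quantify this is to take a table
of proteins significantly altered in one disease (here, an epilepsy
hippocampus differential proteome) and ask, protein by protein, whether
each is also altered in the other disease, and in which direction. The
comparison dataset is typically a meta-analytic resource in which each
protein carries a set of per-study reports ("significantly increased" or
"significantly decreased") rather than a single effect size. This package
implements that comparison end to end: identifier harmonization and
matching, directional-consistency scoring of the multi-study evidence,
concordance classification, overlap enrichment against curated protein
sets, co-expression network analysis linking abundance profiles to a
histological trait, and positive-pixel-count quantification of stained
sections.

# Identifier matching

Proteomic tables identify proteins by UniProt accession and/or gene symbol,
and the mapping between the two is many-to-many. A record pair is
considered the same protein if **either** identifier matches: accessions
are compared case-sensitively after trimming and stripping isoform
suffixes (`P12345-2` → `P12345`), gene symbols case-insensitively after
trimming. Empty fields never match. The relation is deliberately not
transitive; cross-table matching pairs each anchor record directly against
the comparison table (accession match preferred, then gene match, first
occurrence wins) and never chains through intermediates. No external
identifier-mapping service is consulted — synonym expansion would make the
counts irreproducible.

Duplicate keys within a table are collapsed keeping the most significant
record (smallest significance value, then largest |log2FC|, then first
occurrence).

# Directional consistency of multi-study evidence

For one protein with `n_up` "increased" and `n_down` "decreased" reports,
let `M = max(n_up, n_down)` and `m = min(n_up, n_down)`:

* `m = 0` — consistently altered; signed score `±M`.
* `m = 1` and `M > 5` — one discordant report is tolerated for strongly
  replicated proteins; call follows the majority, score `±M`.
* otherwise (ties included) — *inconsistent*, no score.

The score magnitude counts majority-direction reports only, so sign and
call can never disagree. The alternative reading (score = all reports,
`M + m`) would change the printed score but not any call; the
majority-count definition is used throughout. The tolerance threshold is
read strictly: minority exactly 1 *and* majority strictly greater than 5.

# Concordance classification

Each anchor protein is classified `same_up`, `same_down`, `opposite`,
`inconsistent_b` (matched, but the comparison evidence is inconsistent) or
`a_only` (unmatched). The categories partition the anchor table, so counts
always reconcile: `matched = same + opposite + inconsistent_b` and
`a_only = n_a − matched`. Reported percentages follow the printed-table
convention, rounding half-up to integer percent (e.g. 689/777 → 89%).
Proteins matching inconsistent evidence are kept as their own category
rather than dropped, precisely so the arithmetic stays auditable.

# Overlap enrichment and over-representation

Enrichment of an altered-protein set in a curated reference set (tau
interactors, lesion-enriched proteins, causative genes) is the one-sided
Fisher's exact test, i.e. the hypergeometric upper tail
\(p = \sum_{i \ge k} \binom{K}{i}\binom{N-K}{n-i}/\binom{N}{n}\),
computed with R's log-space `phyper`. The odds ratio uses the 2×2 table
with a Haldane 0.5 correction only when a cell is zero. The background
universe matters enormously and is therefore a **required explicit
argument** — there is no silent default. Because published overlap
p-values often omit the background, `scan_universe()` reports the p-value
under each candidate background size so the reproducing universe can be
identified rather than asserted; on the canonical tau-interactor counts
(55/125 hits among 777 altered proteins) a 5311-protein background
reproduces the published-style p ≈ 1.06 × 10⁻¹⁵.

GO-style over-representation (`run_ora()`) consumes a pre-propagated
term→member annotation (GMT or two-column TSV; no ontology-graph
traversal), tests every term with ≥ 1 hit, adjusts with Benjamini–Hochberg
across all tested terms (terms with zero hits are excluded before
adjustment, which changes `m` and is noted in the output), and filters at
q < 0.05 with an optional top-10 report. BH was chosen over Storey's
q-value because it is parameter-free and exactly reproducible. Under a
uniform null the fraction of q < 0.05 terms stays at or below 0.05 (a
simulation in the test suite).

# Co-expression analysis

The co-expression machinery follows the weighted-network recipe: Pearson
correlation across samples (pairwise-complete; proteins with > 30%
missing values are dropped), soft-thresholded adjacency
(`|cor|^β` unsigned by default, `((1+cor)/2)^β` signed), topological
overlap
\(TOM_{ij} = (\sum_{u \ne i,j} a_{iu}a_{uj} + a_{ij}) / (\min(k_i,k_j) + 1 - a_{ij})\),
average-linkage clustering of `1 − TOM`, and module eigenproteins (first
principal component of the row-standardized member submatrix,
sign-anchored to the module mean profile).

**Soft threshold.** For each candidate power the connectivities
`k_i = Σ_j a_ij` are binned into ten equal-width bins and
`log10 p(k)` is regressed on `log10 k`; the fit index is
`−sign(slope)·R²`, positive for the decreasing degree distributions that
characterize approximate scale-free topology. The chosen power is the
smallest reaching the target (default R² = 0.8, the conventional cut, at
which the reference analysis selected power 4 — the package's default
power); if no candidate reaches it the maximizing power is used with a
warning. Equal-width binning is used because equal-occupancy bins make
p(k) constant by construction and cannot measure the fit.

**Module detection.** The published dynamic hybrid tree cut is
deliberately simplified: a fixed-height cut at 0.995 of the dendrogram
height, clusters below `min_module_size` (default 20) unassigned (label
0), then iterative merging of modules whose eigenproteins correlate above
`1 − merge_cut_height` (default 0.15), and renumbering by descending size.
This keeps the algorithm small, deterministic and testable; the fidelity
target is parameter *recovery* on planted data, not label-for-label
replication of any published module set. The whole matrix is treated as a
single block.

**Trait correlation.** Pearson r per profile with the Student-t two-sided
p-value on `n − 2` degrees of freedom, reported with R². Module-level GO
annotation reuses `run_ora()` with a minimum-hit filter (k ≥ 5 at FDR < 5%
is the conventional reporting cut).

# Stain quantification

`classify_pixel()` implements hue/saturation/intensity positive-pixel
classification: intensity `(R+G+B)/3`, saturation `1 − 3·min(R,G,B)/(R+G+B)`,
hue from the standard geometric formula on the `[0,1)` circle. A pixel is
a stain-positive candidate when its circular hue distance to the
configured center is within the width and saturation is at least the
threshold; candidates are binned into strong/medium/weak intensity
classes, and candidates above the weak-positive ceiling plus all
non-candidates are negative. Achromatic pixels (hue undefined, including
black, where saturation is also undefined) are negative by convention.
The shipped defaults encode the two study-stated modifications —
saturation threshold 0 and weak-positive intensity ceiling 80 — while the
remaining thresholds (hue center 0.05, width 0.15, strong/medium bounds
60/65) have no published values and are clearly non-canonical placeholders
suitable for DAB-brown on hematoxylin-blue. Results on real slides
therefore depend on a user-supplied configuration and are not
bit-reproducible from defaults.

Percent positive area is computed per ROI (e.g. hippocampal CA1, CA2, CA3)
and averaged unweighted across ROIs per case. Group comparison reports the
fold change of means and a two-sided Welch t-test by default (the
reference analysis does not name its test; borderline parametric p-values
suggest a t-type test), with Mann–Whitney as an alternative.

# Synthetic data: what it emulates and what it does not

All tests and the acceptance analysis run on generated data with known
ground truth:

* `gen_disease_tables()` plants exact overlap and direction-concordance
  fractions; effect sizes are `±Uniform(0.3, 2)` log2FC, realistic in
  magnitude, with only the sign consumed downstream.
* `gen_study_reports()` plants consistency classes by construction
  (unanimous, one-tolerated-exception, or rule-violating vectors).
* `gen_expression()` draws each module from a shared latent profile:
  member = `√w·latent + √(1−w)·σ·ε`, giving expected within-module
  correlation `w` for σ = 1 and exactly 1 in the noiseless limit; the
  trait is `ρ·latent + √(1−ρ²)·ε`. Defaults for the recovery fixtures are
  two modules of 30 proteins, 50 samples, `w = 0.8`, `ρ = 0.9` — a
  desk-scale stand-in for a ~3000-protein, ~20-sample cohort matrix.
* `gen_stain_image()` paints an exact pixel count in a flat positive
  color, optionally with RGB jitter truncated at ±6 so classification is
  provably unchanged; planted percent-positive values are therefore exact.
* `simulate_cross_disease_study()` composes all of the above into a
  synthetic supplement-scale study whose planted structure equals the
  published study conditions (777 anchor proteins, 4743 comparison
  proteins with multi-study evidence, category split 251/89/216/133,
  reference-set overlaps 9 of 45, 55/125, 161/511, 40/300, 41/192, 13/54,
  universe 5311). A small fraction of pairs match only via gene symbol and
  a few records carry no gene symbol, so the dual-identifier rule is
  genuinely exercised. The causative-gene set size (45) is our choice of a
  realistic clinical-gene panel size; the published overlaps fix only the
  hit counts.

What passing these tests shows: the matching, scoring, classification,
enrichment, network and quantification machinery is correct on data whose
truth is known, at the scale of the real study. What it does not show:
agreement with any particular published supplementary table (those
require the original files as input — the pipeline accepts them via
`read_diff_table()`/`read_reference_set()` with an explicit column map and
sheet name), recovery under realistic missingness, batch structure, or
histology artifacts (folds, blur, counterstain gradients), which the
generators deliberately do not simulate. The published WGCNA outputs (14
modules and specific protein–trait correlations) are likewise not
reproducible here because the underlying per-sample matrix is not public.

# Numerical choices and degenerate inputs

* Hypergeometric tails via `phyper` (log-space); exact-enumeration oracles
  in the tests agree to relative error < 1e-10 for all backgrounds ≤ 200.
* Percentage reporting rounds half-up to integer percent.
* Ties in duplicate collapse break deterministically (significance, then
  |log2FC|, then file order).
* Constant proteins and proteins with > 30% missing samples are dropped
  with a warning before network analysis; constant profiles yield `NA`
  trait correlations with a warning; a constant trait is an error.
* Degenerate group comparisons (both groups constant) report the fold
  change with an undefined test rather than failing.
* All generators take one explicit seed, restore the caller's RNG state,
  and are byte-deterministic given (parameters, seed).

# Problem sizes

The test suite and acceptance analysis use desk-scale problems chosen to
exercise every code path at comfortable runtimes: the supplement-scale
scenario (777/4743/5311) for matching and annotation; 60 × 50 matrices
(20 seeds) for module recovery; 200 × 40 matrices for the soft-threshold
scan; 100 × 100 images for quantification; 500-replicate Monte-Carlo loops
for the FDR-control and fold-change-recovery checks.

# Known limitations

* Matching resolves many-to-many identifier ambiguity by accession
  priority and first occurrence; other dialects (e.g. best-score matching)
  could shift boundary counts by a few proteins, which is why the
  summaries always reconcile arithmetically and the record-level table is
  emitted for audit.
* The tree cut is a simplified fixed-height procedure, not the dynamic
  hybrid algorithm; block-wise decomposition is not implemented.
* Over-representation assumes pre-propagated annotations; no GO-graph
  redundancy trimming.
* Proprietary upstream-regulator databases and external PPI services are
  out of scope; the package only annotates against user-supplied lists.
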