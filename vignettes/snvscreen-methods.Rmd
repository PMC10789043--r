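---
title: "Methods: coupled single-cell genotyping and transcriptomics for base-editor screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled single-cell genotyping and transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis problem

Pooled base-editor screens read out perturbations through the guide RNA
(gRNA) carried by each cell, but a gRNA is a fallible proxy for the edit it
was meant to install: cells may be unedited, heterozygously edited, or carry
bystander edits. snvscreen implements the computational side of a design
that removes this ambiguity by coupling targeted single-cell DNA genotyping
with single-cell transcriptomics through *transcribed clone barcodes*: every
transduced parent cell is tagged by a unique combination of a gRNA-embedded
barcode (iBAR) and an independent barcode in the puromycin-resistance
transcript (puroR). All daughter cells of one parent — a *barcode group* —
share this combination, so genotypes called robustly on the DNA modality can
be transferred to the transcriptomes of sister cells measured on the RNA
modality.

The package covers five analysis stages, plus a synthetic-data generator
with full ground truth so each stage is testable at desk scale:

1. **Barcode assignment** from UMI counts (`fit_count_mixture()`,
   `assignment_thresholds()`, `assign_features()`, `co_assign()`).
2. **Consensus genotyping** over barcode groups
   (`map_puror_to_grna_ibar()`, `form_barcode_groups()`,
   `filter_edit_types()`, `remove_recurrent_artifacts()`,
   `call_consensus()`, `assign_consequence()`).
3. **Transcriptome analysis** (`qc_filter()`, `de_auc()`,
   `select_features_and_embed()`, `cluster_and_merge()`,
   `diffusion_score()`, `classify_barcodes()`, `lof_group_de()`,
   `barcode_de_correlation()`, `sof_gene_signature()`).
4. **Linkage and evaluation** (`link_rna_to_genotype()`,
   `transfer_labels()`, `filter_lone_barcode_cells()`,
   `evaluate_classification()`, `summarize_linkage()`,
   `concordance_summary()`, `compare_to_prediction()`).
5. **Orchestration** (`run_pipeline()`), readers and writers for
   MatrixMarket count directories, per-cell variant TSVs and a per-group
   VCF.

# Barcode assignment: a three-component skew-normal mixture

UMI counts for one barcode class (gRNA, iBAR or puroR), pooled over all
cells and features, mix genuine ("signal") molecules with ambient
background. We model the natural log of all counts strictly above a floor
(`min_count = 2`) as a three-component skew-normal mixture: one ambient
component plus two signal components, the latter allowing the empirically
bimodal distribution of signal counts. The ambient component is identified
as the one with the smallest fitted location.

Two count thresholds are derived from the posterior probability of the
ambient component evaluated on the integer count grid: the *lower*
threshold is the largest count that is still ambient with probability at
least 0.9, and the *upper* threshold is the count past which the ambient
posterior stays at or below 0.1. A feature is called in a cell iff its
count exceeds the upper threshold while no other feature of the class
exceeds the lower threshold; requiring a unique call removes most doublets,
which carry two gRNAs.

Numerical choices:

* **EM with closed E-step, numerical M-step.** Component responsibilities
  are exact; per-component weighted likelihood is maximized over
  (location, log scale, slant) by bounded Nelder-Mead started from the
  current parameters, which keeps the EM objective non-decreasing. Slant is
  bounded at |alpha| <= 10 and scale floored at 0.08 to keep components
  identifiable on discrete data.
* **Continuity correction.** Counts are integers; fitting log counts
  directly lets a component collapse onto a single count atom. Each atom at
  count c <= 50 is therefore spread deterministically over five quadrature
  points in its rounding interval. This also makes the fit cost scale with
  the number of *distinct* counts rather than cells.
* **Initialization.** Three deterministic starts (k-means on all log
  counts; k-means on the distinct log counts, which finds minority signal
  modes under a dominant ambient cluster; one component on the low-count
  bulk with two splitting the high tail) plus seeded jittered restarts.
  Among converged candidates we prefer, by likelihood, those in which the
  smallest-location component actually carries most of the mass below the
  median count — the ambient role the model asserts; a fit in which two
  components share the ambient mode and one spans both signal modes has the
  right likelihood but the wrong semantics for thresholding.
* **Threshold grid.** The posterior is scanned on integers up to the
  largest observed count; for non-monotone posteriors the most conservative
  upper threshold (after the last up-crossing) is preferred, falling back to
  the first down-crossing with a warning when a heavy ambient tail regains
  dominance at extreme counts.

**Known limit.** When the data contain *no* ambient cluster (possible in
simulation with ambient weight zero), a three-component model must still
place its ambient component somewhere, typically on the lower signal mode.
`assignment_thresholds()` errors when the posterior never reaches the upper
level; `run_pipeline()` additionally falls back to the degenerate pair
`t_lo = t_hi = min_count` when the fitted upper threshold would exclude the
bulk of counts. Assignment *accuracy* is unaffected (an ambient-free cell
has nonzero counts only for its own barcodes) but coverage in that regime
can be partial, which the stage counts report honestly.

# Consensus genotyping over barcode groups

Single-cell genotyping of the triploid line is noisy: alleles drop out
during amplification (around 10% per allele) and spurious heterozygous
calls appear. Genotypes are therefore called per barcode group:

* puroR barcodes are mapped to gRNA + iBAR combinations when they co-occur
  with exactly one combination in at least 2 cells; groups pool cells that
  share the combination, attaching cells with only one called key through
  the mapping and excluding cells whose keys conflict.
* Per-cell variants are restricted to the base editor's substitution
  classes (`C>T` and `G>A` on the forward strand, configurable) and
  variants present in more than 10% of barcode groups are removed as
  recurrent artifacts.
* In a group of n >= 3 cells, a variant is called when carried by at least
  2 cells comprising at least 50% of the group, at the dosage shared by a
  strict majority of carriers (tie: uncallable). A group is wild type when
  no position is mutated in more than 1 cell (0 for groups under 10 cells).
  Variants supported by >= 2 cells but under 50% of the group make it
  uncallable. The group-size denominator is all cells of the group, and
  singleton stray calls are ignored for edited groups but break the
  wild-type rule.
* The functional consequence of a genotype is the most severe class among
  its homozygous (dosage = ploidy) variants, ranked stop/start-lost >
  splice > missense > promoter/intron > synonymous; heterozygous-only
  genotypes are assigned no consequence, since heterozygous edits are not
  expected to produce strong phenotypes in this design. Edits inside the
  configured promoter interval (defaults to the JAK1 promoter,
  chr1:64,964,978-64,967,543) are labelled `promoter` without requiring an
  annotation row.
* Predicted genotypes assume complete editing: every protospacer-strand
  cytosine within the editing window (default positions 4-8 of the
  protospacer, standard for this cytidine-editor class, configurable)
  edited on all alleles. Comparisons to called genotypes are reported at
  nucleotide level (exact homozygous edit set) and protein level (equal
  consequence), with discordance reasons (heterozygous / unedited /
  different consequence).

# Transcriptome analysis

Cells failing MAD-based quality control are removed (low outliers of log
total counts and log detected features, high outliers of mitochondrial
percentage; multiplier 3). Differential expression is nonparametric
throughout: for each gene the Wilcoxon rank-sum AUC — the probability that
a random cell of group A exceeds a random cell of group B, ties at one half
— with tie-corrected normal p-values and Benjamini-Hochberg adjustment
(significance at FDR 0.1). A nonparametric statistic is essential here
because cells of one barcode need not follow any single count distribution:
the clearest counterexample is the stochastic responders of
separation-of-function (SoF) variants.

Cells are embedded by PCA on the union of DE genes (each gRNA with at
least 10 cells tested against non-targeting cells) and a pathway gene list
(for synthetic screens, the generator's signature genes). Louvain
communities on the 10-nearest-neighbour graph are merged into exactly two
meta-clusters by average-linkage hierarchical clustering of community
centroids cut at k = 2; the meta-cluster with the higher percentage of
non-targeting cells is `notLoF`.

The *diffusion score* is the first non-trivial eigenvector of the
normalized diffusion operator built from a Gaussian kernel with per-cell
adaptive bandwidth (distance to the k-th neighbour, k = 10) on the kNN
graph, oriented so reference (non-targeting / wild-type) cells score low
and min-max scaled to [0, 1]. Numerical details: neighbours tied with the
k-th distance are all included (duplicated cells then receive identical
scores by construction); at up to 2,048 cells the eigenproblem is solved
densely, above that by deterministic subspace iteration started from the
embedding itself; a genuinely disconnected kNN graph is an error unless
`bridge_components = TRUE`, which restores dense-kernel behaviour by
adding the single minimum-distance edge between components — with strongly
separated expression states the score then approaches a two-block
indicator, which is the honest answer for such data.

Barcode groups are classified on their mean diffusion score against
order-statistic anchors: the low threshold is the 95th percentile of
wild-type barcode means, the high threshold the 5th percentile of
homozygous stop-codon barcode means; barcodes between the two are
`intermediate` — the SoF range. Sarle's bimodality coefficient of each
barcode's cell scores is reported alongside, since SoF barcodes are
expected to split into responding and non-responding cells. SoF-specific
genes are those significantly up versus full-impact missense and not down
versus benign missense (AUC > 0.45), or the mirror image (AUC < 0.55).

# Linkage and evaluation

RNA cells inherit the consensus genotype of the barcode group matching
their gRNA + iBAR combination (or mapped puroR). Label transfer between a
genotyped and a non-genotyped dataset centers both datasets per gene,
embeds them by joint PCA, and gives each query cell the coordinates of its
nearest reference cell and the modal label of its 10 nearest reference
neighbours (label ties to the nearer neighbour set, distance ties by cell
id). Per-gene centering plus joint PCA is a deliberate simplification of
published mutual-nearest-neighbour batch correction; the interface accepts
any precomputed joint embedding. Cells that are the only representative of
their barcode within a cluster are dropped as probable barcode
misassignments.

Genotype calls are evaluated against transcriptome phenotypes on the
barcodes called either wild type or a definite-LoF class (stop codon or
splice): true positives are stop/splice barcodes with a LoF phenotype,
false positives stop/splice with notLoF, false negatives WT with LoF.
Precision and recall are reported as exact fractions and nearest-integer
percentages (the package also keeps unrounded fractions wherever the
report rounds).

# The synthetic-data generator

`sim_config()` / `generate_screen()` emulate the statistical structure the
pipeline assumes, with defaults encoding the study conditions: 250 clone
barcodes (10% non-targeting), triploid genotypes, ~10 DNA cells and ~50 RNA
cells per barcode (zero-truncated Poisson; the target coverage for robust
genotyping and phenotyping), 10% per-allele dropout, 2% per-decoy-site
spurious heterozygous calls, three recurrent artifact sites planted in 20%
of groups, and 2,000 genes of which 100 form a response signature with
4-fold shifts (alternating direction) in the LoF state. Realized edit
classes are drawn per barcode (25% unedited, 20% het on one allele, 10% on
two, 45% homozygous); homozygous stop/splice sites are LoF, homozygous
missense sites split 40/20/40 into benign/SoF/LoF, and SoF cells respond
stochastically (probability 0.5) — responders express the wild-type state,
non-responders the LoF state. Barcode UMI counts come from the
three-component log-scale skew-normal mixture with ambient counts around 3
UMIs and signal modes around 25 and 100 UMIs, each cell receiving ambient
draws for a Binomial(n_barcodes, 0.02) subset of foreign barcodes.
Expression is negative binomial (dispersion 0.1) with log-normal baseline
means.

What the generator deliberately does not emulate: read-level errors and
PCR chemistry, indels and bystander edits outside the window, doublets
beyond an optional flag, ambient RNA in the expression matrix, batch
effects between modalities, and biological covariation among genes beyond
the planted signature. Passing tests therefore demonstrate correctness of
the algorithms under the assumed statistical structure, not robustness to
every artifact of real data.

# Problem sizes and reproducibility

The packaged test-suite runs the full default configuration (250 barcodes,
~2,500 DNA cells, ~12,500 RNA cells, 2,000 genes) once end to end, a
noise-free variant at two scales, and smaller screens (40-120 barcodes,
300-500 genes) for module-level checks; the acceptance script
(`scripts/acceptance.R`) regenerates everything it reports from scratch at
these same sizes. All stochastic steps take explicit seeds and are
bit-reproducible given them; identical configuration and seed give
byte-identical generator output.

# Known limitations

* The mixture model assumes a present, lowest-location ambient cluster;
  ambient-free data leave it partially unidentifiable (see above).
* The diffusion score compresses towards a two-block indicator when the
  expression states are strongly separated; intermediate-state resolution
  is best when states overlap, as in real data.
* Consensus dosage calling under dropout has a small error mode in very
  small groups (a homozygous variant observed at dosage 2 in most cells of
  a 3-cell group is called at dosage 2); the default 10-cell target
  coverage makes this rare.
* The toy transcript annotator maps each simulated site to one consequence
  class; real runs should supply an annotation table from a standard
  predictor.
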