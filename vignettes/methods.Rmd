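---
title: "Predicting histone modification sites from sequence and accessibility: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting histone modification sites from sequence and accessibility: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

ChIP-seq profiling of histone modifications is expensive enough that a full
landscape across many cell types and markers remains out of reach
experimentally. `epideep` predicts, for a 200-bp genomic window in a given
epigenome, the probability that the window is a modification site for each of
seven histone markers (H3K4me1, H3K4me3, H3K27me3, H3K36me3, H3K9me3, H3K9ac,
H3K27ac) simultaneously, by integrating two signals: the DNA sequence of the
surrounding 1-kb region, and the epigenome's chromatin accessibility
(DNase-seq fold enrichment) over the same region. Sequence carries regulatory
grammar (transcription-factor binding motifs) that is shared across cell
types; accessibility is what makes the prediction epigenome-specific, since
the genome itself is the same in every cell type.

# From peak files to training examples

**Site calling.** Each chromosome is scanned with non-overlapping 200-bp
windows anchored at coordinate 0 (window 200 bp, step 200 bp). A window is a
modification site for a marker when its total base overlap with the union of
that marker's ChIP-seq peaks is at least 100 bp. Epigenomes with fewer than
50,000 sites for any marker are discarded (`epigenome_passes_filter()`, a
strict less-than rule: exactly 50,000 passes).

**Labels.** The dataset for one epigenome is the union of all seven markers'
sites; each window carries a 7-long binary label vector, so a window can be a
site for several markers at once. This makes the evaluation's negative set
stringent: for marker $m$, the negatives are modification sites of *other*
markers, never random genome draws — random negatives would differ from
positives in GC content, gene distance and other confounds.

**Encoding.** Each 200-bp site is extended symmetrically to a 1000-bp region.
Sequence is one-hot encoded (rows A, C, G, T); `N` bases become all-zero
columns, preserving the binary-matrix property (the alternative, 0.25 in each
row, would blur the distinction between certainty and ignorance; the choice
is configurable in spirit but fixed here). Openness is a per-base vector:
positions inside a DNase peak receive the peak's fold-enrichment score,
positions covered by several overlapping peaks receive the maximum (fold
enrichment is a peak-level statistic; summing would double-count), and all
other positions — including positions beyond the chromosome ends of regions
extended past a boundary — are zero. Scores are used raw by default; a
`log1p` flag exists for heavy-tailed tracks. Regions that overhang chromosome
ends are kept and padded (`N` / zero openness) rather than dropped, so every
called site yields an example. Windows with partial `N` content are kept.

# The network

The model (`network_spec()`, `build_network()`) has three modules:

* a **DNA branch**: an initial convolution (`init_kernels` kernels of shape
  4 x 9 over the one-hot matrix), then two densely connected convolutional
  blocks in tandem, each followed by a transition convolution and a
  max-pooling layer of width 4;
* a **DNase branch** with the identical architecture except that the initial
  convolution is one-dimensional (1 x 9) over the openness vector;
* a **joint head**: the two branch outputs are flattened, concatenated and
  passed through a fully connected ReLU layer to seven parallel sigmoid
  outputs. Sigmoids rather than a softmax because marker events are not
  mutually exclusive — one window can carry several marks.

A dense block has three pre-activation layers (batch normalization, ReLU,
convolution of length 9 producing `growth` channels); each layer's output is
concatenated onto the running feature map, so the first two layers feed not
only the next layer but all later ones, and the block input itself reaches
the block output unchanged (the skip path). Dense connectivity combats
vanishing gradients and reuses features, which matters at the modest model
sizes used here.

Choices the architecture description leaves open, and what this package
does:

* **Pooling type** is max pooling — standard in this family of sequence
  models.
* **Pooling arithmetic**: with a 1000-bp input and two width-4 pools the
  second pool length (250) is not divisible by 4; pooling uses floor
  semantics and drops the trailing remainder positions. Construction fails
  only if a pool would reduce the length to zero.
* **Transition convolutions** are 1x1 (the usual dense-network transition),
  mapping the block's `init_kernels + 3 * growth` channels back to
  `init_kernels`.
* **Hidden sizes**: dense-block growth and the head width are not dictated
  by the architecture's published shape beyond the initial (128, 4, 9)
  convolution and (1, 4) pools, so they are explicit `network_spec()`
  parameters (defaults: growth 128, head 256) and are recorded on every
  model, keeping experiments reproducible.
* **Batch normalization** uses batch statistics during training and frozen
  running estimates (momentum 0.1) in evaluation state, so the evaluation
  forward pass is deterministic.

The ablations `dna_only` and `dnase_only` drop the other branch and feed the
remaining feature vector to the head; they are used to attribute performance
to sequence versus accessibility.

## Implementation

No neural-network framework is used: the layers, backpropagation and the
Adam optimizer are implemented in the package. A double-precision reference
implementation in R (`R/nn-ops.R`) defines the semantics and is verified
against finite differences in the test suite; a single-precision C++ engine
(`src/branch.cpp`) executes the same math for training and prediction and is
verified against the reference. The engine exists because CPU training is
memory-bandwidth bound: convolutions run per example on an L2-resident
padded tile, batchnorm+ReLU are fused single passes, and backward
reconstructs activations from the cached normalized values instead of
storing them. Training with the compiled engine is numerically within
single-precision rounding of the reference, not bitwise equal to it.

# Training and validation

The loss is multi-label binary cross entropy: the mean over all
`n x 7` entries of $-[p\log q + (1-p)\log(1-q)]$, with predictions clipped
to $[10^{-7}, 1-10^{-7}]$ so the loss stays finite. At the uninformative
prediction 0.5 the loss is $\ln 2$ regardless of the labels. Optimization is
Adam at its default parameters except the initial learning rate, 0.001.

Early stopping monitors the loss on an internal holdout (10% of the training
rows by default): training stops after `patience` consecutive epochs without
improvement, or at `max_epochs`, and the parameters from the best holdout
epoch are kept. Batch size, epoch budget and patience are configuration, not
claims about any reference implementation.

Validation is 5-fold cross-validation: all sites are partitioned at random
into five near-equal parts; each part is predicted by a model trained on the
other four, so every site is tested exactly once. The fold split is at the
window level. Adjacent 200-bp windows share 80% of their 1000-bp inputs, so
window-level splits can leak information between folds;
`make_folds_by_chrom()` is provided as a stricter alternative that holds out
whole chromosomes. Performance is one-vs-rest auROC (computed as the rank
statistic — the probability that a random positive outranks a random
negative, ties counted 1/2) and auPRC (average precision, the step summation
$\sum_t (R_t - R_{t-1}) P_t$ over decreasing distinct thresholds; the
interpolation convention matters for the value, so it is fixed and tested).
Markers whose one-vs-rest split is degenerate (no positives or no negatives)
are flagged rather than scored.

Two methods are compared across epigenomes with the one-sided
paired-sample exact sign test: for a marker, count the epigenomes where
method A beats method B (exact ties dropped, n reduced) and report
$P(X \ge \text{wins})$ under $X \sim \mathrm{Binomial}(n, 1/2)$.

**Cross-epigenome (collective) scoring.** To predict a novel epigenome with
no ChIP-seq data, each known epigenome's five fold models predict the region
(using the novel epigenome's own accessibility track as the DNase input),
the five probabilities are averaged per known epigenome, and the final score
is the unweighted mean over known epigenomes (`collective_predict()`).

# Motif extraction

First-layer DNA kernels act as motif scanners. For kernel $w$ and sequence
$s$, the extreme activation value (EAV) is the maximum of
$\mathrm{sum}(w \cdot x_j)$ over all padding-free length-9 windows $x_j$ of
$s$; a window is *activated* when its activation reaches $\alpha \cdot EAV$
with $\alpha = 0.9$. The kernel's position frequency matrix is the
element-wise mean of all activated one-hot windows across the scanned
sequences. Two decisions the activation rule leaves open:

* The threshold is applied per sequence (the EAV is a property of the
  sequence being scanned), not globally.
* Sequences whose EAV is not positive are skipped: against a non-positive
  maximum, the $\ge \alpha \cdot EAV$ rule would perversely admit the
  *weakest* windows, so only positively activating evidence shapes a motif.

Kernels with fewer than `min_activations` (default 10) activated windows are
dropped as degenerate. Motifs are exported in MEME minimal format for
downstream comparison against motif databases with TomTom-style tools; the
q-value threshold used in such comparisons belongs to that external step.

# Variant scoring

For a SNP, the 1000-bp window centred on the variant position (the SNP sits
at 0-based offset 500) is predicted twice — once with the reference base and
once with the alternate — and the functional implication score is
$\Delta p = |p^{alt} - p^{ref}|$ for the marker of interest. The same
openness vector is used for both alleles: the substitution edits the
sequence, not the accessibility assay. Scoring uses the five
cross-validation fold models of the target epigenome averaged, mirroring the
inner level of collective scoring. Only single-nucleotide substitutions are
scored; the reference allele must match the genome, and a mismatch is a
hard error naming the offending variant.

Control sets are built by distance matching: for each positive SNP, the
not-yet-used candidate on the same chromosome whose distance is nearest the
target (500, 1000, 1500, 2000 or 2500 bp) and within a tolerance (default
±250 bp, since "about d bp away" needs an operational definition) is
selected, in positive order and without replacement; positives with no
admissible candidate are dropped from both sets so the sets stay equal-sized.
Positive and control scores are compared with a one-sided Wilcoxon rank-sum
test (alternative: positives greater), computed by exhaustive enumeration of
rank assignments for small samples (min size ≤ 10 and total ≤ 20, average
ranks for ties) and by a tie-corrected normal approximation with continuity
correction otherwise. The exact branch uses the standard convention
$P(W \ge W_{obs})$; note that for fully tied toy inputs this tail includes
the large point mass at the observed value (e.g. two identical 3-element
samples give 14/20 = 0.7, not 0.5).

# The synthetic data generator

`simulate_epigenome()` produces a complete fixture in exactly the formats
the real pipeline consumes: a FASTA genome, seven narrowPeak files, a DNase
narrowPeak track with fold enrichment, variant TSVs and a truth table. It
emulates the statistical structure the predictor assumes:

* i.i.d. background sequence at GC fraction 0.41 (human-like);
* for each marker, `sites_per_marker` disjoint grid-aligned 200-bp windows,
  each receiving a sample from that marker's 9-bp position frequency matrix
  written at the window centre. The built-in PFMs are information-rich
  (consensus probability 0.85, centre column 0.97, so the centre is the
  unambiguous maximum-information position) around seven distinct consensus
  9-mers;
* one emitted peak per planted window (peak length 200, the window itself,
  so window calling recovers the truth table exactly and one-vs-rest labels
  are clean);
* a DNase peak of fold enrichment 5 over every true site, identical for all
  markers — accessibility alone therefore cannot distinguish among markers,
  which is what makes the DNase-only ablation a chance-level control on
  synthetic data;
* positive variants substituting the base at a planted motif's
  maximum-information column with the least likely base under that column,
  and controls substituting a background base 500 bp away (or the mirrored
  position when the offset leaves the chromosome or lands in a planted
  window).

What the generator does **not** emulate: repeat structure, nucleosome
positioning, CpG islands, GC heterogeneity, read-level noise, correlated
marker co-occurrence, or realistic accessibility profiles. Passing tests on
this generator demonstrate that the dataset construction, network, training
protocol, motif extraction and variant scoring are implemented correctly and
can recover strong planted signal end to end; they say nothing about
prediction accuracy on real epigenomes, which depends on signal the
generator does not model.

An `overlap` between marker loci is deliberately absent by default; the
multi-label path (one window, several markers) is exercised directly by
`build_site_table()` tests instead.

# Problem sizes and numerical choices

The test suite trains the full protocol once at study scale — 7 markers x
2,000 sites (14,000 windows), 5-fold cross-validation of a reduced network
(16 initial kernels, dense growth 2, head width 64, batch 64, at most 3
epochs with patience 2) — and reuses that fit for the motif-recovery and
variant-discrimination checks; unit tests use miniature specs (sequence
length 32-64). `scripts/acceptance.R` runs the same pipeline at 700 sites
per marker over a 4 x 400-kb genome, with a 2-fold ablation comparison on
half the sites. These sizes are the package's own choices for routine runs;
all of them scale up through configuration.

Other numerics: probability clipping at $10^{-7}$ in the loss; batchnorm
variance floor at 0 and $\epsilon = 10^{-5}$; convolutions are
He-initialized scaled by `init_gain` (default 0.03) — every convolution
feeds a batch normalization, which makes the initial weight magnitude
redundant, and a small initial norm lets Adam rotate kernel directions
quickly, which both speeds convergence (holdout loss roughly 3x lower at
the test-suite problem size) and drives first-layer kernels toward clean
full-length motifs rather than fragments locked to their random initial
alignment; the feedforward head uses plain He initialization; pooling ties
broken toward the first position; fold sizes differ by at most one with remainders assigned to the
lowest-numbered folds; every randomized step (genome, planting, fold split,
initialization, holdout split, batch order) is seeded, and a cross-validation
run derives one seed per fold from the master seed.

# Known limitations

* Training runs on one CPU; the engine is tuned for memory bandwidth, not
  for the 7.6M-example scale of full epigenome compendia.
* Window-level fold assignment (the default, matching the validation
  protocol) can leak between adjacent windows; use `make_folds_by_chrom()`
  when that matters.
* The rank-sum test's exact branch is limited to 20 pooled observations;
  beyond that the normal approximation is used.
* Motif extraction reports kernels as they are; it does not merge duplicate
  kernels or align shifted versions of the same motif.
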