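---
title: "Predicting and interpreting m6A sites with m6aconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting and interpreting m6A sites with m6aconv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

N6-methyladenosine (m6A) is the most abundant internal mRNA modification
in eukaryotes. It is deposited almost exclusively at adenosines in the
degenerate DRACH context (D ∈ {A, G, U}, R ∈ {A, G}, then A, C,
H ∈ {A, C, U}), but only a minority of DRACH adenosines are methylated, so
the flanking sequence carries the discriminative signal.
Single-nucleotide-resolution technologies (miCLIP, m6A-REF-seq,
MAZTER-seq) provide per-adenosine positive labels; `m6aconv` builds
balanced benchmark datasets from such site lists, trains a small
convolutional classifier on fixed-length A-centered windows, and — its
main emphasis — interprets what the trained network has learned, through
two complementary routes: *model-based* interpretation (first-layer filter
motifs, activated amounts, virtual-pruning impact scores) and
*propagation-based* interpretation (in-silico mutagenesis and
input-gradient attribution maps).

## Dataset construction

Starting from mature-mRNA sequences and 0-based positive site offsets:

1. every candidate window must be fully inside the transcript, centered
   on an `A`, and have a DRACH central 5-mer; windows overrunning a
   transcript end are **rejected**, not padded — padding would force an
   `N`-encoding convention on the model for a small gain, and rejections
   are logged with reason codes instead;
2. negatives are adenosines in DRACH context at least 200 nt (the default
   `min_distance`) from every positive on the same transcript, so
   negative and positive 201-nt windows can never overlap; all eligible
   candidates are enumerated first and then subsampled uniformly to the
   positive count, giving a balanced set;
3. redundancy is removed at 80% identity. Because all windows have equal
   length and a fixed central anchor, identity is defined as the ungapped
   positionwise match fraction and clustering is greedy in input order
   (a window is dropped iff it matches any already-retained window at or
   above the threshold). This is deterministic, dependency-free and
   conservative for anchored windows; it replaces alignment-based
   clustering tools that solve the general, unanchored problem;
4. the pooled set (redundancy removal is applied to positives and
   negatives together, per condition) is split 9:1 into training and
   independent test sets, stratified by label and seeded.

Default window length is 201 nt (`flank = 100`); all flank lengths are
configurable.

## Encoding

Windows are encoded by ENAC (enhanced nucleic acid composition): a
2-nt sub-window slides with stride 1, and each placement contributes the
nucleotide frequency vector over the fixed channel order A, C, G, U, so a
length-L window becomes an (L−1) × 4 row-stochastic matrix with entries
in {0, ½, 1}. The phrase "length 2, sliding window 1" is read as
*sub-window length 2, stride 1* — the only reading that yields the
(L−1) × 4 shape. On A-centered windows the encoding is injective (the
known central base disambiguates the alternating-dinucleotide case), and
`enac_reconstruct()` inverts it; the test suite uses
reconstruct-and-compare as the injectivity check.

## The classifier

The network is `[conv → ReLU → maxpool → dropout] × k → flatten →
FC(ReLU, dropout) → single sigmoid unit`, trained with binary
cross-entropy and Adam. Convolution is 1-D along the window axis with 4
input channels and no padding ("valid"); pooling windows are
non-overlapping. The implementation is plain R matrix algebra (im2col +
BLAS matmul) with hand-derived backpropagation, which is also what makes
input-gradient attribution and virtual filter pruning direct to
implement. Backpropagation is verified against central finite differences
in the test suite.

Per-condition hyperparameters are configuration-driven. Three presets key
capacity to data volume:

* **small** (a few thousand windows): one block of 64 filters spanning 5
  encoded rows (6 nt), pool 4, dropout 0.2; FC 32, dropout 0.3; 20
  epochs.
* **medium** (tens of thousands): 64×5/pool 2 + 32×3/pool 2; FC 64; 30
  epochs.
* **large**: 64×7 + 64×5; FC 128 + 32; 40 epochs.

64 first-layer filters are kept in all presets because the first layer is
the unit of motif extraction.

Two optimisation details matter for small, all-positive-input networks.
First, the output layer is initialised at a small scale so initial
predictions start near 0.5; with a large-scale head, the first Adam
epoch spends itself violently compressing the spread of predictions and
can drive every ReLU unit of the FC layer into the dead regime — a state
that is absorbing, because pooled ReLU features are non-negative and a
dead unit receives no gradient. Second, FC biases are initialised
slightly positive (0.05) for the same reason. Both choices are standard
remedies for dying-ReLU collapse. Because Adam's scale-normalised steps
can still reach the absorbing all-dead state on unlucky seeds (and
gradient clipping cannot prevent it, for the same normalisation reason),
training additionally detects the state — zero variance of training-set
predictions after an epoch — and restarts from a deterministically
reseeded initialisation, at most three times; the analogue of `nstart`
in k-means. Together these make training robust across seeds.
Early stopping on a held-out validation fraction is available but off by
default. Cross-validation (`cross_validate()`) is stratified k-fold
(default k = 5) and selects the configuration with the best mean
validation AUC before retraining on all data; AUC is used because it is
threshold-free and the benchmark sets are balanced.

## Evaluation

Threshold metrics (Sen, Spe, Acc, MCC) follow the standard confusion
definitions with the classification threshold at 0.5 and ties called
positive. A zero denominator reports the metric as 0 with an explicit
`degenerate` flag rather than an error. AUC is computed by the midrank
Mann–Whitney identity (ties count ½) and AP as the step-wise area under
the precision–recall curve; both are tested against brute-force pairwise
and per-threshold oracles. `cross_condition_matrix()` applies every
condition-specific model to every condition's independent test set
(rows = predictors, columns = datasets).

## Interpretation

**Filter motifs.** For each first-layer filter, the activation threshold
is half of that filter's maximum activation *over the entire evaluated
set* (a per-sequence maximum would let every sequence contribute and blur
rare motifs); placements strictly above threshold contribute their
covered subsequence. A filter spanning `k` encoded rows covers
`k + 1` nucleotides at ENAC window 2, so motifs and PFMs live in
nucleotide space, matching sequence-logo conventions. The PFM is the
column-wise nucleotide frequency over activated subsequences; the
*activated amount* is the mean above-threshold placement count per
sequence; the *impact score* nullifies the filter (weights and bias to
zero) and takes the mean absolute change in predicted probability —
absolute rather than signed, since a filter whose removal moves
predictions in either direction is equally influential. AUC drop under
nullification is computed alongside as a secondary statistic. PFMs can be
compared by Pearson correlation of flattened matrices (with best-offset
alignment for unequal lengths), clustered hierarchically under distance
1 − PCC with average linkage, and exported in minimal MEME format for
TOMTOM-style comparison workflows.

**Attribution maps.** In-silico mutagenesis substitutes each position by
the three alternative nucleotides, re-encodes, re-scores and records
*mutant minus original* (so a harmful substitution is negative); entries
at the observed nucleotide are structurally zero. Gradient attribution
differentiates the sigmoid output (the logit is available via a flag)
with respect to the encoded (L−1) × 4 input and projects back to 4 × l by
summing the gradients of the encoded rows covering each nucleotide
position, scaled by 1/window. On a linear scorer over ENAC features both
methods admit closed forms, and the test suite asserts exact agreement —
including the identity that logit-scale ISM equals the re-centered
projected gradient, since ENAC is affine in a single substitution.
Global position profiles average maps over samples and reduce channels by
the sum of absolute values; the filter-based analogue counts activated
subsequences covering each position. Profile pairs are compared by cosine
similarity.

## The synthetic generator

`generate_dataset()` emulates balanced benchmark sets with known ground
truth: both classes receive a central 5-mer drawn uniformly from the 18
DRACH 5-mers, so the classes differ *only* by motifs planted in the
positive flanks — any learned signal is attributable to the planted
motifs, which is what makes motif-recovery and attribution-localisation
tests meaningful. Background composition is uniform by default and
configurable. `generate_transcripts()` plants positive sites in random
transcripts to exercise the dataset pipeline end to end. The generator
does not emulate transcriptome composition biases, secondary structure,
or experimental noise in site calls; passing tests demonstrate that the
machinery is correct and can recover planted signal, not that any
particular biological performance level will be reached on real data.

The reference experiment used by the tests and the acceptance script:
2000 positives + 2000 negatives of length 101 nt, one-hot GGACU planted
uniformly in the 5′ flank of positives at insertion rate 0.9, 9:1 split,
small preset, at most 20 epochs. These sizes train in about a minute on
one CPU core while leaving the planted signal close to its theoretical
ceiling (with rate 0.9 and chance background occurrences, the Bayes AUC
of a presence detector is about 0.93). The transfer experiment uses three
conditions of 1000 + 1000 windows — two sharing GGACU, one carrying UCCGG
— mirroring the observation that model transferability follows data
similarity. In the motif-recovery check, column-shuffled control motifs
that happen to reproduce the original matrix (the identity permutation,
or permutations swapping identical columns) are redrawn; otherwise the
null distribution would contain the true motif itself.

## Numerical choices and degenerate inputs

* Activation ties at the threshold are excluded (strict `>`); prediction
  ties at 0.5 are called positive.
* Dropout uses inverted scaling, so inference needs no rescaling.
* Max-pool backpropagation routes gradients to the first maximal element
  within each window.
* BCE probabilities are clamped at 1e−12 before the log.
* A uniform PFM has zero variance and therefore an undefined PCC; such
  filters are reported (support 0) but excluded from clustering with a
  warning.
* Empty subsequence sets yield uniform PFMs with support 0 rather than
  errors, so dead filters remain visible in reports.

## Known limitations

* Sequence-only model: no secondary structure, conservation or
  transcript-level covariates.
* The identity measure assumes equal-length anchored windows; it is not a
  general homology reduction.
* Training is CPU-bound pure R; it is sized for benchmark-scale datasets
  (10^3–10^5 windows), not genome-scale scans.
* Genome-to-transcript coordinate mapping is out of scope; callers supply
  mature-mRNA sequences and transcript-relative offsets.
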