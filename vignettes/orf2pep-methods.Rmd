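---
title: "Methods: gene calling and functional peptide screening with orf2pep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene calling and functional peptide screening with orf2pep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

orf2pep mines candidate therapeutic peptides from prokaryotic or
metagenomic DNA in two sequential stages: a coding-potential classifier
over candidate open reading frames (ORFs), and a functional-peptide
classifier over the translated products, followed by physicochemical
profiling. This vignette explains the models, their assumptions, the
tunable parameters, and the design decisions taken where the design was
genuinely open.

## Stage one: ORF enumeration and coding classification

### Candidate enumeration

`scan_orfs()` examines all six reading frames of both strands. Within each
frame, every stop-to-stop segment is inspected: if it contains an in-frame
start codon (ATG, CTG, GTG or TTG — the canonical bacterial initiators),
the segment yields a candidate from its 5'-most start to the stop codon
inclusive (`all_starts = TRUE` instead emits one candidate per start).
Fragment edges receive the completeness taxonomy familiar from metagenomic
gene callers: a first segment with no start is `missing5`, a trailing
segment with a start but no stop is `missing3`, and a frame with neither is
`missing_both`. Candidates shorter than 60 bp (stop included — the spec
of "length" here is a convention; we include the stop) are discarded as
unreliable. The 30 bp window upstream of each start is retained because
bacterial translation-initiation signal (the ribosome-binding site) sits
within roughly 30 bp of the start codon; the window feeds the TIS score
and does not shift the ORF coordinates.

Internally all coordinates are 0-based half-open on the forward strand;
GFF3 output converts to 1-based inclusive and BED passes through unchanged.

### Feature encoding

Each candidate is standardized to 700 bp — shorter sequences are 3'-padded
with a neutral symbol that one-hot encodes to all zeros, longer ones keep
their 5'-most 700 bp, because the start-proximal region (initiation
context, early codons) carries the discriminative signal. The fused input
vector concatenates, in fixed order:

* the flattened 700 x 4 one-hot matrix (2,800 entries; N and pad rows are
  all-zero so they carry no base signal);
* monocodon usage (64): relative frequencies of non-overlapping in-frame
  codons. Frequencies rather than counts remove length confounding;
* dicodon usage (4,096): frequencies of overlapping in-frame codon pairs
  (step of one codon), the standard hexamer statistic of gene finders;
* a scalar TIS score: the log2-odds of the upstream window under a
  position weight matrix trained on the upstream windows of known coding
  starts (pseudocount 1 per cell, windows right-aligned to the start
  codon). The feature is configurable off (`pwm = NULL` scores 0), since
  its exact published form is not fully specified and the PWM is our
  declared formulation;
* ORF length capped at and normalized by 700 bp; GC content; and the four
  base frequencies, all computed over unambiguous bases only.

The total width is 6,967. `feature_blocks()` records the offsets, and
slicing the fused vector at those offsets recovers each block exactly —
a property the test suite asserts.

### The classifier

`build_gene_model()` assembles a 1-D convolutional stack over the fused
vector — conv(k=3) -> max-pool -> conv(k=3) -> max-pool -> dropout — whose
flattened output feeds a fully-connected stage, is reshaped into tokens,
passed through a multi-head self-attention encoder layer (8 heads,
post-norm residual blocks with a ReLU feed-forward), flattened again, and
projected
through a second fully-connected layer and a dropout(0.2) into a single
sigmoid unit: the probability that the candidate encodes protein. ReLU
activations follow each convolution (a standard choice; the reference
description is silent on conv activations). The flatten width is derived
from the configured input width at build time, never hard-coded.

The reshape between the fully-connected stage and the attention encoder is
not dictated by the architecture's description; we expose it as
`tokens x token_width` (default 8 x 32 compact, 32 x 128 paper preset) with
the constraint `tokens * token_width = fc1_out`.

Two presets exist. The `"paper"` preset carries the published widths
(64- and 200-filter convolutions, pool 2, 4,096-wide fully-connected
stage, 4,096 -> 128 projection). At a 6,967-wide input, pool size 2 leaves
a ~348,000-wide flatten, whose 4,096-wide dense layer would need about
1.4 billion parameters — that configuration documents the published
architecture but is not what we train. The `"compact"` preset (8/16
filters, pools 10/6, 256-wide encoder stage, 256 -> 64 projection, ~70k
parameters) is the desk-scale configuration used by the package's tests,
vignette and acceptance experiments; it preserves the topology exactly and
trains in tens of seconds on one CPU core.

Training minimizes binary cross-entropy with Adam (lr 0.001, batch 32).
Every epoch streams approximately stratified mini-batches in which the
minority class is resampled with replacement to parity. Inputs are
standardized per feature using training-set statistics stored on the model:
the fused vector mixes 0/1 indicators with millesimal-scale dicodon
frequencies, and optimization conditions far better on a common scale. All
randomness flows from `config$seed`, making runs bit-reproducible on a
given platform. The whole network and its backpropagation are implemented
in plain R matrix algebra inside the package; the test suite checks every
parameter's gradient against central finite differences.

### GC buckets, greedy resolution and evaluation

Genomes differ widely in GC content, and codon statistics shift with it,
so the package supports a library of ten parameter sets indexed by the
deciles of [0,1] (left-closed, last bucket right-closed;
`select_bucket()` routes a genome by its GC content, and
`train_gene_model(init = )` fine-tunes from the selected bucket's
parameters). How such buckets are populated is a user-level procedure:
`train_gc_buckets()` trains one model per supplied dataset.

Scored candidates are post-processed by `greedy_resolve()`: candidates
below the probability threshold (default 0.5) are dropped, the rest are
visited in order of decreasing probability (ties broken by longer ORF,
then smaller start, making the output deterministic), and each accepted
call discards every remaining candidate overlapping it by strictly more
than 60 bp on forward-strand coordinates — opposite-strand candidates
compete too, since only one gene is retained among overlapping
predictions. An exactly-60 bp overlap survives.

`evaluate_calls()` scores a call as a true positive when its stop
coordinate and strand match an annotated gene — the 3'-end-match criterion
standard in prokaryotic gene finding, which tolerates alternative start
choices.

## Stage two: peptide classification

### Tokenizer and embeddings

Peptides are tokenized over a 26-token vocabulary: the 20 standard
residues, `X` for unknown residues, and the five language-model specials
`[PAD]`, `[UNK]`, `[CLS]`, `[SEP]`, `[MASK]`. (A 26-token vocabulary with
only `[CLS]`/`[SEP]` named leaves three tokens unidentified; completing
the set with the standard specials is our choice.) Sequences become
`[CLS]` + residues + `[SEP]`, right-padded to `max_len` (default 100;
truncation keeps the first residues).

Embeddings come from a pluggable provider. `trainable_lookup` (default) is
a randomly initialized 26 x D table (D = 128 by default) trained jointly
with the classifier, so the package never requires downloaded weights.
`external_lm` loads a frozen per-token embedding table exported from any
protein language model, which is how a pretrained transformer slots in;
per-position contextual embeddings would enter at the same interface.

### Dual channels and head

Two parallel channels read the L x D embedding matrix:

* **CNN channel** — three stacked 1-D convolutions (kernel 3; 256, 128, 64
  filters) with ReLU, then *masked* global average pooling: positions whose
  receptive field (7 tokens after three kernel-3 layers) touches padding
  are excluded, so the channel output is invariant to appended `[PAD]`s.
* **BiLSTM channel** — a bidirectional LSTM (hidden width 64 per
  direction, unstated in the reference and chosen as a typical width). The
  output concatenates the forward direction's hidden state at the last
  *real* token (a masked carry keeps the state across padding) with the
  backward direction's final state.

The channel outputs are concatenated, batch-normalized (running statistics
frozen at inference, the standard convention), and passed through a
three-layer MLP (widths 64, 32, 1) ending in a sigmoid. One model instance
is trained per task (ACP or AMP); the task is metadata on the model.

### Training regime

The objective is binary cross-entropy. The published regime names the
Adafactor optimizer; no R implementation exists, so the package uses Adam
at the configured learning rate — an explicitly permitted adaptive
fallback, recorded in the model's training log. The configured default
learning rate, 2e-5, is a fine-tuning rate appropriate when embeddings
come from a pretrained language model; training the lookup table from
scratch needs a larger step, and the package's own experiments pass
`lr = 1e-3`. Batch size 4, at most 20 epochs, early stopping on validation
loss with patience 3 (patience unstated in the reference; 3 is our
default), an internal stratified 8:2 train/validation split under seed
702, minority-class oversampling to parity per epoch, and per-epoch
validation accuracy, F1 and MCC recorded. The best-validation-loss
parameters are restored at the end.

## Physicochemical profiling

`profile_peptides()` computes eight per-peptide properties: GRAVY (mean
Kyte–Doolittle hydropathy), molecular weight (average residue masses plus
one water), aromaticity (F/W/Y fraction), the Guruprasad instability index
((10/L) times the sum of dipeptide instability weights), isoelectric point,
net charge at pH 7, Boman interaction index (mean per-residue value of the
Boman 2003 scale) and tryptophan content. The underlying scales are not
named in the reference description; the package uses the canonical
defaults above and exposes them via `physchem_scales()`. Charge follows
the Henderson–Hasselbalch sum over termini and D/E/C/Y/H/K/R side chains
under a selectable pKa set (EMBOSS default, Bjellqvist alternative — pI is
pKa-set dependent); pI is found by bisection on (0, 14) to |charge| <
1e-4. Peptides containing `X` have undefined table-based properties and
are dropped with a warning (or rejected), never silently imputed.
`normalize_properties()` min-max scales each property column to [0, 1]
(constant columns map to 0 with a warning) and retains the ranges so raw
values are recoverable; `autoplot()` renders the heatmap view and
`plot_property_scatter()` the GRAVY-versus-charge view colored by Boman
index.

## The simulators and what passing tests mean

`simulate_genome()` writes an iid background at a controllable GC content
and embeds non-overlapping genes — ATG, interior codons drawn from a
biased codon table, a uniform stop — on either strand (reverse-complement
insertion). The codon table is drawn once per simulation from a Dirichlet
centered on a fixed asymmetric reference (geometric weights over the 61
sense codons); `codon_bias_strength` scales the concentration, so larger
values plant a sharper codon-usage contrast — exactly the signal the
monocodon/dicodon features exploit. Supplying a previous simulation's
table yields a fresh genome from the same generative process, which the
package uses as a leakage-free held-out set. `simulate_peptides()` draws
negative residues uniformly and positive residues from a composition
reweighted by the enrichment map (default K, R x4 and W, F x3 — the
cationic/aromatic tendency of anticancer and antimicrobial peptides, with
multipliers chosen to give a clearly separable but not trivial class
structure).

What the simulators do *not* emulate: operons, overlapping genes, genuine
ribosome-binding motifs, GC-skewed codon tables tied to background GC,
realistic peptide length/composition distributions, or homology structure
between training and test items. Consequently, passing the learning tests
demonstrates that the models, features and training loops work as designed
— not that the published accuracies transfer to real genomes or curated
peptide benchmarks, which depend on the original curated datasets and
pretrained weights and are out of scope here.

## Held-out evaluation and chance controls

The gene-stage learning experiment trains on the candidates of one 50 kb,
40-gene genome (negatives downsampled to five per positive, keeping short
spurious ORFs and reverse-strand shadows represented) and evaluates on a
balanced candidate set from a second genome simulated with the same codon
table — 200 independent unseen loci. With only 40 genes per genome, a
same-genome split would leave ~12 test positives, too few for a stable
estimate.

The shuffled-label control is trained on the *parity-balanced* dataset:
permuting labels on an imbalanced set makes the shuffled "positive" class
predominantly background, so the model learns a systematically inverted
decision rule — an imbalance artifact, not the chance behavior the control
is meant to demonstrate. Chance accuracy is reported as the mean over
several independent permutations because a single permutation run has
substantial variance even on 200 evaluation points (predictions of a
noise-fit model correlate across candidates).

## Numerical choices and degenerate inputs

* Frequency blocks with no valid codon (or pair) are all-zero rather than
  NaN; all-N sequences yield zero GC/base composition with a warning.
* Codons containing N are excluded from usage denominators and translate
  to X; translation uses NCBI table 11 (the bacterial/archaeal code —
  unstated in the reference, implied by the prokaryotic scope), and
  alternative starts render M only at position 1 of a called gene.
* Max-pool ties keep the 5'-most position; greedy ties break by length
  then coordinate; both keep outputs deterministic.
* The instability index follows the (10/L)-scaled Guruprasad sum.
* Adam is used for both stages (epsilon 1e-8, betas 0.9/0.999); BCE
  probabilities are clamped to [1e-12, 1 - 1e-12].
* Problem sizes in tests and the acceptance script (50 kb training
  genomes, 125 kb evaluation genomes, 1,000-peptide sets, compact model
  preset) are the package's desk-scale study conditions, chosen so a full
  run completes in minutes on a single CPU core.

## Known limitations

* The paper-preset architecture is documented but not trainable at desk
  scale; all empirical claims here use the compact preset.
* The TIS feature is a PWM log-odds stand-in for an unavailable published
  definition, and is configurable off.
* The external-embedding provider accepts per-token (not per-position
  contextual) tables; a true contextual language model would require an
  inference runtime this package deliberately avoids depending on.
* Circular chromosomes (wrap-around ORFs), eukaryotic splicing and
  Shine–Dalgarno discovery beyond the PWM are out of scope.
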