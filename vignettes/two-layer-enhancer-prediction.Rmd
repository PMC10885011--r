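---
title: "Two-layer enhancer prediction with a k-mer language model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-layer enhancer prediction with a k-mer language model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`enhancerlm` predicts, from raw fixed-length DNA sequence, whether a
fragment is an enhancer and — among enhancers — whether it is strong or
weak. This vignette is the package's own account of the method: the model
and its assumptions, the parameters that matter, what the synthetic data
generator does and does not emulate, the numerical choices, and the known
limitations.

## The two-stage model

### Stage 1: self-supervised k-mer language model

Sequences are tokenized into overlapping k-mers at stride 1; a length-$L$
sequence yields $L-k+1$ tokens. Overlap preserves every positional frame of
the sequence; a non-overlapping mode exists (`kmerize(..., stride = k)`) but
is off by default because it discards $1-1/k$ of the frames. The vocabulary
is corpus-derived (every k-mer observed in training data, sorted for
reproducible id assignment) plus three specials: `<pad>` for batching,
`<unk>` for unseen or N-containing k-mers, and `<bos>`, prepended during
language-model training so the first real k-mer has a prediction context.
A full $4^k$ enumeration is available (`build_vocabulary(..., full = TRUE)`)
for corpora too small to cover the alphabet.

The encoder is an embedding layer followed by three LSTM layers and an
affine decoder to next-token logits. Three stochastic regularizers act
during training only:

* whole-embedding dropout `p_embeddings` (default 0.001) zeroes a token's
  entire vector;
* component dropout `p_embeddings_dim` (default 0.001) zeroes individual
  entries of surviving vectors;
* DropConnect (default 0.4) zeroes individual elements of the input and
  recurrent gate weight matrices $W_i,W_f,W_o,U_i,U_f,U_o$, drawing one mask
  per minibatch that is shared by the forward and backward pass. The
  candidate weights $W_c, U_c$ are left unmasked, and the candidate
  activation $g=\tanh(W_c x + U_c h)$ carries no bias term.

All three use inverted-dropout scaling (survivors multiplied by $1/(1-p)$),
so evaluation mode can use the raw weights without any rescaling and an
untrained forward pass has the same expectation in both modes.

Training minimizes next-k-mer categorical cross-entropy with Adam
(learning rate $10^{-4}$, weight decay $10^{-2}$, batch size 64 — the tuned
defaults for this architecture at full scale; the weight decay is added to
the gradient, the common Adam-with-L2 formulation). A seeded 10% split of
the corpus is held out; training stops when the held-out loss fails to
improve for `patience` epochs (default 50) and the best-scoring parameters
are restored, so the final held-out loss never exceeds the initial one.
Back-propagation runs through the full token length of each sequence
(at most a few hundred tokens for benchmark-sized fragments), so no
truncation window is needed.

Two design points deserve a note. First, the decoder is a plain affine map
from the 256-dimensional hidden state to vocabulary logits; embedding-weight
tying is not used because the embedding width (400) and hidden width (256)
differ by design. Second, `encode()` returns the *final LSTM layer's hidden
state at every k-mer position*, in evaluation mode. The hidden states — not
the raw embeddings — are what the classifier consumes, since they carry the
left-context of each position.

### Stage 2: CNN + attention classifier head

The head operates on the frozen encoder's output, one matrix of
`positions × hidden` per sequence:

1. **Convolution** — a valid (no padding) 1-D cross-correlation with
   `n_filters` kernels of width `kernel_size` (defaults 30 and 3), then
   ReLU. With 200 bp sequences and $k=2$ this maps 199 positions to 197.
2. **Attention** — learned affine projections of the conv features give
   $Q,K,V$ (all of width `n_filters`, so $d_k$ = 30 by default); the
   attention matrix $\mathrm{softmax}(QK^\top/\sqrt{d_k})$ is square with
   side equal to the number of conv positions and row-stochastic, and
   reweights $V$.
3. **Pooling** — the attention output is averaged over positions into one
   vector per sequence. Position-mean pooling is the default because it is
   the simplest permutation-stable reduction; an alternative that weights
   each position by the mean attention it receives is available
   (`pooling = "attention"`), with gradients flowing through the weights.
4. **Batch normalization** — per-feature standardization by minibatch
   moments (biased $1/m$ variance, $\varepsilon=10^{-5}$) with learnable
   scale/shift. Normalization is batch-wise, not layer-wise, matching the
   minibatch-moment formulation of the method.
5. **Dropout** — inverted dropout before the output layer (defaults 0.01
   for identification, 0.1 for strength).
6. **Softmax output** — an affine map to two logits and a shift-stable
   softmax; training minimizes categorical cross-entropy with a $10^{-12}$
   probability floor inside the log. Hard labels use threshold 0.5 on the
   positive-class probability.

The two prediction layers are two independent binary heads — one for
enhancer vs non-enhancer, one for strong vs weak — each with its own tuned
defaults (identification: learning rate $10^{-3}$, weight decay $10^{-4}$,
patience 5; strength: learning rate $2\times10^{-2}$, weight decay
$5\times10^{-3}$, patience 7; batch 64 for both).

All gradients are derived analytically and verified in the test suite
against central finite differences at $10^{-4}$ relative tolerance.

### Exact batch-norm moments for evaluation

Momentum-tracked running moments lag the weights whenever the head trains
for only tens of epochs at an aggressive learning rate, which leaves the
evaluation-mode logits offset: ranking metrics (AUROC) stay high while
threshold accuracy collapses toward 50%. The trainer therefore recomputes
the batch-norm statistics *exactly* over the training set at the end of
every epoch (the "precise BN" strategy), so evaluation-mode normalization
always matches the distribution the affine output layer was trained
against. This is deterministic and costs one extra forward pass over the
training encodings per epoch.

## The synthetic data generator

The generator emulates the compositional class structure of the two-layer
enhancer benchmark: enhancers (and strong enhancers) are GC-enriched,
non-enhancers (and weak enhancers) are AT-enriched and additionally show
runs of consecutive A's and T's. Concretely, positive-class residues are
i.i.d. with $P(G)=P(C)=\texttt{gc\_positive}/2$; negative-class residues
follow a first-order Markov chain with base GC probability
`gc_negative` in which the self-transition weight of A and of T is
multiplied by `1 + homopolymer_boost`. Defaults are 200 bp sequences, GC
0.60 vs 0.40 ("easy" mode; "hard" mode is 0.52 vs 0.48), and boost 0.
Identical specs generate byte-identical datasets under the same seed.

What this does *not* emulate — and hence what passing tests do and do not
show: real enhancers differ from background by motif grammar, positional
structure and chromatin context, not merely by nucleotide composition. A
pipeline that recovers the planted compositional signal demonstrates that
tokenization, representation learning, classification and evaluation are
wired correctly and leak-free; it says nothing about accuracy on genomic
data, which must be assessed on the real benchmark via `load_benchmark()`.

Three synthetic regimes are used as controls:

* **easy** (GC 0.60/0.40): near-perfectly separable by construction — a
  GC-count threshold alone achieves AUROC $\ge 0.99$ — so the full pipeline
  is expected to reach high holdout accuracy, and does in the test suite;
* **null** (identical class distributions): any systematic departure of
  holdout AUROC from 0.5 would indicate train/test leakage;
* **dimer-planted** (equal GC, positive homopolymer boost): the signal
  lives at dinucleotide scale, so $k=2$ should outperform $k=1$, mirroring
  the general observation that single-nucleotide tokens are the weakest
  choice.

## Evaluation suite

`compute_metrics()` reports confusion counts at the decision threshold,
accuracy, sensitivity and specificity as percentages, MCC, AUROC and AUPRC.
Accuracy is $(TP+TN)/n$. AUROC is the tie-aware trapezoidal integral of the
ROC curve and is checked in the tests against an exhaustive pairwise
concordance computation and against pROC; AUPRC is the step-wise
precision-recall integral. The threshold-bound quantity $(SN+SP)/2$ is also
reported, as `balanced_accuracy`, for comparability with summaries that use
it in place of a full curve integral. `stratified_kfold()` partitions with
per-fold class ratios within one example of the global ratio;
`cross_validate()` retrains the language model on each fold's training
sequences by default (no unlabeled test leakage into representation
learning), with `shared_lm = TRUE` as the cheaper documented variant.
`grid_search()` ranks candidate configurations by validation MCC with
accuracy and then smaller model size as tie-breaks, and tolerates diverging
configurations (they rank last rather than aborting the sweep).

## Numerical and scale choices

* Initialization: embeddings $\mathcal N(0,0.1^2)$, LSTM weights uniform
  $\pm 1/\sqrt{H}$, conv filters He-scaled, projections $\pm\sqrt{1/F}$;
  biases zero.
* Softmax subtracts the row maximum before exponentiation; cross-entropy
  floors probabilities at $10^{-12}$.
* Degenerate inputs: empty corpora, single-class labels, too-short
  sequences and invalid probabilities raise immediate errors; a
  single-class truth vector makes AUROC/AUPRC `NA` with a warning rather
  than a fabricated value.
* All stochastic steps (generation, splits, initialization, dropout masks,
  shuffling) run inside a seed-scoped RNG so the caller's RNG stream is
  never disturbed and every run replays exactly.
* The tests and the acceptance script run deliberately small
  configurations — 16-unit embeddings/hidden states, a few hundred
  sequences of 100–200 bp, 2–3 language-model epochs, up to 30 head
  epochs — chosen so the whole suite completes in minutes on one CPU while
  every qualitative property (signal recovery, null behavior, ablation
  direction, k-ordering) is still expressed. The full-scale defaults
  (400-d embeddings, 256 hidden units, patience 50) remain the configured
  defaults for real-data use.

## Known limitations

* Training is single-threaded R with BLAS matrix kernels; full-scale
  pretraining on thousands of 200 bp sequences is feasible but slow
  compared with GPU tool chains. The package's value is transparency and
  reproducibility, not raw speed.
* The strength task at small scale is harder than identification (larger
  vocabulary at $k=4$, weaker GC gradient), and its aggressive default
  learning rate makes per-seed variability visible in small holdouts.
* `<unk>` absorbs all N-containing k-mers; sequences dominated by N lose
  most of their information silently.
* The pretrained-vs-random ablation on *compositional* synthetic signal
  shows only a small positive margin: a frozen random LSTM already acts as
  a serviceable random-feature extractor for composition. Larger gains
  from pretraining are expected when the discriminative signal is
  contextual rather than marginal.
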