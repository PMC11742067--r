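---
title: "ReadBERT: model, estimation machinery and simulation bench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ReadBERT: model, estimation machinery and simulation bench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

ReadBERT classifies individual bisulfite-sequencing reads into cell types
from the joint signal of DNA sequence and per-CpG methylation state, and
aggregates per-read posterior probabilities into bulk composition
estimates — tumour purity in the two-class case. This vignette is the
package's account of the science: the model, the estimation machinery, the
simulation bench, and the choices made where the design was genuinely open.

## The classification model

A read is represented as three parallel sequences: overlapping 3-mer
tokens of its DNA (stride 1, so a read of `L` bases yields `L - 2`
tokens), a methylation code per token (1 = methylated CpG, 0 =
unmethylated CpG, 2 = non-CpG; the state of a CpG is assigned to the token
whose *middle* base is the CpG cytosine), and the token positions. The
vocabulary holds the 64 DNA 3-mers plus five special tokens
(`[PAD]`, `[UNK]`, `[CLS]`, `[SEP]`, `[MASK]`), 69 labels in total; 3-mers
containing `N` map to `[UNK]`. A CpG whose cytosine is the first or last
base of a read has no token with that base in the middle; its state cannot
be encoded and is dropped (reported via a message).

Token, methylation and position embeddings are summed per position and fed
to a BERT-style Transformer encoder: multi-head scaled dot-product
attention (`softmax(QK'/sqrt(d_k)) V` per head, heads concatenated and
projected), residual connections with post-LayerNorm, and a GELU
feed-forward of width `4 x hidden`. The encoder, AdamW optimiser and
backward passes are implemented in the package itself (R plus
RcppArmadillo kernels for attention, GELU and LayerNorm); gradient
correctness is pinned by finite-difference tests over every parameter
tensor. Dropout is not used: the desk-scale models are small relative to
their training data, and omitting it keeps runs bit-reproducible under a
fixed seed.

**Pre-training.** Masked-language-model only (no next-sentence prediction,
which has no meaning for unpaired reads). Seed tokens are selected i.i.d.
at rate 0.15; each seed *and its two immediate neighbours* are marked for
the loss — necessary because stride-1 3-mers overlap, so an unmasked
neighbour would leak the masked token — and the seed's corruption category
(80% `[MASK]`, 10% random 3-mer, 10% unchanged) applies to its triplet.
When triplets overlap, the earlier seed's category wins. The loss is
categorical cross-entropy over the 69 labels at marked positions;
methylation embeddings are held at zero throughout pre-training, because a
reference genome carries no methylation. The full-scale schedule (120k
steps, warm-up 10k, decay 20k, learning rate 4e-4, betas 0.9/0.98, weight
decay 0.01, sequence length 510) is available through `ModelConfig()`;
the bench uses `tinyModelConfig()` (2 layers, hidden 64, 2 heads, batch
16) with a few hundred steps on a synthetic or simulated genome.

**Fine-tuning.** The encoder output (`seqLen x hidden`) is augmented with
DMR information: an embedding table maps the read's region index to a
vector whose dimension equals the sequence length, appended as one extra
per-position channel. One table row is reserved for unseen region
indices. The classifier head is the package's own design: mean-pool the
`(hidden + 1)`-wide representation over unpadded positions, then a
two-layer GELU feed-forward to the class logits; pooling keeps the head
size independent of the sequence length. Softmax posteriors and
cross-entropy are the default; for many-class, imbalanced settings the
focal loss with per-class sigmoids is available (`gamma = 2`,
`alphaF = 0.1` in the leukocyte-style setting). The non-corresponding-class branch follows the original focal-loss
formulation, `-(1 - alpha) p^gamma log(1 - p)`: a `log(p)` there would
be minimised by `p -> 1` for every class and would break the reduction
of the loss to sigmoid cross-entropy at `gamma = 0`.
Exported loss functions use sum reduction exactly as defined; the training
loops scale gradients by the batch size so that the learning rate keeps
one meaning across batch sizes. Class priors `P(cell type)` are recorded
from the training-split label frequencies. Validation accuracy is
evaluated every 10 steps and the best-validation weights are kept.

## From posteriors to composition

Bayes inversion under the equal-read-marginal assumption gives
`score(r, c) = P(c | r) / P(c)`, proportional to `P(r | c)` up to a
read-constant factor; every argmax over the mixing parameter is invariant
to that factor, and each read's scores are divided by their maximum for
numerical stability. Tumour purity is the grid-search maximiser (step
1e-4, evaluated in the log domain) of

```
L(delta) = prod_i [ delta score_T(r_i) + (1 - delta) score_N(r_i) ].
```

Ties go to the smallest `delta`; a perfectly flat likelihood is flagged
rather than silently returned. Region-wise purities `delta_k` apply the
same MLE per DMR.

**Estimation adjustment.** Region purities are asymmetric whenever the two
compartments are unbalanced, and their skewness (adjusted Fisher–Pearson
G1) anti-correlates with the true purity. The adjustment finds mapping
weights `W` minimising `|G1(W o delta)|` subject to `W_k delta_k` in
[0, 1], starting from `W = 1`, and reports the unweighted mean of the
mapped region purities. Minimising a skewness has no standard latent-variable or closed-form
formulation, so the package implements the objective directly by cyclic
coordinate-wise line searches (hold all but one `W_k`,
line-search it inside its box; stop when |G1| changes by less than 1e-8 or
after 500 sweeps); a direct box-constrained L-BFGS-B minimiser of `G1^2`
is shipped as a cross-check. The box constraint keeps mapped purities
probabilities; the final mean is unweighted by region read counts.

**Precision.** The Fisher information is the variance over reads of the
per-read score contribution
`(score_T - score_N) / (delta score_T + (1 - delta) score_N)`. With
adjustment on, a single global value is undefined for the mapped
estimator, so per-region values are reported, one per selected DMR.

**Many classes.** With `C` cell types, reads are grouped by their argmax
class `R_c` and each `theta_c` maximises
`prod_{r in R_c} [theta_c P(r|c) + (1 - theta_c)(1 - P(r|c))]`, with
`P(r|c)` the inverted score rescaled per read to sum to one across classes
(which makes the complement well defined). Under a confident classifier
every `theta_c` tends to 1, so raw `theta` cannot be the composition; the
reported fraction is `theta_c |R_c|`, normalised to sum to one, which
reduces to the classified-read share in the certainty limit — consistent
with the two-class likelihood whose estimate is the tumour-read share for
certain posteriors. The normalisation is the package's own design choice.

## The simulation bench

The simulator is the universal test fixture and defines the bench
conditions. Per region, a tumour mean methylation `d ~ Beta(alpha,
beta = 5)`; tumour reads draw each covered CpG state as Bernoulli(`d`),
normal reads as Bernoulli(`1 - d`) (region-level scenario). Four alphas —
0.1, 1, 2, 3 (complexities `a0_b5`..`a3_b5`) — span simple to complex
patterns: the expected tumour/normal gap shrinks monotonically as alpha
grows. In the CpG-specific scenario `d` and `1 - d` alternate over odd and
even CpG indices for tumour reads (1-based on CpG order within the region,
first CpG odd); normal reads receive the opposite phase — the package's completion of
the scenario, chosen so that region means coincide while per-CpG
patterns anti-correlate, which is what makes the scenario invisible to
any region-mean-based classifier.

Regions are synthetic: each on its own chromosome with read-length flanks,
CpGs planted every `cpgSpacing` bp (default 10, CpG-island-like density;
a BED loader accepts real CpG-island or DMR coordinates when a genome
annotation is at hand), reference sequence random with CG dinucleotides exactly at
planted sites. Reads place uniformly over windows overlapping the region
(uniform placement is assumed); 500 bp reads
deliberately overhang into the flanks, where background CpGs (spacing 75)
carry methylation 0.5 for both cell types. Pseudo-bulks mix exactly
`round(n x fraction)` tumour reads without replacement and store the
ground truth. Everything is deterministic under the `SimConfig` seed.

What the bench does *not* emulate: sequencing error, bisulfite
non-conversion, fragment-length variation, strand effects, linked
methylation within reads (CpG states are independent Bernoulli draws
given the region mean), or realistic genome composition. Passing bench
results therefore demonstrate the correctness and behaviour of the
algorithms under the stated generative model, not performance on real
libraries.

## Baseline

The two-state HMM baseline observes a read's ordered binary CpG states
(inter-CpG distances ignored); hidden states model whether a CpG is
differentially methylated. One HMM per cell type is fitted by Baum–Welch
(5 seeded restarts, best likelihood kept) — per-class fitting with a
forward-likelihood argmax (ties to Normal) is the package's choice of
training procedure and decision rule. Its
log-likelihood ratios are converted to pseudo-posteriors by normalised
exponentiation so the deconvolution stack consumes either classifier.
The baseline also serves as an independent sanity oracle: it excels on
region-level patterns at low alpha and collapses to chance on the
CpG-specific scenario, where only the sequence-aware model stays above it.

## Numerical and reproducibility notes

* Grid likelihoods are evaluated in chunks to bound memory; the outer
  product never materialises beyond ~5e6 doubles.
* `purityMLE` drops reads whose two scores are both zero (with a
  warning); `fisherInformation` excludes reads with a zero mixture
  density.
* The softmax inside attention subtracts the global matrix maximum
  (cheaper than row maxima; scores are bounded, padded keys sit at -1e9
  and underflow to zero weight).
* Weight decay applies to matrix-shaped parameters only, not biases or
  LayerNorm vectors, as is standard for BERT-style training.
* All randomness (simulation, masking, batch order, splits, restarts)
  derives from explicit seeds; two runs with the same seeds give
  identical traces on the same BLAS/thread configuration.

## Bench problem sizes

The package's own experiments run at desk scale, chosen so the behaviour
of interest is measurable with comfortable margins: classification runs
use the tiny preset (2 layers, hidden 64) on 100 regions x coverage 10
(2,000 reads, 150 bp) with a brief synthetic-genome pre-train and 600
fine-tuning steps; the estimation bench uses a calibrated synthetic
posterior channel (see `simulateCalibratedPosteriors()`) with 3,000-4,000
reads per bulk; the pre-training-effect comparison uses a reduced
CpG-specific task (12 regions of 8 alternating CpGs, 60 bp reads at
coverage 40) sized so that the sequence-context load exceeds what an
untrained twin can acquire in the 250-step fine-tuning budget, while a
twin pre-trained for 500 MLM steps on the same chromosomes begins to
learn. At this scale the pre-training advantage manifests as the onset of
learning — a consistent but numerically small validation-accuracy margin
over seeds — rather than the large gap seen at full scale, where the
non-pre-trained model additionally suffers optimisation collapse that a
two-layer desk model does not reproduce. Full-scale
presets (12 layers, hidden 768, 120k pre-training steps) are configurable
but are not exercised by the test bench.

## Known limitations

* The DMR-embedding wiring and classifier head are one of several
  reasonable architectures; both are isolated behind `classifyReads()`
  so alternatives can be swapped in.
* The skewness-minimising objective is under-determined (many `W` reach
  |G1| = 0); coordinate descent from `W = 1` selects a minimal-change
  solution, which is a convention, not an identified estimator.
* Purity estimation assumes two classes; the multi-class path reports
  per-class `theta` with the normalisation described above.
* The bench's synthetic posteriors are calibrated by construction;
  real classifiers are miscalibrated in ways the bench only emulates
  through explicit sharpening/shift parameters.
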