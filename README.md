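# ReadBERT

Read-level DNA methylation classification and tumour-purity estimation
with a BERT-style Transformer, in R.

## The problem

Bulk bisulfite sequencing mixes DNA molecules from different cell
populations. In cancer genomics the quantity of interest is often the
tumour purity — the fraction of reads derived from tumour cells — or,
more generally, the cell-type composition of the mixture. Region-level
average methylation discards the information carried by each molecule, so
ReadBERT works at the level of the single read: every sequenced molecule
is classified by a Transformer encoder that sees its DNA 3-mer sequence,
its per-CpG methylation states (1 = methylated, 0 = unmethylated,
2 = non-CpG, assigned to the 3-mer whose middle base is the CpG cytosine)
and the identity of the differentially methylated region (DMR) it maps
to. Softmax over the classifier's activations gives per-read posteriors
`P(cell type | read)`.

Composition then follows by maximum likelihood. With priors taken from
the training labels, Bayes inversion gives class-conditional scores
`score(r, c) = P(c|r)/P(c)`, and the tumour purity maximises

    L(delta) = prod_i [ delta * score_T(r_i) + (1 - delta) * score_N(r_i) ]

over a grid of step 1e-4 (a single-parameter likelihood: the two
compartment fractions sum to one). The package also provides

* region-wise purities and a skewness-minimising estimation adjustment
  (map region purities by weights `W` to zero the adjusted Fisher-Pearson
  G1 coefficient, then average) for bulks with very high or low purity,
* the Fisher information of the estimate (variance of the per-read score
  contribution) as a precision readout — per DMR when adjustment is on,
* a multi-class likelihood for C-cell-type deconvolution with a focal-loss
  fine-tuning mode for imbalanced class settings,
* reconstructed per-region, per-cell-type methylation levels from the
  classified reads,
* a two-state HMM baseline classifier, and
* a read-level methylome simulator (beta-binomial region-level and
  CpG-specific alternating scenarios, pseudo-bulk mixing) that serves as
  the package's evaluation bench.

Masked-language-model pre-training (15% neighbour-expanded masking,
80/10/10 corruption, methylation embeddings zeroed) on a reference or
synthetic genome precedes fine-tuning, exactly as in BERT-style genomic
models. The Transformer, its backward passes and AdamW are implemented in
the package (R + RcppArmadillo kernels); no deep-learning framework is
required.

## Worked example

```r
library(ReadBERT)

## simulate the simplest bench condition: alpha 0.1 / beta 5, 20 regions
simc  <- SimConfig(alpha = 0.1, beta = 5, nRegions = 20L, coverage = 20L,
                   readLength = 150L, seed = 7L)
rs    <- simulateRegions(simc)
reads <- simulateReads(rs)
enc   <- encodeReads(reads, seqLen = 148L)

## tiny preset: 2 layers, hidden 64; brief pre-train, short fine-tune
cfg   <- tinyModelConfig(seqLen = 148L, nRegions = 20L, seed = 7L)
model <- initModel(cfg)
corpus <- makePretrainCorpus(synthesizeGenome(30000L, seed = 8L),
                             segmentLength = 150L)
model <- pretrainModel(model, corpus, steps = 100L)$model
ft    <- finetuneModel(model, enc, steps = 200L)
ft$valAccuracy
#> [1] 0.96

## classify a pseudo-bulk at 30% tumour and estimate its purity
mix <- mixPseudobulk(reads[cellLabel(reads) == "Tumour"],
                     reads[cellLabel(reads) == "Normal"],
                     tumourFraction = 0.3, nReads = 400L, seed = 9L)
pt  <- classifyReads(ft$model, encodeReads(mix$reads, seqLen = 148L),
                     priors = ft$priors)
estimatePurity(pt, adjust = TRUE)
#> PurityResult
#>   delta_hat (grid MLE): 0.2631
#>   adjusted delta:       0.2870  (G1 0.411 -> 0.000)
#>   regions: 20, Fisher information: per-region (n=20, mean 3.637)
```

`delta_hat` is the pooled grid-search MLE of the tumour purity (truth
0.30 here), and `adjusted delta` the skewness-adjusted estimate — the G1
figures show the region-purity skewness before and after the mapping,
and here the adjustment moves the briefly-trained classifier's estimate
from 0.263 to 0.287, closer to the true 0.30. The Fisher information
quantifies how sharply the likelihood peaks; larger values mean a more
precise estimate.

A thin command-line front end over the same functions ships in
`inst/scripts/readbert` (`simulate`, `encode`, `pretrain`, `finetune`,
`estimate`).

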