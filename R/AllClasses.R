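## S4 class definitions for the central data containers.

#' Vocabulary of 3-mer tokens and special tokens
#'
#' Bidirectional map between the 64 DNA 3-mers plus five special tokens
#' (`[PAD]`, `[UNK]`, `[CLS]`, `[SEP]`, `[MASK]`) and integer ids 1..69.
#'
#' @slot tokens character vector of length 69; position = id.
#' @exportClass Vocabulary
setClass("Vocabulary", representation(tokens = "character"))

setValidity("Vocabulary", function(object) {
    tok <- object@tokens
    if (length(tok) != 69L)
        return("vocabulary must have exactly 69 entries (64 3-mers + 5 special)")
    if (anyDuplicated(tok)) return("vocabulary entries must be unique")
    TRUE
})

#' A set of sequenced molecules with per-CpG methylation calls
#'
#' Container for read-level methylomes: one genomic range per read plus its
#' base sequence, the ordered offsets (0-based, within the read) of called
#' CpG cytosines, their binary methylation states, the index of the region
#' (DMR) the read is assigned to, and an optional cell-type label.
#'
#' @slot ranges [GenomicRanges::GRanges] of the reads (0-based starts are
#'   converted to 1-based GRanges convention internally).
#' @slot sequence [Biostrings::DNAStringSet] read sequences.
#' @slot cpgOffsets [IRanges::IntegerList] 0-based offsets of CpG cytosines
#'   within each read, strictly increasing.
#' @slot cpgStates [IRanges::IntegerList] methylation states, 1 = methylated,
#'   0 = unmethylated, parallel to `cpgOffsets`.
#' @slot regionIndex integer vector, region id per read (NA when unassigned).
#' @slot cellLabel character vector of cell-type labels (NA when unknown).
#' @exportClass MethylReadSet
setClass("MethylReadSet",
    representation(ranges = "GRanges", sequence = "DNAStringSet",
                   cpgOffsets = "IntegerList", cpgStates = "IntegerList",
                   regionIndex = "integer", cellLabel = "character"))

setValidity("MethylReadSet", function(object) {
    n <- length(object@ranges)
    if (length(object@sequence) != n || length(object@cpgOffsets) != n ||
        length(object@cpgStates) != n || length(object@regionIndex) != n ||
        length(object@cellLabel) != n)
        return("all slots must have one entry per read")
    if (any(S4Vectors::elementNROWS(object@cpgOffsets) !=
            S4Vectors::elementNROWS(object@cpgStates)))
        return("cpgOffsets and cpgStates must be parallel")
    st <- unlist(object@cpgStates)
    if (length(st) && !all(st %in% c(0L, 1L)))
        return("cpgStates must be 0/1")
    offs <- object@cpgOffsets
    bad <- any(vapply(seq_len(n), function(i) {
        o <- offs[[i]]
        length(o) > 1L && any(diff(o) <= 0L)
    }, logical(1)))
    if (bad) return("cpgOffsets must be strictly increasing within each read")
    TRUE
})

#' Model-ready encoded reads
#'
#' Parallel integer matrices (reads x positions) holding 3-mer token ids,
#' methylation codes (0 = unmethylated CpG, 1 = methylated CpG, 2 = non-CpG),
#' and the attention mask (0 on the padded tail), plus the region index used
#' by the DMR embedding and the optional cell-type label per read.
#'
#' @slot tokenIds integer matrix, N x L.
#' @slot methylCodes integer matrix, N x L, values in \{0, 1, 2\}.
#' @slot attentionMask integer matrix, N x L, values in \{0, 1\}.
#' @slot regionIndex integer vector of length N.
#' @slot cellLabel character vector of length N (NA allowed).
#' @slot readId character vector of length N.
#' @exportClass EncodedReads
setClass("EncodedReads",
    representation(tokenIds = "matrix", methylCodes = "matrix",
                   attentionMask = "matrix", regionIndex = "integer",
                   cellLabel = "character", readId = "character"))

setValidity("EncodedReads", function(object) {
    d <- dim(object@tokenIds)
    if (!identical(dim(object@methylCodes), d) ||
        !identical(dim(object@attentionMask), d))
        return("tokenIds, methylCodes and attentionMask must share dimensions")
    if (length(object@regionIndex) != d[1L] ||
        length(object@cellLabel) != d[1L] || length(object@readId) != d[1L])
        return("per-read slots must have one entry per row")
    if (!all(object@methylCodes %in% c(0L, 1L, 2L)))
        return("methylCodes must be in {0, 1, 2}")
    if (!all(object@attentionMask %in% c(0L, 1L)))
        return("attentionMask must be binary")
    TRUE
})

#' Per-read cell-type posterior probabilities
#'
#' Rows are reads; the posterior matrix holds P(cell type | read) per class,
#' each row summing to one. Class priors P(cell type) are recorded from the
#' classifier's training labels and are needed for Bayes inversion.
#'
#' @slot readId character, one per read.
#' @slot regionIndex integer, region (DMR) id per read.
#' @slot posterior numeric matrix N x C, rows sum to 1.
#' @slot priors named numeric vector of length C, positive, sums to 1.
#' @slot classes character vector of cell-type names (columns of `posterior`).
#' @slot trueLabel character, optional ground-truth labels (NA when unknown).
#' @exportClass PosteriorTable
setClass("PosteriorTable",
    representation(readId = "character", regionIndex = "integer",
                   posterior = "matrix", priors = "numeric",
                   classes = "character", trueLabel = "character"))

setValidity("PosteriorTable", function(object) {
    n <- length(object@readId)
    if (nrow(object@posterior) != n || length(object@regionIndex) != n ||
        length(object@trueLabel) != n)
        return("posterior rows, regionIndex and trueLabel must match readId")
    C <- length(object@classes)
    if (ncol(object@posterior) != C || length(object@priors) != C)
        return("posterior columns and priors must match classes")
    if (any(object@priors <= 0)) return("priors must be strictly positive")
    if (abs(sum(object@priors) - 1) > 1e-6) return("priors must sum to 1")
    if (n > 0) {
        rs <- rowSums(object@posterior)
        if (any(abs(rs - 1) > 1e-6))
            return("posterior rows must sum to 1 (tolerance 1e-6)")
    }
    TRUE
})

#' Tumour purity estimate with adjustment and precision
#'
#' @slot deltaHat numeric, global grid-search MLE of tumour purity.
#' @slot regionDeltas numeric vector of region-wise purities (one per DMR).
#' @slot W numeric vector, skewness-minimising mapping parameters.
#' @slot adjustedDelta numeric, mean of mapped region-wise purities
#'   (NA when adjustment was not applied).
#' @slot fisherInformation numeric; per-region values when adjustment is on,
#'   a single global value otherwise.
#' @slot gridStep numeric, grid resolution of the MLE search.
#' @slot flat logical, TRUE when the global likelihood was flat.
#' @slot skewBefore,skewAfter numeric, G1 of region purities before/after
#'   the mapping (NA when fewer than 3 regions).
#' @exportClass PurityResult
setClass("PurityResult",
    representation(deltaHat = "numeric", regionDeltas = "numeric",
                   W = "numeric", adjustedDelta = "numeric",
                   fisherInformation = "numeric", gridStep = "numeric",
                   flat = "logical", skewBefore = "numeric",
                   skewAfter = "numeric"))

#' Multi-class cell-type fraction estimate
#'
#' @slot theta named numeric, per-class maximisers of the per-class
#'   likelihood (each in [0, 1]).
#' @slot counts named integer, number of reads classified into each class.
#' @slot fractions named numeric, reported composition, sums to 1.
#' @slot gridStep numeric.
#' @exportClass CellFractionResult
setClass("CellFractionResult",
    representation(theta = "numeric", counts = "integer",
                   fractions = "numeric", gridStep = "numeric"))

#' Simulation configuration for read-level methylomes
#'
#' Generative parameters of the read-level methylome simulator. Per region a
#' tumour mean methylation d is drawn from Beta(alpha, beta); tumour reads
#' draw each CpG state Bernoulli(d) and normal reads Bernoulli(1 - d)
#' (region-level scenario), or the probabilities alternate across CpG
#' indices (CpG-specific scenario).
#'
#' @slot alpha,beta Beta shape parameters (beta defaults to 5).
#' @slot nRegions number of simulated regions.
#' @slot readLength read length in bp.
#' @slot coverage reads per region per cell type.
#' @slot scenario `"region_level"` or `"cpg_specific"`.
#' @slot regionLength region span in bp.
#' @slot cpgSpacing distance between consecutive CpGs inside a region (bp).
#' @slot backgroundCpgSpacing CpG spacing outside regions (bp), used when
#'   reads overhang region boundaries.
#' @slot backgroundMethylation mean methylation of CpGs outside regions.
#' @slot seed integer seed controlling all randomness.
#' @exportClass SimConfig
setClass("SimConfig",
    representation(alpha = "numeric", beta = "numeric", nRegions = "integer",
                   readLength = "integer", coverage = "integer",
                   scenario = "character", regionLength = "integer",
                   cpgSpacing = "integer", backgroundCpgSpacing = "integer",
                   backgroundMethylation = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
    if (object@alpha <= 0 || object@beta <= 0)
        return("alpha and beta must be positive")
    if (object@coverage < 1L) return("coverage must be >= 1")
    if (object@readLength < 3L) return("readLength must be >= 3")
    if (!object@scenario %in% c("region_level", "cpg_specific"))
        return("scenario must be 'region_level' or 'cpg_specific'")
    if (object@backgroundMethylation < 0 || object@backgroundMethylation > 1)
        return("backgroundMethylation must be in [0, 1]")
    TRUE
})

#' Simulated region set
#'
#' Region templates drawn by [simulateRegions()]: coordinates, reference
#' sequence, CpG offsets (region-relative), the tumour mean methylation d per
#' region and the derived per-CpG Bernoulli success probabilities for both
#' cell types.
#'
#' @slot ranges [GenomicRanges::GRanges] of the regions, with `regionIndex`
#'   and `d` metadata columns.
#' @slot chromSeq [Biostrings::DNAStringSet] one synthetic chromosome per
#'   region (region plus flanks), named by chromosome.
#' @slot cpgOffsets [IRanges::IntegerList] 0-based CpG offsets relative to
#'   the chromosome start (region CpGs and background flank CpGs).
#' @slot inRegion [IRanges::IntegerList] 1 when the CpG lies inside the DMR.
#' @slot probTumour,probNormal [IRanges::NumericList] per-CpG methylation
#'   probabilities for the two cell types.
#' @slot config the [SimConfig] used.
#' @exportClass SimRegionSet
setClass("SimRegionSet",
    representation(ranges = "GRanges", chromSeq = "DNAStringSet",
                   cpgOffsets = "IntegerList", inRegion = "IntegerList",
                   probTumour = "NumericList", probNormal = "NumericList",
                   config = "SimConfig"))

#' Transformer model configuration
#'
#' Architecture and optimisation hyper-parameters. The defaults are the
#' full-scale setting (12 layers, hidden 768, 12 heads, sequence
#' length 510, learning rate 4e-4, AdamW betas 0.9/0.98, weight decay 0.01,
#' 15\% masking); [tinyModelConfig()] returns the desk-scale preset used
#' throughout the test-bench.
#'
#' @slot nLayers,nHeads,hidden,intermediate,seqLen architecture sizes.
#' @slot nRegions size of the DMR-embedding table (one extra row is reserved
#'   for unseen region indices).
#' @slot classes character vector of cell-type names for the classifier head.
#' @slot lr,beta1,beta2,weightDecay AdamW settings.
#' @slot warmupSteps,decaySteps learning-rate schedule (linear warm-up, flat,
#'   linear decay over the final `decaySteps`).
#' @slot maskRate MLM seed-masking rate.
#' @slot batchSize,gradAccum batch size and gradient-accumulation factor.
#' @slot seed integer seed for initialisation and batch order.
#' @exportClass ModelConfig
setClass("ModelConfig",
    representation(nLayers = "integer", nHeads = "integer", hidden = "integer",
                   intermediate = "integer", seqLen = "integer",
                   nRegions = "integer", classes = "character",
                   lr = "numeric", beta1 = "numeric", beta2 = "numeric",
                   weightDecay = "numeric", warmupSteps = "integer",
                   decaySteps = "integer", maskRate = "numeric",
                   batchSize = "integer", gradAccum = "integer",
                   seed = "integer"))

setValidity("ModelConfig", function(object) {
    if (object@hidden %% object@nHeads != 0L)
        return("hidden size must be divisible by the number of heads")
    if (object@maskRate <= 0 || object@maskRate >= 1)
        return("maskRate must be in (0, 1)")
    TRUE
})

#' A BERT-style encoder model with its parameters
#'
#' @slot config the [ModelConfig].
#' @slot vocab the [Vocabulary].
#' @slot params named list of parameter matrices/vectors.
#' @slot pretrained logical, whether MLM pre-training has been run.
#' @exportClass BertModel
setClass("BertModel",
    representation(config = "ModelConfig", vocab = "Vocabulary",
                   params = "list", pretrained = "logical"))

#' Two-state HMM read classifier
#'
#' One two-state, two-emission hidden Markov model per cell type, fitted by
#' Baum-Welch on that cell type's CpG-state sequences. Hidden states model
#' whether a CpG is differentially methylated between the cell types;
#' observations are the binary methylation states.
#'
#' @slot models named list, one `list(init, trans, emis)` per cell type;
#'   `init` length-2, `trans` and `emis` 2 x 2 row-stochastic matrices
#'   (emission columns: unmethylated, methylated).
#' @slot classes character vector of cell-type names.
#' @slot priors named numeric, training-set class frequencies.
#' @exportClass HmmClassifier
setClass("HmmClassifier",
    representation(models = "list", classes = "character",
                   priors = "numeric"))
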