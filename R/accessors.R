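## Constructors, accessors and show() methods.

#' Construct a simulation configuration
#'
#' @param alpha,beta Beta shape parameters of the per-region tumour mean
#'   methylation d ~ Beta(alpha, beta). The evaluation bench uses
#'   alpha in \{0.1, 1, 2, 3\} with beta = 5 (complexities a0_b5..a3_b5).
#' @param nRegions number of regions (default 100).
#' @param readLength read length in bp (150 or 500 in the bench).
#' @param coverage reads per region per cell type.
#' @param scenario `"region_level"` (tumour CpG probability d everywhere,
#'   normal 1 - d) or `"cpg_specific"` (d and 1 - d alternate across odd/even
#'   CpG indices; normal gets the opposite phase).
#' @param regionLength region span in bp.
#' @param cpgSpacing CpG spacing inside regions (bp); CpG-island-like density
#'   by default.
#' @param backgroundCpgSpacing CpG spacing in the flanks outside regions.
#' @param backgroundMethylation methylation level of flank CpGs (default 0.5),
#'   used by reads that overhang region boundaries.
#' @param seed integer seed; all simulator randomness derives from it.
#' @return A [SimConfig] object.
#' @export
#' @examples
#' cfg <- SimConfig(alpha = 0.1, coverage = 10, seed = 7)
SimConfig <- function(alpha = 0.1, beta = 5, nRegions = 100L,
                      readLength = 150L, coverage = 10L,
                      scenario = c("region_level", "cpg_specific"),
                      regionLength = 200L, cpgSpacing = 10L,
                      backgroundCpgSpacing = 75L,
                      backgroundMethylation = 0.5, seed = 1L) {
    scenario <- match.arg(scenario)
    new("SimConfig", alpha = as.numeric(alpha), beta = as.numeric(beta),
        nRegions = as.integer(nRegions), readLength = as.integer(readLength),
        coverage = as.integer(coverage), scenario = scenario,
        regionLength = as.integer(regionLength),
        cpgSpacing = as.integer(cpgSpacing),
        backgroundCpgSpacing = as.integer(backgroundCpgSpacing),
        backgroundMethylation = as.numeric(backgroundMethylation),
        seed = as.integer(seed))
}

#' Construct a model configuration
#'
#' Defaults are the full-scale setting; see [tinyModelConfig()]
#' for the desk-scale preset exercised by the test bench.
#'
#' @param nLayers,nHeads,hidden,intermediate,seqLen architecture sizes.
#' @param nRegions DMR-embedding table size (number of distinct regions).
#' @param classes cell-type names of the classifier head.
#' @param lr,beta1,beta2,weightDecay AdamW hyper-parameters.
#' @param warmupSteps,decaySteps learning-rate schedule.
#' @param maskRate MLM seed-masking rate.
#' @param batchSize,gradAccum optimisation batch settings.
#' @param seed integer seed.
#' @return A [ModelConfig] object.
#' @export
ModelConfig <- function(nLayers = 12L, nHeads = 12L, hidden = 768L,
                        intermediate = 4L * hidden, seqLen = 510L,
                        nRegions = 100L, classes = c("Tumour", "Normal"),
                        lr = 4e-4, beta1 = 0.9, beta2 = 0.98,
                        weightDecay = 0.01, warmupSteps = 10000L,
                        decaySteps = 20000L, maskRate = 0.15,
                        batchSize = 256L, gradAccum = 4L, seed = 1L) {
    new("ModelConfig", nLayers = as.integer(nLayers),
        nHeads = as.integer(nHeads), hidden = as.integer(hidden),
        intermediate = as.integer(intermediate), seqLen = as.integer(seqLen),
        nRegions = as.integer(nRegions), classes = as.character(classes),
        lr = lr, beta1 = beta1, beta2 = beta2, weightDecay = weightDecay,
        warmupSteps = as.integer(warmupSteps),
        decaySteps = as.integer(decaySteps), maskRate = maskRate,
        batchSize = as.integer(batchSize), gradAccum = as.integer(gradAccum),
        seed = as.integer(seed))
}

#' Desk-scale model preset
#'
#' Two encoder layers, hidden size 64, two heads, small batches and a short
#' warm-up. All bench experiments run this preset; the full-scale defaults of
#' [ModelConfig()] are shipped for completeness but are not exercised by the
#' test suite.
#'
#' @param seqLen input sequence length (tokens).
#' @param nRegions DMR-embedding table size.
#' @param classes cell-type names.
#' @param hidden,nLayers,nHeads,batchSize,warmupSteps,decaySteps,seed
#'   overridable preset values.
#' @param ... further arguments passed to [ModelConfig()].
#' @return A [ModelConfig].
#' @export
#' @examples
#' cfg <- tinyModelConfig(seqLen = 150L, nRegions = 100L)
tinyModelConfig <- function(seqLen = 150L, nRegions = 100L,
                            classes = c("Tumour", "Normal"), hidden = 64L,
                            nLayers = 2L, nHeads = 2L, batchSize = 16L,
                            warmupSteps = 30L, decaySteps = 0L, seed = 1L,
                            ...) {
    ModelConfig(nLayers = nLayers, nHeads = nHeads, hidden = hidden,
                intermediate = 4L * as.integer(hidden), seqLen = seqLen,
                nRegions = nRegions, classes = classes, batchSize = batchSize,
                gradAccum = 1L, warmupSteps = warmupSteps,
                decaySteps = decaySteps, seed = seed, ...)
}

#' Construct a MethylReadSet
#'
#' @param chrom chromosome name per read.
#' @param start 0-based start position per read.
#' @param sequence character vector or [Biostrings::DNAStringSet] of read
#'   sequences.
#' @param cpgOffsets list / [IRanges::IntegerList] of 0-based offsets of CpG
#'   cytosines within each read.
#' @param cpgStates list / [IRanges::IntegerList] of 0/1 methylation states.
#' @param regionIndex integer region id per read (NA allowed).
#' @param cellLabel character cell-type label per read (NA allowed).
#' @param readId read names; autogenerated when NULL.
#' @param strand strand per read (default "+").
#' @return A [MethylReadSet].
#' @export
MethylReadSet <- function(chrom, start, sequence, cpgOffsets, cpgStates,
                          regionIndex = NA_integer_, cellLabel = NA_character_,
                          readId = NULL, strand = "+") {
    if (!is(sequence, "DNAStringSet")) sequence <- DNAStringSet(sequence)
    n <- length(sequence)
    gr <- GRanges(chrom,
                  IRanges(start = as.integer(start) + 1L,
                          width = Biostrings::width(sequence)),
                  strand = S4Vectors::Rle(strand, if (length(strand) == 1L) n
                                          else NULL))
    if (is.null(readId))
        readId <- sprintf("read_%06d", seq_len(n))
    names(gr) <- readId
    new("MethylReadSet", ranges = gr, sequence = sequence,
        cpgOffsets = as(cpgOffsets, "IntegerList"),
        cpgStates = as(cpgStates, "IntegerList"),
        regionIndex = rep(as.integer(regionIndex), length.out = n),
        cellLabel = rep(as.character(cellLabel), length.out = n))
}

#' @describeIn MethylReadSet number of reads.
#' @param x,object a `MethylReadSet`.
#' @export
setMethod("length", "MethylReadSet", function(x) length(x@ranges))

#' Subset a MethylReadSet
#' @param x a [MethylReadSet].
#' @param i index vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "MethylReadSet", function(x, i, j, ..., drop = TRUE) {
    new("MethylReadSet", ranges = x@ranges[i], sequence = x@sequence[i],
        cpgOffsets = x@cpgOffsets[i], cpgStates = x@cpgStates[i],
        regionIndex = x@regionIndex[i], cellLabel = x@cellLabel[i])
})

#' Combine MethylReadSets
#' @param x,... MethylReadSet objects.
#' @export
setMethod("c", "MethylReadSet", function(x, ...) {
    all <- c(list(x), list(...))
    ## reads from different simulated chromosomes carry disjoint seqinfos;
    ## combining them is intended, so the merge warning is suppressed
    new("MethylReadSet",
        ranges = suppressWarnings(do.call(c, lapply(all, slot, "ranges"))),
        sequence = do.call(c, lapply(all, slot, "sequence")),
        cpgOffsets = do.call(c, lapply(all, slot, "cpgOffsets")),
        cpgStates = do.call(c, lapply(all, slot, "cpgStates")),
        regionIndex = do.call(c, lapply(all, slot, "regionIndex")),
        cellLabel = do.call(c, lapply(all, slot, "cellLabel")))
})

#' @rdname readAccessors
#' @name readAccessors
#' @title Accessors for read-level containers
#' @param x a [MethylReadSet], [EncodedReads] or [PosteriorTable].
#' @return the corresponding slot content.
NULL

#' @rdname readAccessors
#' @export
readSequences <- function(x) x@sequence

#' @rdname readAccessors
#' @export
cpgOffsets <- function(x) x@cpgOffsets

#' @rdname readAccessors
#' @export
cpgStates <- function(x) x@cpgStates

#' @rdname readAccessors
#' @export
regionIndex <- function(x) x@regionIndex

#' @rdname readAccessors
#' @export
cellLabel <- function(x) x@cellLabel

#' @rdname readAccessors
#' @export
readRanges <- function(x) x@ranges

#' @rdname readAccessors
#' @export
readIds <- function(x) {
    if (is(x, "MethylReadSet")) names(x@ranges) else x@readId
}

#' Per-read mean methylation level
#'
#' Fraction of methylated CpGs on each read (NA for reads without CpGs).
#'
#' @param x a [MethylReadSet].
#' @return numeric vector of per-read methylation levels.
#' @export
readMethylationLevel <- function(x) {
    k <- S4Vectors::elementNROWS(x@cpgStates)
    m <- vapply(seq_along(k), function(i)
        if (k[i] > 0L) mean(x@cpgStates[[i]]) else NA_real_, numeric(1))
    m
}

setMethod("show", "MethylReadSet", function(object) {
    cat("MethylReadSet with", length(object), "reads\n")
    k <- S4Vectors::elementNROWS(object@cpgOffsets)
    cat("  CpGs per read:", paste(range(k), collapse = "-"),
        " labels:", paste(unique(object@cellLabel), collapse = ","), "\n")
})

#' @describeIn EncodedReads-class number of encoded reads.
#' @param x an `EncodedReads` object.
#' @export
setMethod("length", "EncodedReads", function(x) nrow(x@tokenIds))

#' @rdname readAccessors
#' @export
tokenIds <- function(x) x@tokenIds

#' @rdname readAccessors
#' @export
methylCodes <- function(x) x@methylCodes

#' @rdname readAccessors
#' @export
attentionMask <- function(x) x@attentionMask

#' Subset an EncodedReads object
#' @param x an [EncodedReads].
#' @param i index vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "EncodedReads", function(x, i, j, ..., drop = TRUE) {
    new("EncodedReads", tokenIds = x@tokenIds[i, , drop = FALSE],
        methylCodes = x@methylCodes[i, , drop = FALSE],
        attentionMask = x@attentionMask[i, , drop = FALSE],
        regionIndex = x@regionIndex[i], cellLabel = x@cellLabel[i],
        readId = x@readId[i])
})

setMethod("show", "EncodedReads", function(object) {
    cat("EncodedReads:", nrow(object@tokenIds), "reads x",
        ncol(object@tokenIds), "positions\n")
})

#' Construct a PosteriorTable
#'
#' @param readId read names.
#' @param regionIndex region id per read.
#' @param posterior N x C matrix of P(cell type | read); rows must sum to 1.
#' @param priors class priors P(cell type) (positive, sum to 1); taken from
#'   the classifier's training-set label frequencies.
#' @param classes cell-type names; defaults to `colnames(posterior)`.
#' @param trueLabel optional ground-truth labels.
#' @return A [PosteriorTable].
#' @export
PosteriorTable <- function(readId, regionIndex, posterior, priors,
                           classes = colnames(posterior),
                           trueLabel = NA_character_) {
    n <- length(readId)
    posterior <- as.matrix(posterior)
    colnames(posterior) <- classes
    new("PosteriorTable", readId = as.character(readId),
        regionIndex = rep(as.integer(regionIndex), length.out = n),
        posterior = posterior,
        priors = setNames(as.numeric(priors), classes),
        classes = as.character(classes),
        trueLabel = rep(as.character(trueLabel), length.out = n))
}

#' @describeIn PosteriorTable number of reads in the table.
#' @param x,object a `PosteriorTable`.
#' @export
setMethod("length", "PosteriorTable", function(x) length(x@readId))

#' @rdname readAccessors
#' @export
posteriors <- function(x) x@posterior

#' @rdname readAccessors
#' @export
classPriors <- function(x) x@priors

#' @rdname readAccessors
#' @export
classNames <- function(x) x@classes

#' Predicted label per read (argmax posterior, first class on ties)
#' @param x a [PosteriorTable].
#' @return character vector of predicted cell types.
#' @export
predictedLabel <- function(x) {
    x@classes[max.col(x@posterior, ties.method = "first")]
}

setMethod("show", "PosteriorTable", function(object) {
    cat("PosteriorTable:", length(object), "reads,",
        length(object@classes), "classes (",
        paste(object@classes, collapse = ", "), ")\n")
    cat("  priors:", paste(sprintf("%s=%.3f", object@classes,
                                   object@priors), collapse = " "), "\n")
})

setMethod("show", "PurityResult", function(object) {
    cat("PurityResult\n")
    cat(sprintf("  delta_hat (grid MLE): %.4f%s\n", object@deltaHat,
                if (isTRUE(object@flat)) "  [flat likelihood]" else ""))
    if (!is.na(object@adjustedDelta))
        cat(sprintf("  adjusted delta:       %.4f  (G1 %.3f -> %.3f)\n",
                    object@adjustedDelta, object@skewBefore,
                    object@skewAfter))
    cat(sprintf("  regions: %d, Fisher information: %s\n",
                length(object@regionDeltas),
                if (length(object@fisherInformation) == 1L)
                    sprintf("%.3f", object@fisherInformation)
                else sprintf("per-region (n=%d, mean %.3f)",
                             length(object@fisherInformation),
                             mean(object@fisherInformation))))
})

setMethod("show", "CellFractionResult", function(object) {
    cat("CellFractionResult\n")
    for (cl in names(object@fractions))
        cat(sprintf("  %-14s theta=%.3f  reads=%5d  fraction=%.4f\n", cl,
                    object@theta[cl], object@counts[cl],
                    object@fractions[cl]))
})

setMethod("show", "BertModel", function(object) {
    cfg <- object@config
    np <- sum(vapply(object@params, length, numeric(1)))
    cat(sprintf(paste0("BertModel: %d layers, hidden %d, %d heads, ",
                       "seqLen %d, %s parameters%s\n"),
                cfg@nLayers, cfg@hidden, cfg@nHeads, cfg@seqLen,
                format(np, big.mark = ","),
                if (object@pretrained) " (pre-trained)" else ""))
})

setMethod("show", "SimRegionSet", function(object) {
    cat("SimRegionSet:", length(object@ranges), "regions, scenario",
        object@config@scenario, "\n")
})

setMethod("show", "HmmClassifier", function(object) {
    cat("HmmClassifier over classes:",
        paste(object@classes, collapse = ", "), "\n")
})

#' @rdname readAccessors
#' @export
regionRanges <- function(x) x@ranges

#' Purity-result accessors
#' @rdname purityAccessors
#' @param x a [PurityResult].
#' @return the corresponding component.
#' @export
deltaHat <- function(x) x@deltaHat

#' @rdname purityAccessors
#' @export
adjustedDelta <- function(x) x@adjustedDelta

#' @rdname purityAccessors
#' @export
regionDeltas <- function(x) x@regionDeltas

#' @rdname purityAccessors
#' @export
fisherInfo <- function(x) x@fisherInformation
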