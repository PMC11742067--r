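## Shared fixture builders for the test suite. Everything is generated in
## code; no data files.

## A tiny hand-built read set with known CpG calls.
tinyReads <- function() {
    MethylReadSet(
        chrom = c("chr1", "chr1", "chr2"),
        start = c(0L, 10L, 5L),
        sequence = c("TACGTACGTT", "ACGTTTCGGA", "TTTTACGTTT"),
        cpgOffsets = list(c(2L, 6L), c(1L, 6L), 5L),
        cpgStates = list(c(1L, 0L), c(1L, 1L), 0L),
        regionIndex = c(1L, 1L, 2L),
        cellLabel = c("Tumour", "Normal", "Tumour"),
        readId = c("r1", "r2", "r3"))
}

## A tiny model configuration for architecture tests.
tinyTestConfig <- function(seqLen = 10L, nRegions = 4L, hidden = 16L,
                           batchSize = 4L, ...) {
    ModelConfig(nLayers = 2L, nHeads = 2L, hidden = hidden,
                intermediate = 2L * hidden, seqLen = seqLen,
                nRegions = nRegions, classes = c("Tumour", "Normal"),
                batchSize = batchSize, gradAccum = 1L, warmupSteps = 5L,
                decaySteps = 0L, seed = 11L, ...)
}

## Random encoded batch for model-level tests.
randomEncoded <- function(n = 4L, L = 10L, seed = 5L, padTail = 0L) {
    set.seed(seed)
    v <- buildVocabulary()
    msk <- matrix(1L, n, L)
    if (padTail > 0L) msk[1L, (L - padTail + 1L):L] <- 0L
    new("EncodedReads",
        tokenIds = matrix(sample(kmerTokenIds(v), n * L, TRUE), n, L),
        methylCodes = matrix(sample(0:2, n * L, TRUE), n, L),
        attentionMask = msk,
        regionIndex = sample(1:4, n, TRUE),
        cellLabel = sample(c("Tumour", "Normal"), n, TRUE),
        readId = sprintf("rr%02d", seq_len(n)))
}
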