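## Methylation-pattern encoding and read-to-model conversion.

#' Encode per-CpG methylation states onto 3-mer tokens
#'
#' Methylation states are assigned to the 3-mer whose middle base is the CpG
#' cytosine: code 1 for a methylated CpG, 0 for an unmethylated CpG, and 2
#' for every other token. A CpG whose cytosine is the first or last base of
#' the read has no token with that base in the middle; its state cannot be
#' represented and is dropped (reported via a message once per call).
#'
#' @param sequence the read sequence (single DNA string).
#' @param cpgOffsets 0-based offsets of CpG cytosines within `sequence`;
#'   each must point at the C of a CG dinucleotide.
#' @param cpgStates 0/1 methylation states parallel to `cpgOffsets`.
#' @param tokens tokens produced from `sequence` by [tokenizeSequence()];
#'   recomputed when NULL.
#' @return integer vector of methylation codes, one per token.
#' @export
#' @examples
#' encodeMethylation("TACGT", 2L, 1L)  # 2 1 2
encodeMethylation <- function(sequence, cpgOffsets, cpgStates,
                              tokens = NULL) {
    sequence <- as.character(sequence)
    if (is.null(tokens)) tokens <- tokenizeSequence(sequence)
    nTok <- length(tokens)
    codes <- rep(2L, nTok)
    if (length(cpgOffsets) == 0L) return(codes)
    stopifnot(length(cpgOffsets) == length(cpgStates))
    dinuc <- substring(sequence, cpgOffsets + 1L, cpgOffsets + 2L)
    if (any(dinuc != "CG"))
        stop("cpg_call offset ", cpgOffsets[which(dinuc != "CG")[1L]],
             " does not point at the C of a CG dinucleotide")
    ## middle base of token i (1-based) sits at 0-based offset i
    tokIdx <- as.integer(cpgOffsets)
    keep <- tokIdx >= 1L & tokIdx <= nTok
    if (any(!keep))
        message(sum(!keep), " boundary CpG(s) dropped from encoding ",
                "(cytosine at a read end cannot be a token middle base)")
    codes[tokIdx[keep]] <- as.integer(cpgStates[keep])
    codes
}

#' Convert reads into model-ready encoded arrays
#'
#' Tokenises each read into overlapping 3-mers, maps tokens to vocabulary
#' ids (N-containing 3-mers to `[UNK]`), encodes methylation codes via
#' [encodeMethylation()], and pads (with `[PAD]`, code 2, attention 0) or
#' truncates every read to `seqLen` positions.
#'
#' @param reads a [MethylReadSet].
#' @param seqLen model input length in tokens; defaults to the longest
#'   tokenised read.
#' @param vocab a [Vocabulary] (built fresh when NULL).
#' @return An [EncodedReads] object.
#' @export
encodeReads <- function(reads, seqLen = NULL, vocab = NULL) {
    if (is.null(vocab)) vocab <- buildVocabulary()
    n <- length(reads)
    seqs <- as.character(reads@sequence)
    if (is.null(seqLen)) seqLen <- max(nchar(seqs)) - 2L
    seqLen <- as.integer(seqLen)
    padId <- specialTokenIds(vocab)[["[PAD]"]]
    tok <- matrix(padId, n, seqLen)
    met <- matrix(2L, n, seqLen)
    msk <- matrix(0L, n, seqLen)
    for (i in seq_len(n)) {
        tk <- tokenizeSequence(seqs[i])
        cd <- suppressMessages(
            encodeMethylation(seqs[i], reads@cpgOffsets[[i]],
                              reads@cpgStates[[i]], tokens = tk))
        L <- min(length(tk), seqLen)
        tok[i, seq_len(L)] <- tokenToId(vocab, tk[seq_len(L)])
        met[i, seq_len(L)] <- cd[seq_len(L)]
        msk[i, seq_len(L)] <- 1L
    }
    new("EncodedReads", tokenIds = tok, methylCodes = met,
        attentionMask = msk, regionIndex = reads@regionIndex,
        cellLabel = reads@cellLabel, readId = readIds(reads))
}
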