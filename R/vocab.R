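## 3-mer vocabulary and sequence tokenisation.

.SPECIAL_TOKENS <- c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]")

#' Build the fixed 3-mer vocabulary
#'
#' The vocabulary holds the five special tokens (`[PAD]`, `[UNK]`, `[CLS]`,
#' `[SEP]`, `[MASK]`, ids 1..5) followed by the 64 DNA 3-mers in
#' alphabetical order (ids 6..69) - 69 labels in total. The function is
#' deterministic and idempotent.
#'
#' @return A [Vocabulary] object.
#' @export
#' @examples
#' v <- buildVocabulary()
#' vocabSize(v)           # 69
#' tokenToId(v, "ACG")    # fixed id
buildVocabulary <- function() {
    b <- c("A", "C", "G", "T")
    kmers <- as.vector(outer(outer(b, b, paste0), b, paste0))
    kmers <- sort(kmers)
    new("Vocabulary", tokens = c(.SPECIAL_TOKENS, kmers))
}

#' @rdname buildVocabulary
#' @param vocab a [Vocabulary].
#' @export
vocabSize <- function(vocab) length(vocab@tokens)

#' @rdname buildVocabulary
#' @param token character vector of tokens; 3-mers containing `N` (or any
#'   token absent from the vocabulary) map to `[UNK]`.
#' @export
tokenToId <- function(vocab, token) {
    id <- match(token, vocab@tokens)
    id[is.na(id)] <- match("[UNK]", vocab@tokens)
    id
}

#' @rdname buildVocabulary
#' @param id integer vector of token ids (1..69).
#' @export
idToToken <- function(vocab, id) {
    stopifnot(all(id >= 1L & id <= length(vocab@tokens)))
    vocab@tokens[id]
}

#' @rdname buildVocabulary
#' @export
specialTokenIds <- function(vocab) {
    setNames(match(.SPECIAL_TOKENS, vocab@tokens), .SPECIAL_TOKENS)
}

#' @rdname buildVocabulary
#' @export
kmerTokenIds <- function(vocab) {
    setdiff(seq_along(vocab@tokens), specialTokenIds(vocab))
}

#' Tokenise a DNA sequence into overlapping 3-mers
#'
#' Sliding-window 3-mers with stride 1 (DNABERT convention), left to right:
#' a sequence of length L yields L - 2 tokens. Only A/C/G/T/N are accepted;
#' tokens containing N are later mapped to `[UNK]` by [tokenToId()].
#'
#' @param sequence a single DNA string (character or
#'   [Biostrings::DNAString]).
#' @return character vector of `nchar(sequence) - 2` 3-mers.
#' @export
#' @examples
#' tokenizeSequence("ACGTA")  # "ACG" "CGT" "GTA"
tokenizeSequence <- function(sequence) {
    sequence <- as.character(sequence)
    stopifnot(length(sequence) == 1L)
    n <- nchar(sequence)
    if (n < 3L)
        stop("sequence must have length >= 3, got ", n)
    if (grepl("[^ACGTN]", sequence))
        stop("sequence contains characters outside A/C/G/T/N")
    substring(sequence, seq_len(n - 2L), seq_len(n - 2L) + 2L)
}
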