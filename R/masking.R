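## Neighbour-expanded MLM masking.
##
## Seed tokens are selected i.i.d. at the mask rate; each seed and its
## immediate left/right neighbours are marked for the loss and receive the
## seed's corruption category (80% [MASK], 10% random 3-mer, 10%
## unchanged). Masking the neighbours together with the seed prevents the
## model from trivially predicting a masked 3-mer from its two overlapping
## neighbours. When triplets of nearby seeds overlap, the earlier seed's
## category wins for the shared token.

#' Apply masked-language-model corruption to a token batch
#'
#' @param tokenIds integer matrix (reads x positions) of vocabulary ids.
#' @param rate seed-selection rate in (0, 1) (default 0.15); the marked
#'   fraction is about `1 - (1 - rate)^3` after neighbour expansion.
#' @param vocab the [Vocabulary] (for the `[MASK]` id and the 64 3-mer ids
#'   used for random replacement).
#' @param attentionMask optional 0/1 matrix; padded positions are never
#'   selected or marked.
#' @return list with `original`, `corrupted` (integer matrices) and
#'   `maskInd` (0/1 matrix; loss positions).
#' @export
#' @examples
#' v <- buildVocabulary()
#' ids <- matrix(sample(kmerTokenIds(v), 50, TRUE), 5, 10)
#' mb <- applyMlmMasking(ids, 0.15, v)
applyMlmMasking <- function(tokenIds, rate = 0.15, vocab = buildVocabulary(),
                            attentionMask = NULL) {
    stopifnot(rate > 0, rate < 1)
    B <- nrow(tokenIds); L <- ncol(tokenIds)
    if (is.null(attentionMask))
        attentionMask <- matrix(1L, B, L)
    maskId <- specialTokenIds(vocab)[["[MASK]"]]
    kmerIds <- kmerTokenIds(vocab)
    eligible <- which(t(attentionMask) == 1L)  # sample-major linear index
    seeds <- eligible[runif(length(eligible)) < rate]
    maskInd <- matrix(0L, B, L)
    corrupted <- tokenIds
    if (length(seeds)) {
        cat3 <- findInterval(runif(length(seeds)), c(0.8, 0.9)) + 1L
        ## expand to neighbours within the same read's unpadded span
        tgt <- c(seeds - 1L, seeds, seeds + 1L)
        cats <- rep(cat3, 3L)
        ord <- order(rep(seq_along(seeds), 3L))  # seed order, first wins
        tgt <- tgt[ord]; cats <- cats[ord]
        pos <- (tgt - 1L) %% L + 1L
        sameRead <- ((tgt - 1L) %/% L) == ((rep(seeds, each = 3L) - 1L) %/% L)
        ok <- tgt >= 1L & tgt <= B * L & sameRead
        tgt <- tgt[ok]; cats <- cats[ok]; pos <- pos[ok]
        read <- (tgt - 1L) %/% L + 1L
        unpadded <- attentionMask[cbind(read, pos)] == 1L
        tgt <- tgt[unpadded]; cats <- cats[unpadded]
        keep <- !duplicated(tgt)
        tgt <- tgt[keep]; cats <- cats[keep]
        pos <- (tgt - 1L) %% L + 1L
        read <- (tgt - 1L) %/% L + 1L
        idx <- cbind(read, pos)
        maskInd[idx] <- 1L
        isMask <- cats == 1L
        isRand <- cats == 2L
        corrupted[idx[isMask, , drop = FALSE]] <- maskId
        if (any(isRand))
            corrupted[idx[isRand, , drop = FALSE]] <-
                sample(kmerIds, sum(isRand), replace = TRUE)
    }
    list(original = tokenIds, corrupted = corrupted, maskInd = maskInd)
}
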