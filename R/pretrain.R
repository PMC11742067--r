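## MLM pre-training on fixed-length genome segments.

#' Synthesize a random genome sequence
#'
#' Uniform A/C/G/T sequence used as a pre-training corpus when no reference
#' FASTA is at hand (all bench experiments pre-train on such synthetic
#' genomes).
#'
#' @param nBases genome length in bp.
#' @param seed integer seed.
#' @return a single character string.
#' @export
synthesizeGenome <- function(nBases, seed = 1L) {
    set.seed(seed)
    paste(sample(c("A", "C", "G", "T"), nBases, replace = TRUE),
          collapse = "")
}

#' Build an MLM pre-training corpus from genome sequence
#'
#' Splits the genome into fixed-length segments (510 bp at full scale), tokenises each into overlapping 3-mers and encodes them with
#' all-non-CpG methylation codes (methylation embeddings are zeroed during
#' pre-training anyway).
#'
#' @param genome character vector or [Biostrings::DNAStringSet] of
#'   chromosome sequences.
#' @param segmentLength segment length in bp.
#' @param vocab a [Vocabulary].
#' @return An [EncodedReads] object (one row per segment).
#' @export
makePretrainCorpus <- function(genome, segmentLength = 510L,
                               vocab = buildVocabulary()) {
    genome <- as.character(genome)
    segs <- unlist(lapply(genome, function(g) {
        n <- nchar(g)
        starts <- seq(1L, n - segmentLength + 1L, by = segmentLength)
        substring(g, starts, starts + segmentLength - 1L)
    }))
    if (length(segs) == 0L) stop("genome too short for one segment")
    L <- segmentLength - 2L
    tok <- t(vapply(segs, function(s)
        tokenToId(vocab, tokenizeSequence(s)), integer(L)))
    dimnames(tok) <- NULL
    new("EncodedReads", tokenIds = tok,
        methylCodes = matrix(2L, nrow(tok), L),
        attentionMask = matrix(1L, nrow(tok), L),
        regionIndex = rep(NA_integer_, nrow(tok)),
        cellLabel = rep(NA_character_, nrow(tok)),
        readId = sprintf("segment_%05d", seq_len(nrow(tok))))
}

#' Pre-train a model with the masked language model
#'
#' Runs MLM training: per step a batch of segments is drawn, corrupted by
#' [applyMlmMasking()], and the categorical cross-entropy on the masked
#' tokens is minimised with AdamW under the warm-up/flat/decay schedule.
#' Methylation embeddings are held at zero throughout. Fully seeded: two
#' runs from the same model and seed give identical loss traces.
#'
#' @param model a freshly initialised [BertModel].
#' @param corpus an [EncodedReads] corpus from [makePretrainCorpus()].
#' @param steps number of optimisation steps.
#' @param seed seed for batch order and masking (defaults to the model
#'   config seed).
#' @param batchSize segments per step (defaults to the config batch size;
#'   small corpora profit from smaller MLM batches, i.e. more distinct
#'   update directions for the same step count).
#' @return list with `model` (pre-trained) and `trace` (data.frame of step,
#'   learning rate, mean masked-token loss).
#' @export
pretrainModel <- function(model, corpus, steps,
                          seed = model@config@seed,
                          batchSize = model@config@batchSize) {
    if (length(corpus) == 0L) stop("empty pre-training corpus")
    cfg <- model@config
    if (ncol(corpus@tokenIds) > cfg@seqLen)
        stop("corpus segments exceed the model sequence length")
    set.seed(seed)
    params <- model@params
    state <- .adamInit(params)
    bs <- min(batchSize, length(corpus))
    trace <- data.frame(step = integer(steps), lr = numeric(steps),
                        loss = numeric(steps))
    for (s in seq_len(steps)) {
        lr <- lrSchedule(s, steps, cfg@lr, cfg@warmupSteps, cfg@decaySteps)
        grads <- NULL
        lossAcc <- 0; maskAcc <- 0
        for (acc in seq_len(cfg@gradAccum)) {
            idx <- sample.int(length(corpus), bs)
            batch <- corpus[idx]
            mb <- applyMlmMasking(batch@tokenIds, cfg@maskRate, model@vocab,
                                  batch@attentionMask)
            corrupt <- batch
            corrupt@tokenIds <- mb$corrupted
            fw <- .encoderForward(params, cfg, corrupt, pretrainMode = TRUE)
            maskVec <- as.vector(t(mb$maskInd)) == 1L
            nMask <- sum(maskVec)
            if (nMask == 0L) next
            Hsub <- fw$H[maskVec, , drop = FALSE]
            mh <- .mlmHeadForward(params, Hsub)
            target <- as.vector(t(mb$original))[maskVec]
            ls <- .logSoftmaxRows(mh$logits)
            lossAcc <- lossAcc - sum(ls[cbind(seq_len(nMask), target)])
            maskAcc <- maskAcc + nMask
            dlogits <- .softmaxGrad(mh$logits, target) / nMask /
                cfg@gradAccum
            hb <- .mlmHeadBackward(dlogits, mh, params, Hsub)
            dH <- matrix(0, nrow(fw$H), ncol(fw$H))
            dH[maskVec, ] <- hb$dHsub
            gEnc <- .encoderBackward(dH, fw, params, cfg, corrupt)
            gAll <- c(hb$grads, gEnc)
            grads <- if (is.null(grads)) gAll
                     else Map(`+`, grads, gAll[names(grads)])
        }
        if (!is.null(grads)) {
            st <- .adamStep(params, grads, state, lr, cfg@beta1, cfg@beta2,
                            cfg@weightDecay)
            params <- st$params
            state <- st$state
        }
        trace$step[s] <- s
        trace$lr[s] <- lr
        trace$loss[s] <- if (maskAcc > 0) lossAcc / maskAcc else NA_real_
    }
    model@params <- params
    model@pretrained <- TRUE
    list(model = model, trace = trace)
}
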