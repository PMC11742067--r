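## Fine-tuning the encoder + classifier head on labelled reads.

.labelIndex <- function(labels, classes) {
    idx <- match(labels, classes)
    if (anyNA(idx))
        stop("labels outside the model's class set: ",
             paste(unique(labels[is.na(idx)]), collapse = ", "))
    idx
}

#' Fine-tune a model for read-level cell-type classification
#'
#' Trains the full network (embeddings, encoder, DMR embedding, classifier
#' head) on labelled encoded reads with AdamW, using the softmax
#' cross-entropy loss or the focal loss. A seeded validation split is held
#' out; validation accuracy is recorded every `evalEvery` steps (on a fixed
#' subset of at most `evalMax` validation reads) and the weights with the
#' best recorded validation accuracy are kept. Class priors P(cell type)
#' are recorded from the training-split label frequencies.
#'
#' @param model a [BertModel] (pre-trained or freshly initialised).
#' @param encoded labelled [EncodedReads]; labels must be a subset of the
#'   model's configured classes, with at least two classes present.
#' @param steps number of optimisation steps (600 or 1000 in the
#'   full-scale setting; default 600).
#' @param lossMode `"cross_entropy"` or `"focal"`.
#' @param gamma,alphaF focal-loss hyper-parameters (used in focal mode).
#' @param valFraction held-out fraction for validation.
#' @param evalEvery evaluation cadence in steps.
#' @param evalMax maximum validation reads used for the periodic metric.
#' @param keepBest return the weights of the best evaluation step rather
#'   than the last step.
#' @param seed seed for the split and batch order (defaults to config).
#' @return list with `model` (fine-tuned, priors attached), `trace`
#'   (step, lr, mean train loss, validation accuracy), `priors`,
#'   `valIndex` (indices of the held-out reads) and `valAccuracy` (final
#'   full-validation accuracy of the returned weights).
#' @export
finetuneModel <- function(model, encoded, steps = 600L,
                          lossMode = c("cross_entropy", "focal"),
                          gamma = 2, alphaF = 0.1, valFraction = 0.25,
                          evalEvery = 10L, evalMax = 160L, keepBest = TRUE,
                          seed = model@config@seed) {
    lossMode <- match.arg(lossMode)
    cfg <- model@config
    labAll <- encoded@cellLabel
    if (anyNA(labAll)) stop("all reads must carry a cell label")
    if (length(unique(labAll)) < 2L)
        stop("fine-tuning needs at least two cell types in the input")
    yAll <- .labelIndex(labAll, cfg@classes)
    n <- length(encoded)
    set.seed(seed)
    valIdx <- sort(sample.int(n, max(1L, round(n * valFraction))))
    trainIdx <- setdiff(seq_len(n), valIdx)
    priors <- table(factor(cfg@classes[yAll[trainIdx]],
                           levels = cfg@classes))
    priors <- as.numeric(priors) / length(trainIdx)
    names(priors) <- cfg@classes
    if (any(priors == 0))
        stop("every configured class must appear in the training split")
    evalIdx <- if (length(valIdx) > evalMax)
        sort(sample(valIdx, evalMax)) else valIdx

    params <- model@params
    state <- .adamInit(params)
    bs <- min(cfg@batchSize, length(trainIdx))
    nEval <- floor(steps / evalEvery)
    trace <- data.frame(step = integer(0), lr = numeric(0),
                        trainLoss = numeric(0), valAccuracy = numeric(0))
    bestAcc <- -1
    bestParams <- params
    for (s in seq_len(steps)) {
        lr <- lrSchedule(s, steps, cfg@lr, cfg@warmupSteps, cfg@decaySteps)
        grads <- NULL
        lossAcc <- 0; nAcc <- 0
        for (acc in seq_len(cfg@gradAccum)) {
            idx <- trainIdx[sample.int(length(trainIdx), bs)]
            batch <- encoded[idx]
            y <- yAll[idx]
            fw <- .encoderForward(params, cfg, batch)
            cl <- .classifierForward(params, cfg, fw, batch)
            if (lossMode == "cross_entropy") {
                loss <- finetuneLoss(cl$logits, y)
                dlogits <- .softmaxGrad(cl$logits, y)
            } else {
                loss <- focalLoss(cl$logits, y, gamma, alphaF)
                dlogits <- .focalGrad(cl$logits, y, gamma, alphaF)
            }
            dlogits <- dlogits / bs / cfg@gradAccum
            lossAcc <- lossAcc + loss
            nAcc <- nAcc + bs
            cb <- .classifierBackward(dlogits, cl, params, cfg, fw, batch)
            gEnc <- .encoderBackward(cb$dH, fw, params, cfg, batch)
            gAll <- c(cb$grads, gEnc)
            grads <- if (is.null(grads)) gAll
                     else Map(`+`, grads, gAll[names(grads)])
        }
        st <- .adamStep(params, grads, state, lr, cfg@beta1, cfg@beta2,
                        cfg@weightDecay)
        params <- st$params
        state <- st$state
        if (s %% evalEvery == 0L || s == steps) {
            acc <- .evalAccuracy(params, cfg, encoded[evalIdx],
                                 yAll[evalIdx], lossMode)
            trace <- rbind(trace, data.frame(
                step = s, lr = lr, trainLoss = lossAcc / nAcc,
                valAccuracy = acc))
            if (keepBest && acc > bestAcc) {
                bestAcc <- acc
                bestParams <- params
            }
        }
    }
    model@params <- if (keepBest) bestParams else params
    finalAcc <- .evalAccuracy(model@params, cfg, encoded[valIdx],
                              yAll[valIdx], lossMode)
    list(model = model, trace = trace, priors = priors, valIndex = valIdx,
         valAccuracy = finalAcc)
}

.evalAccuracy <- function(params, cfg, encoded, y, lossMode,
                          batchSize = 64L) {
    pred <- .predictLogits(params, cfg, encoded, batchSize)
    mean(max.col(pred, ties.method = "first") == y)
}

.predictLogits <- function(params, cfg, encoded, batchSize = 64L) {
    n <- length(encoded)
    out <- matrix(NA_real_, n, length(cfg@classes))
    for (startI in seq(1L, n, by = batchSize)) {
        idx <- startI:min(startI + batchSize - 1L, n)
        batch <- encoded[idx]
        fw <- .encoderForward(params, cfg, batch)
        cl <- .classifierForward(params, cfg, fw, batch)
        out[idx, ] <- cl$logits
    }
    out
}

#' Classify reads with a fine-tuned model
#'
#' Runs the encoder and classifier head over the reads and returns the
#' per-read posterior probabilities: the softmax of the class activations
#' (cross-entropy mode), or the per-class sigmoids normalised to sum to one
#' (focal mode). Unseen region indices fall back to the reserved
#' "unknown region" embedding row.
#'
#' @param model a fine-tuned [BertModel].
#' @param encoded an [EncodedReads] batch.
#' @param priors class priors to record in the table (training-set label
#'   frequencies; uniform when NULL).
#' @param lossMode posterior mode, matching the fine-tuning loss.
#' @param batchSize forward-pass batch size.
#' @return A [PosteriorTable] (true labels carried over when present).
#' @export
classifyReads <- function(model, encoded, priors = NULL,
                          lossMode = c("cross_entropy", "focal"),
                          batchSize = 64L) {
    lossMode <- match.arg(lossMode)
    cfg <- model@config
    logits <- .predictLogits(model@params, cfg, encoded, batchSize)
    post <- if (lossMode == "cross_entropy") exp(.logSoftmaxRows(logits))
            else {
                p <- plogis(logits)
                p / rowSums(p)
            }
    if (is.null(priors))
        priors <- rep(1 / length(cfg@classes), length(cfg@classes))
    PosteriorTable(readId = encoded@readId,
                   regionIndex = encoded@regionIndex, posterior = post,
                   priors = priors, classes = cfg@classes,
                   trueLabel = encoded@cellLabel)
}
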