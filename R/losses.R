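## Loss functions: MLM cross-entropy, fine-tuning cross-entropy, focal loss.
## Exported losses follow the sum-reduction formulas; the training loops
## scale gradients by 1/batch for step-size stability (documented in the
## methods vignette).

.logSoftmaxRows <- function(logits) {
    m <- apply(logits, 1L, max)
    s <- logits - m
    s - log(rowSums(exp(s)))
}

#' Masked-language-model loss
#'
#' Categorical cross-entropy `-sum_t sum_l m^t y^t_l log yhat^t_l` over all
#' tokens, where `m^t` marks masked tokens, `y` is the one-hot original
#' token and `yhat` the softmax-normalised prediction. Non-masked tokens
#' contribute zero.
#'
#' @param logits numeric matrix T x vocabSize: one row per token position
#'   (sample-major flattening of the batch).
#' @param maskedBatch the list returned by [applyMlmMasking()] (`original`,
#'   `corrupted`, `maskInd` matrices).
#' @return the summed loss (numeric scalar).
#' @export
mlmLoss <- function(logits, maskedBatch) {
    mask <- as.vector(t(maskedBatch$maskInd)) == 1L
    if (!any(mask)) return(0)
    target <- as.vector(t(maskedBatch$original))[mask]
    ls <- .logSoftmaxRows(logits[mask, , drop = FALSE])
    -sum(ls[cbind(seq_along(target), target)])
}

#' Fine-tuning cross-entropy loss
#'
#' `-sum_r sum_c m_{r,c} log softmax(x_r)_c` over reads, with one-hot
#' cell-type labels (sum reduction).
#'
#' @param logits numeric matrix R x C of final activations `x_r`.
#' @param labels integer class indices (1..C) per read.
#' @return the summed loss.
#' @export
finetuneLoss <- function(logits, labels) {
    stopifnot(all(labels >= 1L & labels <= ncol(logits)))
    ls <- .logSoftmaxRows(logits)
    -sum(ls[cbind(seq_along(labels), labels)])
}

.softmaxGrad <- function(logits, labels) {
    P <- exp(.logSoftmaxRows(logits))
    P[cbind(seq_along(labels), labels)] <-
        P[cbind(seq_along(labels), labels)] - 1
    P
}

#' Focal loss for class-imbalanced multi-class classification
#'
#' Per read and class, with `p = sigmoid(x_c)`:
#' `-alphaF * (1 - p)^gamma * log(p)` for the read's own cell type and
#' `-(1 - alphaF) * p^gamma * log(1 - p)` for every other class (the
#' original focal-loss formulation with per-class sigmoids). With
#' `gamma = 0, alphaF = 0.5` it reduces to half the sigmoid binary
#' cross-entropy. The leukocyte deconvolution setting is `gamma = 2`,
#' `alphaF = 0.1`.
#'
#' @param logits numeric matrix R x C of activations.
#' @param labels integer class indices (1..C) per read.
#' @param gamma focusing parameter, >= 0.
#' @param alphaF class-balance weight in (0, 1).
#' @return the summed loss.
#' @export
focalLoss <- function(logits, labels, gamma = 2, alphaF = 0.1) {
    stopifnot(gamma >= 0, alphaF > 0, alphaF < 1)
    p <- plogis(logits)
    Y <- matrix(0, nrow(logits), ncol(logits))
    Y[cbind(seq_along(labels), labels)] <- 1
    pos <- -alphaF * (1 - p)^gamma * log(pmax(p, 1e-12))
    neg <- -(1 - alphaF) * p^gamma * log(pmax(1 - p, 1e-12))
    sum(Y * pos + (1 - Y) * neg)
}

## d focalLoss / d logits (sum reduction).
.focalGrad <- function(logits, labels, gamma, alphaF) {
    p <- plogis(logits)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    Y <- matrix(0, nrow(logits), ncol(logits))
    Y[cbind(seq_along(labels), labels)] <- 1
    dpos <- alphaF * (gamma * (1 - p)^(gamma - 1) * log(p) -
                      (1 - p)^gamma / p)
    dneg <- -(1 - alphaF) * (gamma * p^(gamma - 1) * log(1 - p) -
                             p^gamma / (1 - p))
    (Y * dpos + (1 - Y) * dneg) * p * (1 - p)
}
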