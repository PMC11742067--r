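## AdamW and the learning-rate schedule (linear warm-up, flat, linear decay
## over the final decaySteps).

.adamInit <- function(params) {
    list(m = lapply(params, function(p) p * 0),
         v = lapply(params, function(p) p * 0), t = 0L)
}

## Decoupled weight decay on matrix-shaped parameters only (biases and
## LayerNorm vectors are excluded, as is standard for BERT-style training).
.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.98,
                      weightDecay = 0.01, eps = 1e-8) {
    state$t <- state$t + 1L
    t <- state$t
    for (nm in names(grads)) {
        gr <- grads[[nm]]
        state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
        state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr * gr
        mh <- state$m[[nm]] / (1 - beta1^t)
        vh <- state$v[[nm]] / (1 - beta2^t)
        upd <- mh / (sqrt(vh) + eps)
        if (is.matrix(params[[nm]]) && weightDecay > 0)
            upd <- upd + weightDecay * params[[nm]]
        params[[nm]] <- params[[nm]] - lr * upd
    }
    list(params = params, state = state)
}

#' Learning rate at a given step
#'
#' Linear warm-up to the base rate over `warmupSteps`, flat in the middle,
#' linear decay to zero over the final `decaySteps`.
#'
#' @param step current step (1-based).
#' @param totalSteps total training steps.
#' @param lr base learning rate.
#' @param warmupSteps,decaySteps schedule segments.
#' @return the scheduled learning rate.
#' @export
lrSchedule <- function(step, totalSteps, lr, warmupSteps, decaySteps) {
    if (warmupSteps > 0 && step <= warmupSteps)
        return(lr * step / warmupSteps)
    if (decaySteps > 0 && step > totalSteps - decaySteps)
        return(lr * max(0, totalSteps - step) / decaySteps)
    lr
}
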