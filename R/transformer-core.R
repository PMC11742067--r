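## Transformer primitives: scaled dot-product attention, multi-head
## attention, GELU and LayerNorm, with hand-derived backward passes.
## All heavy lifting is dense matrix algebra through BLAS.

.softmaxRows <- function(S) {
    E <- exp(S - max(S))   # global shift: softmax is row-shift invariant and
    E / rowSums(E)         # scores are bounded, so this is safe and cheap
}

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V` with an optional key mask. Rows of the
#' softmax weight matrix sum to one; masked keys receive zero weight.
#'
#' @param Q,K,V numeric matrices; `Q` is n_q x d_k, `K` n_k x d_k, `V`
#'   n_k x d_v.
#' @param keyMask optional logical/0-1 vector of length n_k; keys with 0
#'   are excluded from attention.
#' @return n_q x d_v output matrix.
#' @export
#' @examples
#' Q <- matrix(rnorm(8), 2, 4); K <- matrix(rnorm(12), 3, 4)
#' V <- matrix(rnorm(6), 3, 2)
#' scaledAttention(Q, K, V)
scaledAttention <- function(Q, K, V, keyMask = NULL) {
    if (ncol(Q) != ncol(K) || nrow(K) != nrow(V))
        stop("Q/K/V dimensions are not conformable")
    dk <- ncol(K)
    if (dk < 1L) stop("key dimension must be positive")
    S <- Q %*% t(K) / sqrt(dk)
    if (!is.null(keyMask))
        S[, !as.logical(keyMask)] <- -1e9
    .softmaxRows(S) %*% V
}

#' Multi-head attention
#'
#' Computes `H` attention heads `A_i = Attention(Q Wq_i, K Wk_i, V Wv_i)`,
#' concatenates them and projects by `Wo`.
#'
#' @param Q,K,V input matrices (n x d_model).
#' @param weights list with elements `Wq`, `Wk`, `Wv` (each a list of H
#'   per-head projection matrices d_model x d_head) and `Wo`
#'   ((H * d_head) x d_out).
#' @param keyMask optional key mask as in [scaledAttention()].
#' @return n x d_out output matrix.
#' @export
multiHeadAttention <- function(Q, K, V, weights, keyMask = NULL) {
    H <- length(weights$Wq)
    heads <- lapply(seq_len(H), function(i)
        scaledAttention(Q %*% weights$Wq[[i]], K %*% weights$Wk[[i]],
                        V %*% weights$Wv[[i]], keyMask = keyMask))
    do.call(cbind, heads) %*% weights$Wo
}

.gelu <- function(x) x * pnorm(x)
.geluGrad <- function(x) pnorm(x) + x * dnorm(x)

## forward caching Phi = pnorm(x) so the backward pass reuses it
.geluFwd <- function(x) cpp_gelu_forward(x)
.geluBwdFromCache <- function(x, Phi) cpp_gelu_grad(x, Phi)

## LayerNorm over the feature (column) dimension, per row.
.lnForward <- function(x, g, b, eps = 1e-6) {
    cpp_layernorm_forward(x, g, b, eps)
}

.lnBackward <- function(dy, cache, g) {
    out <- cpp_layernorm_backward(dy, cache$xhat, cache$invstd, g)
    out$dg <- as.vector(out$dg)
    out$db <- as.vector(out$db)
    out
}

.addBias <- function(M, b) M + b[col(M)]

## Self-attention over a sample-major stacked batch (rows = B blocks of L),
## delegated to the RcppArmadillo kernel. padAdd is the B x L additive key
## mask (0 real, -1e9 padded).
.selfAttention <- function(Q, K, V, B, L, nHeads, padAdd) {
    cpp_attention_forward(Q, K, V, B, L, nHeads, padAdd)
}

.selfAttentionBackward <- function(dA, Q, K, V, P, B, L, nHeads) {
    cpp_attention_backward(dA, Q, K, V, P, B, L, nHeads)
}
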