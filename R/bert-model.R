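## Model assembly: parameter initialisation, input embeddings, the encoder
## stack with caches for backpropagation, and the MLM / classifier heads.
##
## Parameters live in a flat named list; gradients mirror its structure.
## Batches are stacked sample-major: row (b-1)*L + l is position l of read b.

.initMat <- function(nr, nc, sd = 0.02) matrix(rnorm(nr * nc, sd = sd), nr, nc)

#' Initialise a BERT-style model
#'
#' Token (69), methylation (3) and position embeddings, `nLayers` encoder
#' layers (post-LayerNorm, GELU feed-forward of width `intermediate`), an
#' MLM head, a DMR-embedding table of dimension `seqLen` with one reserved
#' row for unseen region indices, and a two-layer classifier head over the
#' mean-pooled, DMR-augmented encoder output. Weights are Gaussian(0, 0.02),
#' biases zero.
#'
#' @param config a [ModelConfig].
#' @param vocab a [Vocabulary] (default-built when NULL).
#' @return A [BertModel].
#' @export
initModel <- function(config, vocab = NULL) {
    if (is.null(vocab)) vocab <- buildVocabulary()
    set.seed(config@seed)
    h <- config@hidden; f <- config@intermediate; L <- config@seqLen
    V <- vocabSize(vocab); C <- length(config@classes)
    p <- list(tokEmb = .initMat(V, h), methEmb = .initMat(3L, h),
              posEmb = .initMat(L, h),
              embLNg = rep(1, h), embLNb = rep(0, h))
    for (i in seq_len(config@nLayers)) {
        pre <- sprintf("L%d.", i)
        p[[paste0(pre, "Wq")]] <- .initMat(h, h)
        p[[paste0(pre, "bq")]] <- rep(0, h)
        p[[paste0(pre, "Wk")]] <- .initMat(h, h)
        p[[paste0(pre, "bk")]] <- rep(0, h)
        p[[paste0(pre, "Wv")]] <- .initMat(h, h)
        p[[paste0(pre, "bv")]] <- rep(0, h)
        p[[paste0(pre, "Wo")]] <- .initMat(h, h)
        p[[paste0(pre, "bo")]] <- rep(0, h)
        p[[paste0(pre, "ln1g")]] <- rep(1, h)
        p[[paste0(pre, "ln1b")]] <- rep(0, h)
        p[[paste0(pre, "W1")]] <- .initMat(h, f)
        p[[paste0(pre, "b1")]] <- rep(0, f)
        p[[paste0(pre, "W2")]] <- .initMat(f, h)
        p[[paste0(pre, "b2")]] <- rep(0, h)
        p[[paste0(pre, "ln2g")]] <- rep(1, h)
        p[[paste0(pre, "ln2b")]] <- rep(0, h)
    }
    p$mlmW <- .initMat(h, h); p$mlmb <- rep(0, h)
    p$mlmLNg <- rep(1, h); p$mlmLNb <- rep(0, h)
    p$mlmDec <- .initMat(h, V); p$mlmDecb <- rep(0, V)
    p$regEmb <- .initMat(config@nRegions + 1L, L)
    p$headW1 <- .initMat(h + 1L, h); p$headb1 <- rep(0, h)
    p$headW2 <- .initMat(h, C); p$headb2 <- rep(0, C)
    new("BertModel", config = config, vocab = vocab, params = p,
        pretrained = FALSE)
}

#' Input embeddings of encoded reads
#'
#' Per position the token, methylation and position embeddings are summed.
#' In pre-training mode the methylation contribution is forced to zero
#' (reference genomes carry no methylation).
#'
#' @param model a [BertModel].
#' @param encoded an [EncodedReads] batch.
#' @param pretrainMode logical; zero out the methylation embeddings.
#' @return numeric matrix (nReads * seqLen) x hidden, sample-major rows.
#' @export
embedInputs <- function(model, encoded, pretrainMode = FALSE) {
    p <- model@params
    ids <- encoded@tokenIds
    B <- nrow(ids); L <- ncol(ids)
    if (L > model@config@seqLen)
        stop("encoded length exceeds the model sequence length")
    idsVec <- as.vector(t(ids))
    X <- p$tokEmb[idsVec, , drop = FALSE] +
        p$posEmb[rep(seq_len(L), B), , drop = FALSE]
    if (!pretrainMode) {
        codes <- as.vector(t(encoded@methylCodes))
        if (!all(codes %in% c(0L, 1L, 2L)))
            stop("methylation codes outside {0, 1, 2}")
        X <- X + p$methEmb[codes + 1L, , drop = FALSE]
    }
    X
}

## Full encoder forward with caches. Returns H (BL x h) and everything the
## backward pass needs.
.encoderForward <- function(params, config, encoded, pretrainMode = FALSE,
                            model = NULL) {
    B <- nrow(encoded@tokenIds); L <- ncol(encoded@tokenIds)
    mdl <- new("BertModel", config = config, vocab = buildVocabulary(),
               params = params, pretrained = FALSE)
    X0 <- embedInputs(mdl, encoded, pretrainMode = pretrainMode)
    padAdd <- (1 - encoded@attentionMask) * -1e9
    lnE <- .lnForward(X0, params$embLNg, params$embLNb)
    X <- lnE$y
    layers <- vector("list", config@nLayers)
    for (i in seq_len(config@nLayers)) {
        pre <- sprintf("L%d.", i)
        h <- config@hidden
        QKV <- .addBias(X %*% cbind(params[[paste0(pre, "Wq")]],
                                    params[[paste0(pre, "Wk")]],
                                    params[[paste0(pre, "Wv")]]),
                        c(params[[paste0(pre, "bq")]],
                          params[[paste0(pre, "bk")]],
                          params[[paste0(pre, "bv")]]))
        Q <- QKV[, seq_len(h), drop = FALSE]
        K <- QKV[, h + seq_len(h), drop = FALSE]
        V <- QKV[, 2L * h + seq_len(h), drop = FALSE]
        att <- .selfAttention(Q, K, V, B, L, config@nHeads, padAdd)
        O <- .addBias(att$A %*% params[[paste0(pre, "Wo")]],
                      params[[paste0(pre, "bo")]])
        R1 <- X + O
        ln1 <- .lnForward(R1, params[[paste0(pre, "ln1g")]],
                          params[[paste0(pre, "ln1b")]])
        X1 <- ln1$y
        Z <- .addBias(X1 %*% params[[paste0(pre, "W1")]],
                      params[[paste0(pre, "b1")]])
        gf <- .geluFwd(Z)
        Fv <- gf$y
        Y <- .addBias(Fv %*% params[[paste0(pre, "W2")]],
                      params[[paste0(pre, "b2")]])
        ln2 <- .lnForward(X1 + Y, params[[paste0(pre, "ln2g")]],
                          params[[paste0(pre, "ln2b")]])
        layers[[i]] <- list(X = X, Q = Q, K = K, V = V, P = att$P, A = att$A,
                            ln1 = ln1, X1 = X1, Z = Z, Fv = Fv,
                            Phi = gf$Phi, ln2 = ln2)
        X <- ln2$y
    }
    list(H = X, X0 = X0, lnE = lnE, layers = layers, B = B, L = L,
         pretrainMode = pretrainMode)
}

## Backward through the encoder stack. dH: gradient at the encoder output.
## Returns flat gradient list for all encoder + embedding parameters.
.encoderBackward <- function(dH, fw, params, config, encoded) {
    B <- fw$B; L <- fw$L
    g <- list()
    dX <- dH
    for (i in rev(seq_len(config@nLayers))) {
        pre <- sprintf("L%d.", i)
        cc <- fw$layers[[i]]
        bl2 <- .lnBackward(dX, cc$ln2, params[[paste0(pre, "ln2g")]])
        g[[paste0(pre, "ln2g")]] <- bl2$dg
        g[[paste0(pre, "ln2b")]] <- bl2$db
        dR2 <- bl2$dx
        dY <- dR2
        g[[paste0(pre, "W2")]] <- crossprod(cc$Fv, dY)
        g[[paste0(pre, "b2")]] <- colSums(dY)
        dF <- tcrossprod(dY, params[[paste0(pre, "W2")]])
        dZ <- dF * .geluBwdFromCache(cc$Z, cc$Phi)
        g[[paste0(pre, "W1")]] <- crossprod(cc$X1, dZ)
        g[[paste0(pre, "b1")]] <- colSums(dZ)
        dX1 <- dR2 + tcrossprod(dZ, params[[paste0(pre, "W1")]])
        bl1 <- .lnBackward(dX1, cc$ln1, params[[paste0(pre, "ln1g")]])
        g[[paste0(pre, "ln1g")]] <- bl1$dg
        g[[paste0(pre, "ln1b")]] <- bl1$db
        dR1 <- bl1$dx
        dO <- dR1
        g[[paste0(pre, "Wo")]] <- crossprod(cc$A, dO)
        g[[paste0(pre, "bo")]] <- colSums(dO)
        dA <- tcrossprod(dO, params[[paste0(pre, "Wo")]])
        bAtt <- .selfAttentionBackward(dA, cc$Q, cc$K, cc$V, cc$P, B, L,
                                       config@nHeads)
        h <- config@hidden
        dQKV <- cbind(bAtt$dQ, bAtt$dK, bAtt$dV)
        gW <- crossprod(cc$X, dQKV)
        g[[paste0(pre, "Wq")]] <- gW[, seq_len(h), drop = FALSE]
        g[[paste0(pre, "bq")]] <- colSums(bAtt$dQ)
        g[[paste0(pre, "Wk")]] <- gW[, h + seq_len(h), drop = FALSE]
        g[[paste0(pre, "bk")]] <- colSums(bAtt$dK)
        g[[paste0(pre, "Wv")]] <- gW[, 2L * h + seq_len(h), drop = FALSE]
        g[[paste0(pre, "bv")]] <- colSums(bAtt$dV)
        dX <- dR1 + dQKV %*% t(cbind(params[[paste0(pre, "Wq")]],
                                     params[[paste0(pre, "Wk")]],
                                     params[[paste0(pre, "Wv")]]))
    }
    blE <- .lnBackward(dX, fw$lnE, params$embLNg)
    g$embLNg <- blE$dg
    g$embLNb <- blE$db
    dX0 <- blE$dx
    idsVec <- as.vector(t(encoded@tokenIds))
    gTok <- rowsum(dX0, group = idsVec)
    g$tokEmb <- matrix(0, nrow(params$tokEmb), ncol(params$tokEmb))
    g$tokEmb[as.integer(rownames(gTok)), ] <- gTok
    gPos <- rowsum(dX0, group = rep(seq_len(L), B))
    g$posEmb <- matrix(0, nrow(params$posEmb), ncol(params$posEmb))
    g$posEmb[as.integer(rownames(gPos)), ] <- gPos
    g$methEmb <- matrix(0, 3L, ncol(params$methEmb))
    if (!fw$pretrainMode) {
        codes <- as.vector(t(encoded@methylCodes))
        gM <- rowsum(dX0, group = codes + 1L)
        g$methEmb[as.integer(rownames(gM)), ] <- gM
    }
    g
}

## MLM head on selected (masked) rows of the encoder output.
.mlmHeadForward <- function(params, Hsub) {
    Z <- .addBias(Hsub %*% params$mlmW, params$mlmb)
    gf <- .geluFwd(Z)
    Fv <- gf$y
    ln <- .lnForward(Fv, params$mlmLNg, params$mlmLNb)
    logits <- .addBias(ln$y %*% params$mlmDec, params$mlmDecb)
    list(logits = logits, Z = Z, Phi = gf$Phi, ln = ln)
}

.mlmHeadBackward <- function(dlogits, cache, params, Hsub) {
    g <- list()
    g$mlmDec <- crossprod(cache$ln$y, dlogits)
    g$mlmDecb <- colSums(dlogits)
    dLn <- tcrossprod(dlogits, params$mlmDec)
    bl <- .lnBackward(dLn, cache$ln, params$mlmLNg)
    g$mlmLNg <- bl$dg; g$mlmLNb <- bl$db
    dZ <- bl$dx * .geluBwdFromCache(cache$Z, cache$Phi)
    g$mlmW <- crossprod(Hsub, dZ)
    g$mlmb <- colSums(dZ)
    list(grads = g, dHsub = tcrossprod(dZ, params$mlmW))
}

## Classifier head: append the DMR-embedding channel, mean-pool over
## unpadded positions, two-layer feed-forward to class logits.
.regionRow <- function(config, regionIndex) {
    r <- as.integer(regionIndex)
    r[is.na(r) | r < 1L | r > config@nRegions] <- config@nRegions + 1L
    r
}

.classifierForward <- function(params, config, fw, encoded) {
    B <- fw$B; L <- fw$L
    rows <- .regionRow(config, encoded@regionIndex)
    regChan <- as.vector(t(params$regEmb[rows, seq_len(L), drop = FALSE]))
    Hc <- cbind(fw$H, regChan)
    maskVec <- as.vector(t(encoded@attentionMask))
    w <- maskVec / rep(rowSums(encoded@attentionMask), each = L)
    pooled <- rowsum(Hc * w, group = rep(seq_len(B), each = L))
    Z1 <- .addBias(pooled %*% params$headW1, params$headb1)
    F1 <- .gelu(Z1)
    logits <- .addBias(F1 %*% params$headW2, params$headb2)
    list(logits = logits, pooled = pooled, Z1 = Z1, F1 = F1, w = w,
         regRows = rows)
}

.classifierBackward <- function(dlogits, cache, params, config, fw,
                                encoded) {
    B <- fw$B; L <- fw$L
    g <- list()
    g$headW2 <- crossprod(cache$F1, dlogits)
    g$headb2 <- colSums(dlogits)
    dF1 <- tcrossprod(dlogits, params$headW2)
    dZ1 <- dF1 * .geluGrad(cache$Z1)
    g$headW1 <- crossprod(cache$pooled, dZ1)
    g$headb1 <- colSums(dZ1)
    dPooled <- tcrossprod(dZ1, params$headW1)
    dHc <- dPooled[rep(seq_len(B), each = L), , drop = FALSE] * cache$w
    h <- ncol(fw$H)
    dH <- dHc[, seq_len(h), drop = FALSE]
    dReg <- matrix(dHc[, h + 1L], nrow = B, ncol = L, byrow = TRUE)
    g$regEmb <- matrix(0, nrow(params$regEmb), ncol(params$regEmb))
    gR <- rowsum(dReg, group = cache$regRows)
    g$regEmb[as.integer(rownames(gR)), seq_len(L)] <- gR
    list(grads = g, dH = dH)
}
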