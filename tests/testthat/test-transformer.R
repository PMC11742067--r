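test_that("single-key attention returns V and uniform scores average V", {
    Q <- matrix(rnorm(4), 1, 4)
    K <- matrix(rnorm(4), 1, 4)
    V <- matrix(c(2, -1, 3), 1, 3)
    expect_equal(scaledAttention(Q, K, V), V)
    ## all scores equal (Q orthogonal to every key): output = column means
    K2 <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0))
    Q2 <- matrix(c(0, 0, 0, 5), 1)
    V2 <- matrix(rnorm(9), 3, 3)
    expect_equal(scaledAttention(Q2, K2, V2),
                 matrix(colMeans(V2), 1), tolerance = 1e-12)
})

test_that("scaled attention matches the direct formula on a 2x2 case", {
    Q <- matrix(c(1, 2, -1, 0.5), 2, 2)
    K <- matrix(c(0.3, -1, 2, 1), 2, 2)
    V <- matrix(c(1, 0, 0, 1), 2, 2)
    S <- Q %*% t(K) / sqrt(2)
    W <- exp(S) / rowSums(exp(S))
    expect_equal(scaledAttention(Q, K, V), W %*% V, tolerance = 1e-6)
    ## rows of the weight matrix sum to one by construction
    expect_equal(rowSums(W), c(1, 1), tolerance = 1e-12)
})

test_that("attention dimension mismatches are rejected", {
    expect_error(scaledAttention(matrix(0, 2, 3), matrix(0, 2, 4),
                                 matrix(0, 2, 2)), "conformable")
})

test_that("H = 1 multi-head with identity projections is scaled attention", {
    set.seed(21)
    Q <- matrix(rnorm(12), 3, 4)
    K <- matrix(rnorm(12), 3, 4)
    V <- matrix(rnorm(12), 3, 4)
    w <- list(Wq = list(diag(4)), Wk = list(diag(4)), Wv = list(diag(4)),
              Wo = diag(4))
    expect_equal(multiHeadAttention(Q, K, V, w), scaledAttention(Q, K, V))
})

test_that("multi-head output shape and head-permutation equivariance", {
    set.seed(22)
    n <- 5; d <- 6; H <- 3; dh <- 2
    X <- matrix(rnorm(n * d), n, d)
    w <- list(Wq = lapply(1:H, function(i) matrix(rnorm(d * dh), d, dh)),
              Wk = lapply(1:H, function(i) matrix(rnorm(d * dh), d, dh)),
              Wv = lapply(1:H, function(i) matrix(rnorm(d * dh), d, dh)),
              Wo = matrix(rnorm(H * dh * d), H * dh, d))
    out <- multiHeadAttention(X, X, X, w)
    expect_equal(dim(out), c(n, d))
    ## permuting heads together with the matching Wo row blocks is a no-op
    perm <- c(2, 3, 1)
    blocks <- split(seq_len(H * dh), rep(seq_len(H), each = dh))
    w2 <- list(Wq = w$Wq[perm], Wk = w$Wk[perm], Wv = w$Wv[perm],
               Wo = w$Wo[unlist(blocks[perm]), ])
    expect_equal(multiHeadAttention(X, X, X, w2), out, tolerance = 1e-12)
})

test_that("pre-training mode makes embeddings independent of methylation", {
    cfg <- tinyTestConfig()
    m <- initModel(cfg)
    enc <- randomEncoded()
    enc2 <- enc
    enc2@methylCodes <- matrix(sample(0:2, length(enc@methylCodes), TRUE),
                               nrow(enc@methylCodes))
    expect_equal(embedInputs(m, enc, pretrainMode = TRUE),
                 embedInputs(m, enc2, pretrainMode = TRUE))
    ## in fine-tuning mode a single changed code changes only that position
    enc3 <- enc
    enc3@methylCodes[2L, 4L] <- (enc3@methylCodes[2L, 4L] + 1L) %% 3L
    d <- embedInputs(m, enc3) - embedInputs(m, enc)
    changed <- which(rowSums(abs(d)) > 0)
    expect_equal(changed, (2L - 1L) * 10L + 4L)
})

test_that("position embeddings separate identical tokens at different positions", {
    cfg <- tinyTestConfig()
    m <- initModel(cfg)
    enc <- randomEncoded()
    enc@tokenIds[1L, ] <- enc@tokenIds[1L, 1L]   # same token everywhere
    enc@methylCodes[1L, ] <- 2L
    X <- embedInputs(m, enc)
    rows <- X[1:10, ]
    expect_gt(min(dist(rows)), 0)
})

test_that("invalid methylation codes are rejected", {
    cfg <- tinyTestConfig()
    m <- initModel(cfg)
    enc <- randomEncoded()
    enc@methylCodes[1L, 1L] <- 7L
    expect_error(embedInputs(m, enc), "codes")
})

test_that("encoder+classifier gradients match finite differences", {
    cfg <- tinyTestConfig()
    m <- initModel(cfg)
    enc <- randomEncoded(n = 3L, padTail = 3L)
    y <- c(1L, 2L, 1L)
    lossFn <- function(params) {
        fw <- ReadBERT:::.encoderForward(params, cfg, enc)
        cl <- ReadBERT:::.classifierForward(params, cfg, fw, enc)
        finetuneLoss(cl$logits, y)
    }
    params <- m@params
    fw <- ReadBERT:::.encoderForward(params, cfg, enc)
    cl <- ReadBERT:::.classifierForward(params, cfg, fw, enc)
    dlog <- ReadBERT:::.softmaxGrad(cl$logits, y)
    cb <- ReadBERT:::.classifierBackward(dlog, cl, params, cfg, fw, enc)
    g <- c(cb$grads, ReadBERT:::.encoderBackward(cb$dH, fw, params, cfg,
                                                 enc))
    eps <- 1e-5
    set.seed(33)
    for (nm in names(g)) {
        p0 <- params[[nm]]
        for (i in sample(length(p0), min(3L, length(p0)))) {
            pp <- params
            pp[[nm]][i] <- p0[i] + eps
            lp <- lossFn(pp)
            pp[[nm]][i] <- p0[i] - eps
            lm <- lossFn(pp)
            num <- (lp - lm) / (2 * eps)
            expect_equal(g[[nm]][i], num, tolerance = 1e-3,
                         label = sprintf("grad %s[%d]", nm, i))
        }
    }
})

test_that("classifier posteriors are normalised and region-sensitive", {
    cfg <- tinyTestConfig()
    m <- initModel(cfg)
    enc <- randomEncoded(n = 6L)
    pt <- classifyReads(m, enc)
    expect_equal(rowSums(posteriors(pt)), rep(1, 6L), tolerance = 1e-9)
    expect_true(all(posteriors(pt) >= 0 & posteriors(pt) <= 1))
    ## the DMR embedding is live: a different region index changes posteriors
    enc2 <- enc
    enc2@regionIndex <- (enc@regionIndex %% 4L) + 1L
    pt2 <- classifyReads(m, enc2)
    expect_gt(max(abs(posteriors(pt2) - posteriors(pt))), 0)
    ## unseen region index falls back to the reserved row without error
    enc3 <- enc
    enc3@regionIndex[1L] <- 99L
    expect_silent(classifyReads(m, enc3))
})

test_that("equal class activations give the uniform posterior", {
    cfg <- tinyTestConfig()
    m <- initModel(cfg)
    m@params$headW2[] <- 0
    m@params$headb2[] <- 0
    enc <- randomEncoded(n = 3L)
    pt <- classifyReads(m, enc)
    expect_equal(posteriors(pt),
                 matrix(0.5, 3, 2, dimnames = list(NULL,
                     c("Tumour", "Normal"))), tolerance = 1e-12)
})
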