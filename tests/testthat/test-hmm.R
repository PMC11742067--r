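## Brute-force HMM likelihood: explicit sum over all hidden paths.
bruteLoglik <- function(model, states) {
    obs <- as.integer(states) + 1L
    Tn <- length(obs)
    paths <- as.matrix(expand.grid(rep(list(1:2), Tn)))
    tot <- 0
    for (r in seq_len(nrow(paths))) {
        z <- paths[r, ]
        p <- model$init[z[1L]] * model$emis[z[1L], obs[1L]]
        if (Tn > 1L) for (t in 2:Tn)
            p <- p * model$trans[z[t - 1L], z[t]] * model$emis[z[t], obs[t]]
        tot <- tot + p
    }
    log(tot)
}

## Independent naive Baum-Welch (unscaled, joint over short sequences),
## used as the reference implementation on a tiny corpus.
naiveBaumWelch <- function(seqs, init, trans, emis, iters = 60L) {
    for (it in seq_len(iters)) {
        iN <- numeric(2); tN <- matrix(0, 2, 2); eN <- matrix(0, 2, 2)
        for (s in seqs) {
            o <- as.integer(s) + 1L
            Tn <- length(o)
            a <- matrix(0, 2, Tn)
            a[, 1] <- init * emis[, o[1]]
            if (Tn > 1) for (t in 2:Tn)
                a[, t] <- (t(trans) %*% a[, t - 1]) * emis[, o[t]]
            b <- matrix(0, 2, Tn)
            b[, Tn] <- 1
            if (Tn > 1) for (t in (Tn - 1):1)
                b[, t] <- trans %*% (emis[, o[t + 1]] * b[, t + 1])
            lik <- sum(a[, Tn])
            g <- a * b / lik
            iN <- iN + g[, 1]
            for (t in seq_len(Tn)) eN[, o[t]] <- eN[, o[t]] + g[, t]
            if (Tn > 1) for (t in seq_len(Tn - 1))
                tN <- tN + trans * outer(a[, t],
                                         emis[, o[t + 1]] * b[, t + 1]) / lik
        }
        init <- iN / sum(iN)
        if (all(rowSums(tN) > 0)) trans <- tN / rowSums(tN)
        emis <- eN / rowSums(eN)
        emis <- pmin(pmax(emis, 1e-6), 1 - 1e-6)
        emis <- emis / rowSums(emis)
    }
    list(init = init, trans = trans, emis = emis)
}

test_that("forward likelihood equals brute-force path summation", {
    set.seed(5)
    for (i in 1:10) {
        init <- runif(2); init <- init / sum(init)
        trans <- matrix(runif(4), 2); trans <- trans / rowSums(trans)
        emis <- matrix(runif(4), 2); emis <- emis / rowSums(emis)
        model <- list(init = init, trans = trans, emis = emis)
        states <- sample(0:1, sample(1:8, 1), TRUE)
        expect_equal(hmmLoglik(model, states), bruteLoglik(model, states),
                     tolerance = 1e-10)
    }
})

test_that("a single-CpG read reduces to initial-state-weighted emissions", {
    model <- list(init = c(0.3, 0.7),
                  trans = matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE),
                  emis = matrix(c(0.95, 0.05, 0.1, 0.9), 2, byrow = TRUE))
    expect_equal(hmmLoglik(model, 1L),
                 log(0.3 * 0.05 + 0.7 * 0.9), tolerance = 1e-12)
})

test_that("a separable corpus yields near-degenerate opposite emissions", {
    reads <- MethylReadSet(
        chrom = rep("c", 8), start = rep(0L, 8),
        sequence = rep("TACGACGTACGAT", 8),
        cpgOffsets = rep(list(c(2L, 5L, 9L)), 8),
        cpgStates = c(rep(list(c(1L, 1L, 1L)), 4),
                      rep(list(c(0L, 0L, 0L)), 4)),
        cellLabel = rep(c("Tumour", "Normal"), each = 4))
    hc <- fitHmm(reads, seed = 2L)
    emT <- hc@models$Tumour$emis
    emN <- hc@models$Normal$emis
    ## tumour model emits methylated (column 2) with high probability from
    ## both states; normal the opposite
    expect_true(all(emT[, 2L] > 0.95))
    expect_true(all(emN[, 1L] > 0.95))
    pt <- classifyReadsHmm(hc, reads)
    expect_equal(predictedLabel(pt), cellLabel(reads))
})

test_that("Baum-Welch training log-likelihood is non-decreasing", {
    set.seed(9)
    seqs <- lapply(1:10, function(i) sample(0:1, sample(3:8, 1), TRUE))
    init <- c(0.5, 0.5)
    trans <- matrix(c(0.6, 0.4, 0.3, 0.7), 2, byrow = TRUE)
    emis <- matrix(c(0.7, 0.3, 0.4, 0.6), 2, byrow = TRUE)
    lls <- numeric(15)
    cur <- list(init = init, trans = trans, emis = emis)
    for (it in seq_len(15)) {
        lls[it] <- sum(vapply(seqs, function(s)
            hmmLoglik(cur, s), numeric(1)))
        cur <- ReadBERT:::.baumWelch(seqs, cur$init, cur$trans, cur$emis,
                                     maxIter = 1L)$model
    }
    expect_true(all(diff(lls) > -1e-8))
})

test_that("package Baum-Welch matches the naive reference on a toy corpus", {
    set.seed(12)
    seqs <- lapply(1:10, function(i)
        rbinom(6, 1, if (i %% 2) 0.85 else 0.2))
    init <- c(0.6, 0.4)
    trans <- matrix(c(0.7, 0.3, 0.25, 0.75), 2, byrow = TRUE)
    emis <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, byrow = TRUE)
    ref <- naiveBaumWelch(seqs, init, trans, emis, iters = 60L)
    fit <- ReadBERT:::.baumWelch(seqs, init, trans, emis, maxIter = 60L,
                                 tol = 0)$model
    expect_equal(fit$init, ref$init, tolerance = 1e-4)
    expect_equal(fit$trans, ref$trans, tolerance = 1e-4)
    expect_equal(fit$emis, ref$emis, tolerance = 1e-4)
})

test_that("identical models for both classes tie every read to Normal", {
    model <- list(init = c(0.5, 0.5),
                  trans = matrix(0.5, 2, 2),
                  emis = matrix(0.5, 2, 2))
    hc <- new("HmmClassifier",
              models = list(Tumour = model, Normal = model),
              classes = c("Tumour", "Normal"),
              priors = c(Tumour = 0.5, Normal = 0.5))
    reads <- tinyReads()
    pt <- classifyReadsHmm(hc, reads)
    expect_true(all(predictedLabel(pt) == "Normal"))
})

test_that("HMM accuracy degrades with alpha and collapses on CpG-specific", {
    accOf <- function(scenario, alpha, seed) {
        cfg <- SimConfig(alpha = alpha, nRegions = 12L, coverage = 12L,
                         scenario = scenario, seed = seed)
        reads <- simulateReads(simulateRegions(cfg))
        n <- length(reads)
        set.seed(seed + 1)
        tr <- sample.int(n, round(0.7 * n))
        hc <- fitHmm(reads[tr], seed = seed)
        pt <- suppressMessages(classifyReadsHmm(hc, reads[-tr]))
        mean(predictedLabel(pt) == pt@trueLabel)
    }
    accRegion <- vapply(c(0.1, 3), function(a)
        mean(vapply(1:2, function(s) accOf("region_level", a, s * 7),
                    numeric(1))), numeric(1))
    ## Fig-2A-style ordering: simplest complexity is the most accurate
    expect_gt(accRegion[1L], accRegion[2L])
    expect_gt(accRegion[1L], 0.9)
    ## CpG-specific patterns defeat the HMM (region means coincide)
    accCpg <- mean(vapply(1:2, function(s)
        accOf("cpg_specific", 0.1, s * 11), numeric(1)))
    expect_lt(accCpg, 0.65)
})
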