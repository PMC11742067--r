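## Independent dense-optimiser oracle for the two-class mixture MLE,
## written directly from the likelihood definition.
denseMLE <- function(scores) {
    f <- function(d) sum(log(d * scores[, 1L] + (1 - d) * scores[, 2L]))
    o <- optimize(f, c(0, 1), maximum = TRUE, tol = 1e-9)
    ## compare the interior optimum against the boundaries
    cand <- c(0, o$maximum, 1)
    vals <- vapply(cand, f, numeric(1))
    cand[which.max(vals)]
}

test_that("posterior inversion follows Bayes under equal read marginals", {
    pt <- PosteriorTable("r1", 1L,
                         matrix(c(0.8, 0.2), 1,
                                dimnames = list(NULL, c("Tumour", "Normal"))),
                         priors = c(0.5, 0.5))
    sc <- invertPosteriors(pt, normalise = FALSE)
    expect_equal(unname(sc[1L, 1L]), 1.6)
    expect_equal(unname(sc[1L, 2L]), 0.4)
    ## uniform priors: scores proportional to posteriors
    expect_equal(sc[1L, ] / sum(sc[1L, ]), c(Tumour = 0.8, Normal = 0.2))
})

test_that("per-read score scaling leaves the purity MLE unchanged", {
    pt <- simulateCalibratedPosteriors(400, 0.3, seed = 4L)
    sc <- invertPosteriors(pt, normalise = FALSE)
    d1 <- purityMLE(sc, 1e-3)$delta
    set.seed(1)
    sc2 <- sc * runif(nrow(sc), 0.1, 10)   # read-constant rescaling
    expect_equal(purityMLE(sc2, 1e-3)$delta, d1)
})

test_that("purity MLE recovers certainty-limit and closed-form cases", {
    ## perfectly certain posteriors, 30% tumour reads
    sc <- cbind(c(rep(1, 30), rep(0, 70)), c(rep(0, 30), rep(1, 70)))
    expect_equal(purityMLE(sc)$delta, 0.3, tolerance = 1e-12)
    ## two certain reads, one each: L ~ delta (1 - delta), argmax 0.5
    sc2 <- cbind(c(1, 0), c(0, 1))
    expect_equal(purityMLE(sc2)$delta, 0.5, tolerance = 1e-12)
    ## identical scores for both classes: flat, delta 0 by the tie rule
    sc3 <- cbind(rep(1, 10), rep(1, 10))
    r <- purityMLE(sc3)
    expect_true(r$flat)
    expect_equal(r$delta, 0)
})

test_that("grid MLE is within two grid steps of the dense oracle", {
    for (s in 1:5) {
        pt <- simulateCalibratedPosteriors(800, c(0.1, 0.3, 0.5, 0.8, 0.95)[s],
                                           nRegions = 10L, seed = s)
        sc <- invertPosteriors(pt)
        expect_lt(abs(purityMLE(sc)$delta - denseMLE(sc)), 2 * 1e-4 + 1e-9)
    }
})

test_that("class swap maps the estimate to its complement exactly", {
    pt <- simulateCalibratedPosteriors(600, 0.23, seed = 7L)
    sc <- invertPosteriors(pt)
    d <- purityMLE(sc)$delta
    dSwap <- purityMLE(sc[, 2:1])$delta
    expect_equal(dSwap, 1 - d, tolerance = 1e-12)
    ## likelihood value itself is unchanged under (swap, 1 - delta)
    ll <- function(s, dd) sum(log(dd * s[, 1] + (1 - dd) * s[, 2]))
    expect_equal(ll(sc, 0.37), ll(sc[, 2:1], 0.63), tolerance = 1e-9)
})

test_that("region purities are the per-region MLEs", {
    sc <- rbind(cbind(c(1, 0, 0, 0, 0), c(0, 1, 1, 1, 1)),   # region 1: 0.2
                cbind(c(1, 1, 0, 0, 0), c(0, 0, 1, 1, 1)))   # region 2: 0.4
    reg <- rep(1:2, each = 5)
    rd <- regionPurities(sc, reg)
    expect_equal(unname(rd), c(0.2, 0.4), tolerance = 1e-12)
    ## homogeneous regions: pooled MLE ~ mean of region MLEs
    pt <- simulateCalibratedPosteriors(2000, 0.4, nRegions = 8L,
                                       regionConcentration = 500,
                                       seed = 11L)
    sc2 <- invertPosteriors(pt)
    pooled <- purityMLE(sc2)$delta
    expect_lt(abs(pooled - mean(regionPurities(sc2, pt@regionIndex))),
              0.02)
})

test_that("G1 skewness matches hand values and a three-pass oracle", {
    expect_equal(skewnessG1(c(1, 2, 3)), 0)
    expect_equal(skewnessG1(c(0, 0, 1)), sqrt(3), tolerance = 1e-12)
    threePass <- function(x) {
        K <- length(x)
        mu <- sum(x) / K
        m2 <- sum((x - mu)^2) / K
        m3 <- sum((x - mu)^3) / K
        m3 * sqrt(K * (K - 1)) / (m2^1.5 * (K - 2))
    }
    set.seed(2)
    for (i in 1:20) {
        x <- rnorm(sample(3:50, 1))
        expect_equal(skewnessG1(x), threePass(x), tolerance = 1e-12)
        expect_equal(skewnessG1(-x), -skewnessG1(x), tolerance = 1e-12)
    }
    expect_error(skewnessG1(c(1, 2)), "at least 3")
    expect_error(skewnessG1(c(1, 1, 1)), "zero variance")
})

test_that("adjustment reduces the skewness magnitude on any input", {
    set.seed(3)
    for (i in 1:10) {
        d <- runif(sample(5:40, 1))
        a <- adjustEstimate(d)
        expect_lte(abs(a$skewAfter), abs(a$skewBefore) + 1e-9)
        expect_true(all(a$W * d >= -1e-12 & a$W * d <= 1 + 1e-12))
    }
})

test_that("already-symmetric purities are left essentially unmapped", {
    d <- seq(0.2, 0.8, length.out = 7)   # equally spaced, zero skew
    a <- adjustEstimate(d)
    expect_equal(a$adjusted, mean(d), tolerance = 1e-6)
    ## all-equal purities: W = 1, adjusted = the common value
    a2 <- adjustEstimate(rep(0.4, 5))
    expect_equal(a2$W, rep(1, 5))
    expect_equal(a2$adjusted, 0.4)
})

test_that("coordinate descent reaches skewness comparable to a direct optimiser", {
    set.seed(13)
    for (i in 1:5) {
        d <- rbeta(20, 2, 5)
        a <- adjustEstimate(d)
        dir <- adjustEstimateDirect(d)
        g1dir <- abs(skewnessG1(pmin(pmax(dir$W * d, 0), 1)))
        expect_lte(abs(a$skewAfter), g1dir + 0.05)
    }
})

test_that("Fisher information equals the finite-difference variance oracle", {
    pt <- simulateCalibratedPosteriors(200, 0.3, seed = 17L)
    sc <- invertPosteriors(pt)
    delta <- 0.3
    fi <- fisherInformation(sc, delta)
    h <- 1e-6
    perRead <- (log(sc[, 1] * (delta + h) + sc[, 2] * (1 - delta - h)) -
                log(sc[, 1] * (delta - h) + sc[, 2] * (1 - delta + h))) /
        (2 * h)
    expect_equal(fi, var(perRead), tolerance = 1e-6)
    ## equal scores carry no information
    expect_equal(fisherInformation(cbind(rep(1, 5), rep(1, 5)), 0.4), 0)
})

test_that("sharper posteriors carry more Fisher information", {
    fis <- vapply(c(0.5, 1, 2, 4), function(sep) {
        pt <- simulateCalibratedPosteriors(2000, 0.3, separation = sep,
                                           seed = 19L)
        fisherInformation(invertPosteriors(pt), 0.3)
    }, numeric(1))
    expect_true(all(diff(fis) > 0))
})

test_that("estimatePurity wires the components together", {
    pt <- simulateCalibratedPosteriors(2000, 0.3, nRegions = 10L, seed = 23L)
    pr <- estimatePurity(pt, adjust = TRUE, gridStep = 1e-3)
    expect_s4_class(pr, "PurityResult")
    expect_lt(abs(deltaHat(pr) - 0.3), 0.05)
    expect_length(regionDeltas(pr), 10L)
    expect_length(fisherInfo(pr), 10L)   # per-region when adjusted
    prU <- estimatePurity(pt, adjust = FALSE, gridStep = 1e-3)
    expect_length(fisherInfo(prU), 1L)
    expect_true(is.na(adjustedDelta(prU)))
})

test_that("region purity skewness anti-correlates with true purity", {
    ## the asymmetry that motivates the adjustment: low-purity bulks have
    ## right-skewed region purities, high-purity bulks left-skewed
    fracs <- c(0.1, 0.3, 0.5, 0.7, 0.9)
    g1s <- sapply(1:6, function(s) vapply(fracs, function(f) {
        pt <- simulateCalibratedPosteriors(1500, f, nRegions = 20L,
                                           regionConcentration = 8,
                                           separation = 1.5,
                                           seed = s * 31 + round(f * 100))
        rd <- regionPurities(invertPosteriors(pt), pt@regionIndex, 1e-3)
        if (var(rd) == 0) 0 else skewnessG1(rd)
    }, numeric(1)))
    rho <- cor(fracs, rowMeans(g1s), method = "spearman")
    expect_lt(rho, 0)
})

test_that("multi-class fractions: certainty limit and empty classes", {
    post <- matrix(0, 10, 2, dimnames = list(NULL, c("A", "B")))
    post[1:3, 1] <- 1; post[4:10, 2] <- 1
    post <- post + 1e-9; post <- post / rowSums(post)
    pt <- PosteriorTable(sprintf("r%d", 1:10), 1L, post,
                         priors = c(0.5, 0.5))
    cf <- cellFractions(pt, gridStep = 1e-3)
    expect_equal(unname(cf@fractions), c(0.3, 0.7), tolerance = 1e-3)
    ## a class that attracts no reads gets fraction zero
    post2 <- cbind(A = rep(0.9, 5), B = rep(0.1, 5), C = rep(0, 5))
    post2 <- post2 + 1e-9; post2 <- post2 / rowSums(post2)
    pt2 <- PosteriorTable(sprintf("r%d", 1:5), 1L, post2,
                          priors = rep(1 / 3, 3))
    cf2 <- cellFractions(pt2, gridStep = 1e-3)
    expect_equal(unname(cf2@fractions[c("B", "C")]), c(0, 0))
    expect_error(cellFractions(PosteriorTable(character(0), integer(0),
        matrix(numeric(0), 0, 2, dimnames = list(NULL, c("A", "B"))),
        c(0.5, 0.5))), "empty")
})

test_that("reconstructed methylation separates the generative cell levels", {
    cfg <- SimConfig(alpha = 1, nRegions = 6L, coverage = 30L, seed = 37L)
    rs <- simulateRegions(cfg)
    reads <- simulateReads(rs)
    ## perfect classification: use the true labels
    rec <- reconstructMethylation(reads, cellLabel(reads),
                                  classes = c("Tumour", "Normal"))
    d <- S4Vectors::mcols(rs@ranges)$d
    bulk <- vapply(seq_len(6), function(k)
        mean(readMethylationLevel(reads)[regionIndex(reads) == k]),
        numeric(1))
    errRef <- mean(abs(rec[, "Tumour"] - d)) +
        mean(abs(rec[, "Normal"] - (1 - d)))
    errBulk <- mean(abs(rec[, "Tumour"] - bulk)) +
        mean(abs(rec[, "Normal"] - bulk))
    expect_lt(errRef, errBulk)
    ## correlation with the generative levels is higher than with the bulk
    expect_gt(cor(c(rec), c(d, 1 - d)), cor(c(rec), rep(bulk, 2)))
})

test_that("fully methylated reads reconstruct level 1; empty cells are NA", {
    r <- MethylReadSet(c("c", "c", "c"), c(0L, 0L, 0L),
                       rep("TACGTT", 3), list(2L, 2L, 2L),
                       list(1L, 1L, 1L), regionIndex = c(1L, 1L, 2L))
    rec <- reconstructMethylation(r, c("T", "T", "T"),
                                  classes = c("T", "N"))
    expect_equal(rec["1", "T"], 1)
    expect_true(is.na(rec["1", "N"]))
    expect_true(is.na(rec["2", "N"]))
})
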