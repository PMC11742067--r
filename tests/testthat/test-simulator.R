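test_that("Beta draws match the analytic moments at the bench alphas", {
    n <- 50000
    for (alpha in c(0.1, 1, 2, 3)) {
        set.seed(100 + alpha * 10)
        d <- sampleRegionLevel(n, alpha, 5)
        m <- alpha / (alpha + 5)
        v <- alpha * 5 / ((alpha + 5)^2 * (alpha + 5 + 1))
        expect_lt(abs(mean(d) - m), 3 * sqrt(v / n))
        ## variance within Monte-Carlo error (4th-moment based SE bound)
        seVar <- sd((d - m)^2) / sqrt(n)
        expect_lt(abs(var(d) - v), 4 * seVar)
    }
    set.seed(7); a <- sampleRegionLevel(100, 5, 5)
    expect_lt(abs(mean(a) - 0.5), 3 * sqrt(var(a) / 100))
    expect_error(sampleRegionLevel(1, -1, 5), "positive")
})

test_that("draws are reproducible under a fixed seed", {
    set.seed(3); a <- sampleRegionLevel(100, 0.1)
    set.seed(3); b <- sampleRegionLevel(100, 0.1)
    expect_identical(a, b)
    cfg <- SimConfig(alpha = 1, nRegions = 3L, coverage = 3L, seed = 5L)
    r1 <- simulateReads(simulateRegions(cfg))
    r2 <- simulateReads(simulateRegions(cfg))
    expect_identical(GenomicRanges::start(readRanges(r1)),
                     GenomicRanges::start(readRanges(r2)))
    expect_identical(as.list(cpgStates(r1)), as.list(cpgStates(r2)))
})

test_that("degenerate d gives deterministic CpG states per cell type", {
    cfg <- SimConfig(alpha = 1, nRegions = 2L, coverage = 5L, seed = 8L,
                     readLength = 150L, regionLength = 200L)
    rs <- simulateRegions(cfg)
    ## force d = 1 in every region
    S4Vectors::mcols(rs@ranges)$d <- 1
    rs@probTumour <- IRanges::NumericList(lapply(
        seq_along(rs@probTumour),
        function(i) ifelse(rs@inRegion[[i]] == 1L, 1, rs@probTumour[[i]])))
    rs@probNormal <- IRanges::NumericList(lapply(
        seq_along(rs@probNormal),
        function(i) ifelse(rs@inRegion[[i]] == 1L, 0, rs@probNormal[[i]])))
    reads <- simulateReads(rs)
    for (i in seq_len(length(reads))) {
        off <- cpgOffsets(reads)[[i]]
        st <- cpgStates(reads)[[i]]
        chrom <- as.character(GenomicRanges::seqnames(readRanges(reads)))[i]
        ri <- match(chrom, names(rs@chromSeq))
        gpos <- off + GenomicRanges::start(readRanges(reads))[i] - 1L
        inreg <- rs@inRegion[[ri]][match(gpos, rs@cpgOffsets[[ri]])]
        if (cellLabel(reads)[i] == "Tumour")
            expect_true(all(st[inreg == 1L] == 1L))
        else
            expect_true(all(st[inreg == 1L] == 0L))
    }
})

test_that("region-level read methylation matches the binomial mean", {
    cfg <- SimConfig(alpha = 1, nRegions = 1L, coverage = 200L, seed = 31L)
    rs <- simulateRegions(cfg)
    d <- 0.8
    S4Vectors::mcols(rs@ranges)$d <- d
    rs@probTumour[[1L]][] <- d   # all CpGs, incl. flanks, at the same p
    reads <- simulateReads(rs, cellTypes = "Tumour")
    states <- unlist(cpgStates(reads))
    p <- mean(states)
    expect_lt(abs(p - d), 3 * sqrt(d * (1 - d) / length(states)))
})

test_that("complexity ordering: the tumour/normal gap shrinks as alpha grows", {
    n <- 50000
    gap <- vapply(c(0.1, 1, 2, 3), function(alpha) {
        set.seed(500 + alpha)
        d <- sampleRegionLevel(n, alpha, 5)
        abs(1 - 2 * mean(pmin(d, 1 - d)))
    }, numeric(1))
    expect_true(all(diff(gap) < 0))
})

test_that("CpG-specific scenario: region means agree, per-CpG means oppose", {
    cfg <- SimConfig(alpha = 0.1, nRegions = 1L, coverage = 400L,
                     scenario = "cpg_specific", seed = 41L,
                     readLength = 200L, regionLength = 200L,
                     backgroundMethylation = 0.5)
    rs <- simulateRegions(cfg)
    d <- 0.05
    inreg <- rs@inRegion[[1L]] == 1L
    idx <- cumsum(rs@inRegion[[1L]])
    odd <- idx %% 2L == 1L
    rs@probTumour[[1L]][inreg] <- ifelse(odd[inreg], d, 1 - d)
    rs@probNormal[[1L]][inreg] <- ifelse(odd[inreg], 1 - d, d)
    reads <- simulateReads(rs)
    m <- readMethylationLevel(reads)
    lab <- cellLabel(reads)
    ## balanced odd/even CpG coverage: region means differ by ~0
    nT <- sum(lab == "Tumour")
    se <- sqrt(var(m[lab == "Tumour"]) / nT + var(m[lab == "Normal"]) / nT)
    expect_lt(abs(mean(m[lab == "Tumour"]) - mean(m[lab == "Normal"])),
              3 * se + 0.02)
    ## yet per-CpG means differ by ~0.9 in opposite phase
    gstart <- GenomicRanges::start(readRanges(reads)) - 1L
    firstCpg <- rs@cpgOffsets[[1L]][inreg][1L]
    covering <- which(vapply(seq_len(length(reads)), function(i)
        firstCpg %in% (cpgOffsets(reads)[[i]] + gstart[i]), logical(1)))
    st <- vapply(covering, function(i) {
        o <- match(firstCpg, cpgOffsets(reads)[[i]] + gstart[i])
        cpgStates(reads)[[i]][o]
    }, integer(1))
    mT <- mean(st[lab[covering] == "Tumour"])
    mN <- mean(st[lab[covering] == "Normal"])
    expect_lt(mT, 0.15)   # odd CpG, tumour prob = d = 0.05
    expect_gt(mN, 0.85)
})

test_that("d = 0.5 makes the CpG-specific scenario indistinguishable", {
    cfg <- SimConfig(alpha = 1, nRegions = 1L, coverage = 300L,
                     scenario = "cpg_specific", seed = 43L)
    rs <- simulateRegions(cfg)
    inreg <- rs@inRegion[[1L]] == 1L
    rs@probTumour[[1L]][inreg] <- 0.5
    rs@probNormal[[1L]][inreg] <- 0.5
    reads <- simulateReads(rs)
    st <- unlist(cpgStates(reads))
    expect_lt(abs(mean(st) - 0.5), 3 * sqrt(0.25 / length(st)))
})

test_that("pseudo-bulk mixing reproduces the requested fraction exactly", {
    cfg <- SimConfig(alpha = 0.1, nRegions = 4L, coverage = 40L, seed = 51L)
    rs <- simulateRegions(cfg)
    tum <- simulateReads(rs, cellTypes = "Tumour")
    nor <- simulateReads(rs, cellTypes = "Normal", seed = 99L)
    mix <- mixPseudobulk(tum, nor, 0.2, 100L, seed = 1L)
    expect_equal(mix$truth$nTumour, 20L)
    expect_equal(sum(cellLabel(mix$reads) == "Tumour"), 20L)
    expect_equal(sum(cellLabel(mix$reads) == "Normal"), 80L)
    ## boundary: fraction 0
    mix0 <- mixPseudobulk(tum, nor, 0, 50L, seed = 1L)
    expect_true(all(cellLabel(mix0$reads) == "Normal"))
    ## ctDNA-like regime
    mix3 <- mixPseudobulk(tum, nor, 0.03, 100L, seed = 1L)
    expect_equal(mix3$truth$nTumour, 3L)
    ## without replacement the pool size is a hard limit
    expect_error(mixPseudobulk(tum, nor, 1, 10000L, seed = 1L),
                 "pool size")
})

test_that("SEM follows the 1/sqrt(n) law and hand values", {
    ## per-read means {0, 1}: sd = 0.7071, SEM = 0.5
    r <- MethylReadSet(c("c", "c"), c(0L, 0L), c("ACGTA", "ACGTA"),
                       list(1L, 1L), list(0L, 1L))
    expect_equal(semOfRegion(r), 0.5, tolerance = 1e-12)
    ## identical reads: SEM 0
    r2 <- MethylReadSet(c("c", "c"), c(0L, 0L), c("ACGTA", "ACGTA"),
                        list(1L, 1L), list(1L, 1L))
    expect_equal(semOfRegion(r2), 0)
    expect_error(semOfRegion(r2[1L]), "fewer than 2")
    ## SEM decreases with coverage at fixed d
    sems <- vapply(c(10L, 40L, 160L), function(cov) {
        cfg <- SimConfig(alpha = 1, nRegions = 1L, coverage = cov,
                         seed = 61L)
        semOfRegion(simulateReads(simulateRegions(cfg),
                                  cellTypes = "Tumour"))
    }, numeric(1))
    expect_true(all(diff(sems) < 0))
})
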