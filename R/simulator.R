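## Read-level methylome simulator: the evaluation bench.
##
## Per region a tumour mean methylation d ~ Beta(alpha, beta = 5) is drawn;
## tumour reads sample each CpG state Bernoulli(d) and normal reads
## Bernoulli(1 - d) (region-level scenario). In the CpG-specific scenario d
## and 1 - d alternate over odd/even CpG indices for tumour, and normal
## receives the opposite phase, so region means coincide while per-CpG
## patterns anti-correlate.

#' Draw per-region tumour mean methylation levels
#'
#' d ~ Beta(alpha, beta). Uses the current RNG state; seed externally (or
#' via [simulateRegions()]) for reproducibility.
#'
#' @param n number of draws.
#' @param alpha,beta positive Beta shape parameters (bench default beta = 5).
#' @return numeric vector in [0, 1].
#' @export
sampleRegionLevel <- function(n, alpha, beta = 5) {
    if (alpha <= 0 || beta <= 0)
        stop("Beta shape parameters must be positive")
    rbeta(n, alpha, beta)
}

#' Simulate region templates
#'
#' Builds `nRegions` synthetic regions, each on its own chromosome with
#' `readLength` bp flanks. CpGs are planted every `cpgSpacing` bp inside the
#' region and every `backgroundCpgSpacing` bp in the flanks; the reference
#' sequence is random with CG dinucleotides exactly at the planted sites.
#' Per region d ~ Beta(alpha, beta) determines the per-CpG methylation
#' probabilities of the two cell types according to the scenario; flank
#' (non-DMR) CpGs use `backgroundMethylation` for both cell types.
#'
#' @param config a [SimConfig].
#' @return A [SimRegionSet].
#' @export
#' @examples
#' rs <- simulateRegions(SimConfig(nRegions = 5, seed = 1))
simulateRegions <- function(config) {
    stopifnot(is(config, "SimConfig"))
    set.seed(config@seed)
    nR <- config@nRegions
    flank <- config@readLength
    regLen <- config@regionLength
    chromLen <- regLen + 2L * flank
    d <- sampleRegionLevel(nR, config@alpha, config@beta)

    kIn <- max(1L, regLen %/% config@cpgSpacing)
    inOff <- flank + config@cpgSpacing %/% 2L +
        config@cpgSpacing * (seq_len(kIn) - 1L)
    inOff <- inOff[inOff <= flank + regLen - 2L]
    safeSeq <- function(from, to, by)
        if (from > to) integer(0) else seq(from, to, by = by)
    bgLeft <- safeSeq(config@backgroundCpgSpacing %/% 2L, flank - 2L,
                      config@backgroundCpgSpacing)
    bgRight <- safeSeq(flank + regLen + config@backgroundCpgSpacing %/% 2L,
                       chromLen - 2L, config@backgroundCpgSpacing)
    cpgAll <- sort(unique(c(bgLeft, inOff, bgRight)))
    ## drop background CpGs that would collide with a region CpG's G base
    cpgAll <- cpgAll[!(cpgAll + 1L) %in% cpgAll]
    inReg <- as.integer(cpgAll %in% inOff)

    seqs <- character(nR)
    probT <- probN <- vector("list", nR)
    offs <- vector("list", nR)
    for (i in seq_len(nR)) {
        s <- sample(c("A", "C", "G", "T"), chromLen, replace = TRUE)
        s[cpgAll + 1L] <- "C"
        s[cpgAll + 2L] <- "G"
        ## remove accidental CG dinucleotides outside planted sites
        isCG <- which(s[-chromLen] == "C" & s[-1L] == "G")  # 1-based C pos
        acc <- setdiff(isCG, cpgAll + 1L)
        if (length(acc)) s[acc + 1L] <- "A"
        seqs[i] <- paste(s, collapse = "")
        k <- length(cpgAll)
        idxInRegion <- cumsum(inReg)          # CpG order within the region
        pT <- pN <- rep(config@backgroundMethylation, k)
        if (config@scenario == "region_level") {
            pT[inReg == 1L] <- d[i]
            pN[inReg == 1L] <- 1 - d[i]
        } else {
            odd <- idxInRegion %% 2L == 1L    # 1-based CpG order: first = odd
            pT[inReg == 1L & odd] <- d[i]
            pT[inReg == 1L & !odd] <- 1 - d[i]
            pN[inReg == 1L & odd] <- 1 - d[i]  # opposite phase
            pN[inReg == 1L & !odd] <- d[i]
        }
        offs[[i]] <- cpgAll
        probT[[i]] <- pT
        probN[[i]] <- pN
    }
    chroms <- sprintf("simChr%03d", seq_len(nR))
    gr <- GRanges(chroms, IRanges(start = flank + 1L, width = regLen))
    names(gr) <- chroms
    mcols(gr)$regionIndex <- seq_len(nR)
    mcols(gr)$d <- d
    chromSeq <- DNAStringSet(seqs)
    names(chromSeq) <- chroms
    new("SimRegionSet", ranges = gr, chromSeq = chromSeq,
        cpgOffsets = IntegerList(offs),
        inRegion = IntegerList(rep(list(inReg), nR)),
        probTumour = NumericList(probT), probNormal = NumericList(probN),
        config = config)
}

#' Simulate labelled reads from region templates
#'
#' Places `coverage` reads per region per requested cell type uniformly over
#' the start positions whose window overlaps the region, takes the reference
#' slice as the read sequence, and draws every covered CpG state as an
#' independent Bernoulli with the cell-type- and CpG-specific probability of
#' the template (both scenarios are realised through those probabilities).
#'
#' @param regions a [SimRegionSet] from [simulateRegions()].
#' @param cellTypes which cell types to simulate.
#' @param seed integer seed; defaults to `config seed + 1` so that region
#'   drawing and read drawing are independently reproducible.
#' @return A [MethylReadSet] with `cellLabel` and `regionIndex` set.
#' @export
simulateReads <- function(regions, cellTypes = c("Tumour", "Normal"),
                          seed = regions@config@seed + 1L) {
    stopifnot(is(regions, "SimRegionSet"))
    config <- regions@config
    set.seed(seed)
    L <- config@readLength
    out <- list()
    for (ct in cellTypes) {
        pList <- if (ct == "Tumour") regions@probTumour else regions@probNormal
        for (i in seq_along(regions@ranges)) {
            chrom <- as.character(seqnames(regions@ranges))[i]
            regStart0 <- start(regions@ranges)[i] - 1L  # 0-based
            regEnd0 <- end(regions@ranges)[i]           # 0-based half-open
            chromLen <- Biostrings::width(regions@chromSeq)[i]
            cpg <- regions@cpgOffsets[[i]]
            p <- pList[[i]]
            lo <- max(0L, regStart0 - L + 1L)
            hi <- min(chromLen - L, regEnd0 - 1L)
            starts <- integer(config@coverage)
            for (r in seq_len(config@coverage)) {
                for (try in 1:50) {
                    s0 <- lo + sample.int(hi - lo + 1L, 1L) - 1L
                    cov <- cpg >= s0 & cpg <= s0 + L - 2L
                    if (any(cov & regions@inRegion[[i]] == 1L)) break
                }
                starts[r] <- s0
            }
            seqs <- substring(as.character(regions@chromSeq[[i]]),
                              starts + 1L, starts + L)
            offL <- stL <- vector("list", config@coverage)
            for (r in seq_len(config@coverage)) {
                cov <- which(cpg >= starts[r] & cpg <= starts[r] + L - 2L)
                offL[[r]] <- cpg[cov] - starts[r]
                stL[[r]] <- as.integer(runif(length(cov)) < p[cov])
            }
            out[[length(out) + 1L]] <- MethylReadSet(
                chrom = chrom, start = starts, sequence = seqs,
                cpgOffsets = offL, cpgStates = stL,
                regionIndex = mcols(regions@ranges)$regionIndex[i],
                cellLabel = ct,
                readId = sprintf("%s_%s_r%03d", chrom, ct,
                                 seq_len(config@coverage)))
        }
    }
    do.call(c, out)
}

#' Mix tumour and normal read pools into a pseudo-bulk
#'
#' Samples exactly `round(nReads * tumourFraction)` tumour reads and the
#' remainder from the normal pool, without replacement by default, and
#' records the ground truth.
#'
#' @param tumourReads,normalReads [MethylReadSet] pools.
#' @param tumourFraction requested tumour read fraction in [0, 1].
#' @param nReads total pseudo-bulk size.
#' @param seed integer seed.
#' @param replace sample with replacement (needed when a pool is smaller
#'   than its share).
#' @return list with `reads` (a [MethylReadSet], labels retained as ground
#'   truth) and `truth` (requested fraction, realised counts).
#' @export
mixPseudobulk <- function(tumourReads, normalReads, tumourFraction, nReads,
                          seed = 1L, replace = FALSE) {
    stopifnot(tumourFraction >= 0, tumourFraction <= 1)
    nT <- as.integer(round(nReads * tumourFraction))
    nN <- as.integer(nReads) - nT
    if (!replace && (nT > length(tumourReads) || nN > length(normalReads)))
        stop("requested more reads than pool size; use replace = TRUE")
    if (nT > 0 && length(tumourReads) == 0L)
        stop("tumour pool is empty but tumour share > 0")
    if (nN > 0 && length(normalReads) == 0L)
        stop("normal pool is empty but normal share > 0")
    set.seed(seed)
    parts <- list()
    if (nT > 0)
        parts <- c(parts, list(tumourReads[sample.int(length(tumourReads),
                                                      nT, replace = replace)]))
    if (nN > 0)
        parts <- c(parts, list(normalReads[sample.int(length(normalReads),
                                                      nN, replace = replace)]))
    reads <- if (length(parts) > 1L) do.call(c, parts) else parts[[1L]]
    list(reads = reads,
         truth = list(tumourFraction = tumourFraction, nTumour = nT,
                      nNormal = nN, realisedFraction = nT / (nT + nN)))
}

#' Standard error of the mean read methylation in a region
#'
#' SEM over the average methylation level of reads: the standard deviation
#' of per-read mean methylation divided by the square root of the number of
#' reads. Quantifies how well the sample mean represents the population
#' mean at a given coverage.
#'
#' @param reads a [MethylReadSet] (all reads are treated as one region);
#'   reads without CpGs are excluded.
#' @return the SEM (numeric scalar).
#' @export
semOfRegion <- function(reads) {
    m <- readMethylationLevel(reads)
    m <- m[!is.na(m)]
    if (length(m) < 2L)
        stop("SEM undefined for fewer than 2 reads with CpGs")
    sd(m) / sqrt(length(m))
}

#' @rdname semOfRegion
#' @details `semByRegion()` applies [semOfRegion()] per `regionIndex`.
#' @export
semByRegion <- function(reads) {
    idx <- split(seq_along(reads@regionIndex), reads@regionIndex)
    vapply(idx, function(i) semOfRegion(reads[i]), numeric(1))
}
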