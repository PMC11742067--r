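## BAM I/O with the Bismark-style per-base methylation-call tag (XM).
##
## Only the CpG symbols of the dialect are used: "Z" = methylated CpG,
## "z" = unmethylated CpG; every other character is ignored. States are
## never re-called from the sequence, so any aligner emitting the dialect
## is supported. Alignments are assumed ungapped (M-only CIGAR).

.xmString <- function(len, offsets, states) {
    x <- rep(".", len)
    x[offsets + 1L] <- ifelse(states == 1L, "Z", "z")
    paste(x, collapse = "")
}

#' Write reads as an XM-tagged BAM file
#'
#' Emits a SAM file with one `@SQ` line per chromosome and an `XM` tag per
#' read encoding the CpG methylation calls (Z/z), converts it to an indexed
#' BAM via [Rsamtools::asBam()]. Exercises the same on-disk dialect the
#' parser consumes, for end-to-end round trips.
#'
#' @param reads a [MethylReadSet].
#' @param seqlengths named integer vector of chromosome lengths (for a
#'   [SimRegionSet] use `simChromLengths()`).
#' @param path output path without extension (".bam" is appended).
#' @return path of the BAM file.
#' @export
writeMethylationBam <- function(reads, seqlengths, path) {
    sam <- sub("\\.bam$", "", path)
    sam <- paste0(sam, ".sam")
    con <- file(sam, "w")
    hdr <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                     as.integer(seqlengths)))
    writeLines(hdr, con)
    n <- length(reads)
    seqs <- as.character(reads@sequence)
    lens <- nchar(seqs)
    for (i in seq_len(n)) {
        xm <- .xmString(lens[i], reads@cpgOffsets[[i]], reads@cpgStates[[i]])
        writeLines(paste(readIds(reads)[i], 0L,
                         as.character(seqnames(reads@ranges))[i],
                         start(reads@ranges)[i], 42L,
                         paste0(lens[i], "M"), "*", 0L, 0L, seqs[i], "*",
                         paste0("XM:Z:", xm), sep = "\t"), con)
    }
    close(con)
    bam <- Rsamtools::asBam(sam, sub("\\.sam$", "", sam), overwrite = TRUE,
                            indexDestination = TRUE)
    unlink(sam)
    bam
}

#' Chromosome lengths of a simulated region set
#' @param regions a [SimRegionSet].
#' @return named integer vector.
#' @export
simChromLengths <- function(regions) {
    setNames(Biostrings::width(regions@chromSeq), names(regions@chromSeq))
}

#' Parse an XM-tagged BAM into a MethylReadSet
#'
#' Streams the reads overlapping `regions`, extracts CpG methylation calls
#' from the Z/z symbols of the `XM` tag, and assigns each read to the
#' overlapping region; a read spanning several regions goes to the one with
#' the larger base-pair overlap (tie: lower region start). Reads overlapping
#' no region are skipped, as are unmapped reads.
#'
#' @param path BAM path (must be indexed).
#' @param regions [GenomicRanges::GRanges] of target regions; a
#'   `regionIndex` metadata column is used when present.
#' @param missingTag `"skip"` (count and drop reads without an XM tag) or
#'   `"error"`.
#' @return A [MethylReadSet]; the number of tag-less reads skipped is
#'   reported via a message.
#' @export
parseMethylationBam <- function(path, regions,
                                missingTag = c("skip", "error")) {
    missingTag <- match.arg(missingTag)
    param <- Rsamtools::ScanBamParam(
        which = regions,
        what = c("qname", "rname", "pos", "strand", "seq"),
        tag = "XM",
        flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
    res <- Rsamtools::scanBam(path, param = param)
    qname <- unlist(lapply(res, `[[`, "qname"), use.names = FALSE)
    if (length(qname) == 0L)
        return(MethylReadSet(character(0), integer(0), DNAStringSet(),
                             list(), list()))
    rname <- unlist(lapply(res, function(x) as.character(x$rname)),
                    use.names = FALSE)
    pos <- unlist(lapply(res, `[[`, "pos"), use.names = FALSE)
    strand <- unlist(lapply(res, function(x) as.character(x$strand)),
                     use.names = FALSE)
    seq <- unlist(lapply(res, function(x) as.character(x$seq)),
                  use.names = FALSE)
    xm <- unlist(lapply(res, function(x) x$tag$XM), use.names = FALSE)
    keep <- !duplicated(qname)  # a read can match several which-ranges
    qname <- qname[keep]; rname <- rname[keep]; pos <- pos[keep]
    strand <- strand[keep]; seq <- seq[keep]; xm <- xm[keep]
    noTag <- is.na(xm)
    if (any(noTag)) {
        if (missingTag == "error")
            stop(sum(noTag), " read(s) without an XM tag")
        message(sum(noTag), " read(s) without an XM tag skipped")
        qname <- qname[!noTag]; rname <- rname[!noTag]; pos <- pos[!noTag]
        strand <- strand[!noTag]; seq <- seq[!noTag]; xm <- xm[!noTag]
    }
    readGr <- GRanges(rname, IRanges(start = pos, width = nchar(seq)))
    hits <- findOverlaps(readGr, regions)
    ov <- width(pintersect(readGr[S4Vectors::queryHits(hits)],
                           regions[S4Vectors::subjectHits(hits)]))
    ## per read: max overlap, tie -> lower region start
    ordHits <- order(S4Vectors::queryHits(hits), -ov,
                     start(regions)[S4Vectors::subjectHits(hits)])
    firstHit <- ordHits[!duplicated(S4Vectors::queryHits(hits)[ordHits])]
    assigned <- rep(NA_integer_, length(readGr))
    ri <- if (!is.null(mcols(regions)$regionIndex))
        mcols(regions)$regionIndex else seq_along(regions)
    assigned[S4Vectors::queryHits(hits)[firstHit]] <-
        ri[S4Vectors::subjectHits(hits)[firstHit]]
    inAny <- !is.na(assigned)
    calls <- lapply(strsplit(xm[inAny], ""), function(ch) {
        hit <- which(ch %in% c("Z", "z"))
        list(off = hit - 1L, st = as.integer(ch[hit] == "Z"))
    })
    MethylReadSet(chrom = rname[inAny], start = pos[inAny] - 1L,
                  sequence = seq[inAny],
                  cpgOffsets = lapply(calls, `[[`, "off"),
                  cpgStates = lapply(calls, `[[`, "st"),
                  regionIndex = assigned[inAny],
                  readId = qname[inAny], strand = strand[inAny])
}
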