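## Plain-text I/O: DMR tables, read tables, posterior tables, truth JSON.
##
## Coordinates are 0-based half-open internally and in all TSV output,
## matching BED; GRanges conversion happens at the boundaries.

#' Read a DMR table (BED-like with an areaStat column)
#'
#' Expects a tab-separated file with columns `chrom`, `start`, `end`,
#' `areaStat` (header optional; extra columns kept). Coordinates are BED
#' (0-based half-open).
#'
#' @param path file path.
#' @return A [GenomicRanges::GRanges] with `areaStat` and `regionIndex`
#'   metadata columns (regionIndex in file order).
#' @export
readDmrTable <- function(path) {
    first <- readLines(path, n = 1L)
    hasHeader <- grepl("chrom|start", first, ignore.case = TRUE)
    df <- read.delim(path, header = hasHeader, stringsAsFactors = FALSE)
    if (!hasHeader) {
        if (ncol(df) < 4L)
            stop("DMR table needs >= 4 columns: chrom, start, end, areaStat")
        colnames(df)[1:4] <- c("chrom", "start", "end", "areaStat")
    }
    need <- c("chrom", "start", "end", "areaStat")
    if (!all(need %in% colnames(df)))
        stop("DMR table is missing columns: ",
             paste(setdiff(need, colnames(df)), collapse = ", "))
    bad <- which(!is.finite(df$start) | !is.finite(df$end) |
                 df$start >= df$end | !is.finite(df$areaStat))
    if (length(bad))
        stop("malformed DMR row at line ",
             bad[1L] + as.integer(hasHeader),
             " (need start < end and numeric areaStat)")
    gr <- GRanges(df$chrom, IRanges(start = df$start + 1L, end = df$end))
    mcols(gr)$areaStat <- df$areaStat
    mcols(gr)$regionIndex <- seq_along(gr)
    gr
}

#' Select the top regions by areaStat
#'
#' Keeps the `n` regions with the largest `areaStat`, breaking ties
#' deterministically by (chrom, start). The standard workflow keeps the top
#' 100 DMRs by this score. `regionIndex` is re-assigned 1..n in the selected order.
#'
#' @param regions a [GenomicRanges::GRanges] with an `areaStat` column.
#' @param n number of regions to keep.
#' @return the selected `GRanges`.
#' @export
selectTopRegions <- function(regions, n = 100L) {
    if (n > length(regions)) {
        warning("requested ", n, " regions but only ", length(regions),
                " available; returning all")
        n <- length(regions)
    }
    ord <- order(-mcols(regions)$areaStat,
                 as.character(seqnames(regions)), start(regions))
    out <- regions[ord[seq_len(n)]]
    mcols(out)$regionIndex <- seq_len(n)
    out
}

#' Write / read a per-read table (TSV)
#'
#' Columns: read_id, chrom, start (0-based), strand, sequence, cpg_offsets
#' and cpg_states (comma-separated), region_index, cell_label.
#'
#' @param reads a [MethylReadSet].
#' @param path file path.
#' @return `writeReadTable()` returns `path` invisibly; `readReadTable()`
#'   returns a [MethylReadSet].
#' @export
writeReadTable <- function(reads, path) {
    df <- data.frame(
        read_id = readIds(reads),
        chrom = as.character(seqnames(reads@ranges)),
        start = start(reads@ranges) - 1L,
        strand = as.character(strand(reads@ranges)),
        sequence = as.character(reads@sequence),
        cpg_offsets = vapply(reads@cpgOffsets, paste, "", collapse = ","),
        cpg_states = vapply(reads@cpgStates, paste, "", collapse = ","),
        region_index = reads@regionIndex,
        cell_label = reads@cellLabel)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeReadTable
#' @export
readReadTable <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE,
                     colClasses = c(cpg_offsets = "character",
                                    cpg_states = "character"))
    parseInts <- function(x) lapply(strsplit(x, ","), function(v)
        as.integer(v[nzchar(v)]))
    MethylReadSet(chrom = df$chrom, start = df$start,
                  sequence = df$sequence,
                  cpgOffsets = parseInts(df$cpg_offsets),
                  cpgStates = parseInts(df$cpg_states),
                  regionIndex = df$region_index,
                  cellLabel = df$cell_label, readId = df$read_id,
                  strand = df$strand)
}

#' Write / read a posterior table (TSV)
#'
#' Header: read_id, region_index, one probability column per cell type,
#' predicted_label. Rows must sum to one (checked on read and write within
#' 1e-6); class priors are stored in `# prior:` comment lines.
#'
#' @param pt a [PosteriorTable].
#' @param path file path.
#' @return `writePosteriorTable()` returns `path` invisibly;
#'   `readPosteriorTable()` returns a [PosteriorTable].
#' @export
writePosteriorTable <- function(pt, path) {
    validObject(pt)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# prior:%s=%.10g", pt@classes, pt@priors), con)
    df <- data.frame(read_id = pt@readId, region_index = pt@regionIndex,
                     check.names = FALSE)
    for (j in seq_along(pt@classes))
        df[[pt@classes[j]]] <- sprintf("%.10g", pt@posterior[, j])
    df$predicted_label <- if (length(pt) > 0) predictedLabel(pt)
                          else character(0)
    df$true_label <- pt@trueLabel
    suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                                 row.names = FALSE))
    invisible(path)
}

#' @rdname writePosteriorTable
#' @export
readPosteriorTable <- function(path) {
    lines <- readLines(path)
    priorLines <- grep("^# prior:", lines, value = TRUE)
    priors <- vapply(strsplit(sub("^# prior:", "", priorLines), "="),
                     function(x) as.numeric(x[2]), numeric(1))
    names(priors) <- vapply(strsplit(sub("^# prior:", "", priorLines), "="),
                            `[`, "", 1L)
    body <- lines[!grepl("^# ", lines)]
    df <- read.delim(text = paste(body, collapse = "\n"),
                     stringsAsFactors = FALSE, check.names = FALSE)
    classes <- names(priors)
    post <- as.matrix(df[, classes, drop = FALSE])
    if (nrow(post) > 0 && any(abs(rowSums(post) - 1) > 1e-6))
        stop("posterior rows must sum to 1 within 1e-6")
    PosteriorTable(readId = df$read_id, regionIndex = df$region_index,
                   posterior = post, priors = priors, classes = classes,
                   trueLabel = if ("true_label" %in% colnames(df))
                       df$true_label else NA_character_)
}

#' Write a pseudo-bulk ground-truth record as JSON
#'
#' @param truth the `truth` list from [mixPseudobulk()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeTruth <- function(truth, path) {
    write_json(truth, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
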