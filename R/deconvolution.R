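## From per-read posteriors to bulk composition: Bayes inversion,
## grid-search maximum likelihood, skewness-based adjustment, Fisher
## information, multi-class fractions and methylation reconstruction.

#' Invert posteriors into class-conditional read scores
#'
#' Applies Bayes' rule under the equal-read-marginal assumption:
#' `score(r, c) = P(c | r) / P(c)`, proportional to `P(r | c)` up to a
#' read-constant factor. For numerical stability each read's scores are
#' divided by their maximum; every downstream argmax over the mixing
#' parameter is invariant to such per-read constants.
#'
#' @param pt a [PosteriorTable] with strictly positive priors.
#' @param normalise divide each row by its maximum (default TRUE).
#' @return numeric matrix N x C of scores.
#' @export
invertPosteriors <- function(pt, normalise = TRUE) {
    if (any(pt@priors <= 0)) stop("class priors must be strictly positive")
    sc <- sweep(pt@posterior, 2L, pt@priors, `/`)
    if (normalise && nrow(sc) > 0) {
        mx <- pmax(apply(sc, 1L, max), .Machine$double.xmin)
        sc <- sc / mx
    }
    sc
}

## Log-likelihood of the two-class mixture at each grid delta, evaluated in
## chunks to bound memory. scores: N x 2 (Tumour, Normal).
.gridLoglik <- function(scores, grid) {
    a <- scores[, 1L] - scores[, 2L]
    b <- scores[, 2L]
    out <- numeric(length(grid))
    chunk <- max(1L, floor(5e6 / max(1L, length(a))))
    for (i in seq(1L, length(grid), by = chunk)) {
        j <- i:min(i + chunk - 1L, length(grid))
        out[j] <- colSums(log(outer(a, grid[j]) + b))
    }
    out
}

#' Grid-search maximum-likelihood tumour purity
#'
#' Maximises `sum_i log[delta * score_T(r_i) + (1 - delta) * score_N(r_i)]`
#' over the grid `{0, gridStep, ..., 1}` (default step 1e-4). Reads whose
#' two scores are both zero are dropped with a warning; ties are broken
#' toward the smallest delta and a perfectly flat likelihood is flagged.
#'
#' @param scores numeric N x 2 matrix of inverted scores, tumour column
#'   first (see [invertPosteriors()]).
#' @param gridStep grid resolution.
#' @return list with `delta` (the MLE), `flat` (logical), `loglik`
#'   (log-likelihood at the optimum).
#' @export
purityMLE <- function(scores, gridStep = 1e-4) {
    scores <- as.matrix(scores)
    if (nrow(scores) == 0L) stop("needs at least one read")
    zero <- rowSums(scores) == 0
    if (any(zero)) {
        warning(sum(zero), " read(s) with all-zero scores dropped")
        scores <- scores[!zero, , drop = FALSE]
        if (nrow(scores) == 0L) stop("no reads left after dropping zeros")
    }
    grid <- seq(0, 1, by = gridStep)
    ll <- .gridLoglik(scores, grid)
    ok <- is.finite(ll)
    if (!any(ok))
        return(list(delta = 0, flat = TRUE, loglik = -Inf))
    best <- which(ok)[which.max(ll[ok])]   # which.max: first = smallest delta
    flat <- (max(ll[ok]) - min(ll[ok])) < 1e-12
    list(delta = grid[if (flat) which(ok)[1L] else best], flat = flat,
         loglik = max(ll[ok]))
}

#' Region-wise tumour purities
#'
#' Applies [purityMLE()] independently to the reads of each region. Regions
#' without reads are absent from the result; the vector is named by region
#' index.
#'
#' @param scores numeric N x 2 matrix of inverted scores.
#' @param regionIndex integer region id per read.
#' @param gridStep grid resolution.
#' @return named numeric vector of region purities.
#' @export
regionPurities <- function(scores, regionIndex, gridStep = 1e-4) {
    idx <- split(seq_along(regionIndex), regionIndex)
    vapply(idx, function(i)
        purityMLE(scores[i, , drop = FALSE], gridStep)$delta, numeric(1))
}

#' Adjusted Fisher-Pearson standardised moment coefficient (G1)
#'
#' `G1 = m3 * sqrt(K (K - 1)) / (m2^{3/2} (K - 2))` with central sample
#' moments `m_t` about the mean.
#'
#' @param values numeric vector, length >= 3, non-zero variance.
#' @return the skewness (numeric scalar).
#' @export
#' @examples
#' skewnessG1(c(0, 0, 1))  # sqrt(3)
skewnessG1 <- function(values) {
    K <- length(values)
    if (K < 3L) stop("G1 needs at least 3 values")
    mu <- mean(values)
    m2 <- mean((values - mu)^2)
    m3 <- mean((values - mu)^3)
    if (m2 == 0) stop("G1 undefined for zero variance")
    m3 * sqrt(K * (K - 1)) / (m2^1.5 * (K - 2))
}

#' Skewness-minimising adjustment of region-wise purities
#'
#' Finds mapping parameters `W` minimising `|G1(W o delta)|` subject to
#' `W_k delta_k` in [0, 1], by cyclic coordinate-wise line searches started
#' from `W = 1` (each sweep holds all but one `W_k` fixed and line-searches
#' it inside the box), until the skewness change drops below `tol` or
#' `maxSweeps` sweeps. The adjusted purity is the unweighted mean of the
#' mapped region purities, `mean(W o delta)`.
#'
#' @param deltas numeric vector of region-wise purities (length >= 3 with
#'   at least two distinct values for an actual adjustment; otherwise
#'   `W = 1` is returned).
#' @param tol convergence tolerance on |G1|.
#' @param maxSweeps maximum coordinate sweeps.
#' @return list with `W`, `adjusted`, `skewBefore`, `skewAfter`, `sweeps`.
#' @export
adjustEstimate <- function(deltas, tol = 1e-8, maxSweeps = 500L) {
    K <- length(deltas)
    if (K < 3L || length(unique(deltas)) < 2L)
        return(list(W = rep(1, K), adjusted = mean(deltas),
                    skewBefore = NA_real_, skewAfter = NA_real_,
                    sweeps = 0L))
    W <- rep(1, K)
    obj <- function(W) {
        x <- W * deltas
        if (var(x) == 0) 0 else abs(skewnessG1(x))
    }
    cur <- obj(W)
    skewBefore <- skewnessG1(deltas)
    sweeps <- 0L
    repeat {
        sweeps <- sweeps + 1L
        prev <- cur
        for (k in seq_len(K)) {
            if (deltas[k] == 0) next
            up <- 1 / deltas[k]          # keeps W_k * delta_k in [0, 1]
            f <- function(w) { W2 <- W; W2[k] <- w; obj(W2) }
            o <- optimize(f, c(0, up))
            if (o$objective < cur - 1e-15) {
                W[k] <- o$minimum
                cur <- o$objective
            }
        }
        if (abs(prev - cur) < tol || sweeps >= maxSweeps) break
    }
    mapped <- pmin(pmax(W * deltas, 0), 1)
    list(W = W, adjusted = mean(mapped), skewBefore = skewBefore,
         skewAfter = if (var(mapped) == 0) 0 else skewnessG1(mapped),
         sweeps = sweeps)
}

#' @rdname adjustEstimate
#' @details `adjustEstimateDirect()` is an independent cross-check that
#'   minimises the squared skewness with a box-constrained quasi-Newton
#'   optimiser instead of coordinate descent.
#' @export
adjustEstimateDirect <- function(deltas) {
    K <- length(deltas)
    if (K < 3L || length(unique(deltas)) < 2L)
        return(list(W = rep(1, K), adjusted = mean(deltas)))
    obj <- function(W) {
        x <- W * deltas
        if (var(x) == 0) return(0)
        skewnessG1(x)^2
    }
    up <- ifelse(deltas > 0, 1 / deltas, 1)
    o <- optim(rep(1, K), obj, method = "L-BFGS-B", lower = 0, upper = up)
    mapped <- pmin(pmax(o$par * deltas, 0), 1)
    list(W = o$par, adjusted = mean(mapped))
}

#' Fisher information of the purity estimate
#'
#' The variance of the per-read score contribution
#' `s_i = (score_T - score_N) / (delta * score_T + (1 - delta) * score_N)`,
#' i.e. the variance of the derivative of the log-likelihood. Reads with a
#' zero denominator are excluded with a warning.
#'
#' @param scores numeric N x 2 matrix of inverted scores.
#' @param delta mixing parameter in (0, 1).
#' @return the Fisher information (numeric scalar, >= 0).
#' @export
fisherInformation <- function(scores, delta) {
    if (delta <= 0 || delta >= 1) stop("delta must be in (0, 1)")
    den <- delta * scores[, 1L] + (1 - delta) * scores[, 2L]
    bad <- den == 0
    if (any(bad)) {
        warning(sum(bad), " read(s) with zero mixture density excluded")
        scores <- scores[!bad, , drop = FALSE]
        den <- den[!bad]
    }
    s <- (scores[, 1L] - scores[, 2L]) / den
    if (length(s) < 2L) return(0)
    var(s)
}

#' Estimate tumour purity from a posterior table
#'
#' The full estimation pipeline: Bayes inversion, global grid-search MLE,
#' region-wise purities, optional skewness-minimising adjustment (the
#' adjusted estimate is the mean of the mapped region purities), and Fisher
#' information - per region when adjustment is applied (the global
#' single-value information is undefined for the adjusted estimator), one
#' global value otherwise.
#'
#' @param pt a two-class [PosteriorTable]; the first configured class is
#'   taken as the tumour class unless `tumourClass` says otherwise.
#' @param adjust apply the skewness adjustment.
#' @param gridStep grid resolution of the MLE search.
#' @param tumourClass name of the tumour class.
#' @return A [PurityResult].
#' @export
estimatePurity <- function(pt, adjust = TRUE, gridStep = 1e-4,
                           tumourClass = pt@classes[1L]) {
    if (length(pt@classes) != 2L)
        stop("purity estimation is defined for exactly two classes")
    ord <- c(match(tumourClass, pt@classes),
             setdiff(1:2, match(tumourClass, pt@classes)))
    sc <- invertPosteriors(pt)[, ord, drop = FALSE]
    gl <- purityMLE(sc, gridStep)
    rd <- regionPurities(sc, pt@regionIndex, gridStep)
    if (adjust) {
        ad <- adjustEstimate(rd)
        byReg <- split(seq_along(pt@regionIndex), pt@regionIndex)
        fi <- vapply(seq_along(byReg), function(k) {
            d <- min(max(rd[k], gridStep), 1 - gridStep)
            fisherInformation(sc[byReg[[k]], , drop = FALSE], d)
        }, numeric(1))
        names(fi) <- names(byReg)
        new("PurityResult", deltaHat = gl$delta, regionDeltas = rd,
            W = ad$W, adjustedDelta = ad$adjusted,
            fisherInformation = fi, gridStep = gridStep, flat = gl$flat,
            skewBefore = ad$skewBefore, skewAfter = ad$skewAfter)
    } else {
        d <- min(max(gl$delta, gridStep), 1 - gridStep)
        new("PurityResult", deltaHat = gl$delta, regionDeltas = rd,
            W = rep(1, length(rd)), adjustedDelta = NA_real_,
            fisherInformation = fisherInformation(sc, d),
            gridStep = gridStep, flat = gl$flat, skewBefore = NA_real_,
            skewAfter = NA_real_)
    }
}

#' Multi-class cell-type fraction estimation
#'
#' For each class `c`, over the reads classified into `c` (argmax
#' posterior), `theta_c` maximises
#' `prod_r [theta_c P(r|c) + (1 - theta_c)(1 - P(r|c))]` on the grid, where
#' `P(r|c)` is the inverted score rescaled per read to sum to one across
#' classes. Because each `theta_c` tends to 1 under a confident classifier,
#' the reported composition is `fraction_c` proportional to
#' `theta_c * |R_c|`, normalised to sum to one (reducing to the
#' classified-read share in the certainty limit). Classes with no
#' classified reads get fraction 0.
#'
#' @param pt a [PosteriorTable] with C >= 2 classes.
#' @param gridStep grid resolution.
#' @return A [CellFractionResult].
#' @export
cellFractions <- function(pt, gridStep = 1e-4) {
    if (length(pt) == 0L) stop("empty posterior table")
    C <- length(pt@classes)
    sc <- invertPosteriors(pt, normalise = FALSE)
    prc <- sc / rowSums(sc)               # read-normalised P(r | c) proxy
    lab <- max.col(pt@posterior, ties.method = "first")
    grid <- seq(0, 1, by = gridStep)
    theta <- setNames(numeric(C), pt@classes)
    counts <- setNames(integer(C), pt@classes)
    for (j in seq_len(C)) {
        rows <- which(lab == j)
        counts[j] <- length(rows)
        if (length(rows) == 0L) { theta[j] <- 0; next }
        p <- prc[rows, j]
        a <- 2 * p - 1                    # theta*p + (1-theta)*(1-p)
        b <- 1 - p
        ll <- vapply(grid, function(d) sum(log(pmax(a * d + b, 1e-300))),
                     numeric(1))
        theta[j] <- grid[which.max(ll)]
    }
    raw <- theta * counts
    fractions <- if (sum(raw) > 0) raw / sum(raw)
                 else rep(1 / C, C)
    names(fractions) <- pt@classes
    new("CellFractionResult", theta = theta, counts = counts,
        fractions = fractions, gridStep = gridStep)
}

#' Reconstructed cell-type methylation levels
#'
#' For every (region, predicted class) pair, the mean over the assigned
#' reads of the per-read methylated-CpG fraction. Pairs without reads are
#' `NA` (missing, not zero).
#'
#' @param reads a [MethylReadSet] (provides the CpG states and regions).
#' @param labels predicted class per read, e.g. `predictedLabel(pt)`.
#' @param classes class names ordering the columns.
#' @return numeric matrix regions x classes of mean methylation levels.
#' @export
reconstructMethylation <- function(reads, labels,
                                   classes = sort(unique(labels))) {
    m <- readMethylationLevel(reads)
    reg <- reads@regionIndex
    regs <- sort(unique(reg))
    out <- matrix(NA_real_, length(regs), length(classes),
                  dimnames = list(as.character(regs), classes))
    for (i in seq_along(regs)) for (j in seq_along(classes)) {
        sel <- reg == regs[i] & labels == classes[j] & !is.na(m)
        if (any(sel)) out[i, j] <- mean(m[sel])
    }
    out
}
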