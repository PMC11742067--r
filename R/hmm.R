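## Two-state HMM baseline read classifier.
##
## Observations are the ordered binary CpG states of a read (inter-CpG
## genomic distance is ignored); hidden states model whether a CpG is
## differentially methylated between the cell types. One HMM is fitted per
## cell type by Baum-Welch; a read is classified to the cell type whose
## model gives the larger forward-algorithm likelihood (ties -> Normal,
## i.e. the last class).

## Scaled forward pass; obs in {1, 2} (unmethylated, methylated).
.hmmForward <- function(init, trans, emis, obs) {
    Tn <- length(obs)
    alpha <- init * emis[, obs[1L]]
    c1 <- sum(alpha)
    ll <- log(c1)
    alpha <- alpha / c1
    if (Tn > 1L) for (t in 2:Tn) {
        alpha <- as.vector(crossprod(trans, alpha)) * emis[, obs[t]]
        ct <- sum(alpha)
        ll <- ll + log(ct)
        alpha <- alpha / ct
    }
    ll
}

#' Forward-algorithm log-likelihood of a CpG-state sequence
#'
#' @param model a `list(init, trans, emis)` HMM parameter set (2 states;
#'   emission columns: unmethylated, methylated).
#' @param states integer vector of 0/1 methylation states.
#' @return the log-likelihood.
#' @export
hmmLoglik <- function(model, states) {
    if (length(states) < 1L) stop("needs at least one CpG state")
    .hmmForward(model$init, model$trans, model$emis,
                as.integer(states) + 1L)
}

## One Baum-Welch run on a list of 0/1 sequences from a given start.
.baumWelch <- function(seqs, init, trans, emis, maxIter = 100L,
                       tol = 1e-6) {
    obs <- lapply(seqs, function(s) as.integer(s) + 1L)
    prev <- -Inf
    for (iter in seq_len(maxIter)) {
        iNum <- numeric(2)
        tNum <- matrix(0, 2, 2)
        eNum <- matrix(0, 2, 2)
        ll <- 0
        for (o in obs) {
            Tn <- length(o)
            alpha <- matrix(0, 2, Tn)
            cs <- numeric(Tn)
            a <- init * emis[, o[1L]]
            cs[1L] <- sum(a)
            alpha[, 1L] <- a / cs[1L]
            if (Tn > 1L) for (t in 2:Tn) {
                a <- as.vector(crossprod(trans, alpha[, t - 1L])) *
                    emis[, o[t]]
                cs[t] <- sum(a)
                alpha[, t] <- a / cs[t]
            }
            beta <- matrix(0, 2, Tn)
            beta[, Tn] <- 1
            if (Tn > 1L) for (t in (Tn - 1L):1L)
                beta[, t] <- trans %*% (emis[, o[t + 1L]] *
                                        beta[, t + 1L]) / cs[t + 1L]
            gam <- alpha * beta
            gam <- sweep(gam, 2L, colSums(gam), `/`)
            iNum <- iNum + gam[, 1L]
            for (t in seq_len(Tn))
                eNum[, o[t]] <- eNum[, o[t]] + gam[, t]
            if (Tn > 1L) for (t in seq_len(Tn - 1L)) {
                xi <- trans * outer(alpha[, t],
                                    emis[, o[t + 1L]] * beta[, t + 1L]) /
                    cs[t + 1L]
                tNum <- tNum + xi
            }
            ll <- ll + sum(log(cs))
        }
        init <- iNum / sum(iNum)
        rowT <- rowSums(tNum)
        if (all(rowT > 0)) trans <- tNum / rowT
        emis <- eNum / rowSums(eNum)
        emis <- pmin(pmax(emis, 1e-6), 1 - 1e-6)
        emis <- emis / rowSums(emis)
        if (is.finite(prev) && abs(ll - prev) < tol) break
        prev <- ll
    }
    list(model = list(init = init, trans = trans, emis = emis),
         loglik = ll)
}

#' Fit the two-state HMM baseline
#'
#' Fits one HMM per cell type by Baum-Welch on that cell type's CpG-state
#' sequences, with `nRestarts` seeded random restarts (best final
#' likelihood kept). Reads without CpGs are skipped. The training
#' log-likelihood is non-decreasing across EM iterations.
#'
#' @param reads a labelled [MethylReadSet].
#' @param nRestarts random restarts per cell type.
#' @param seed integer seed.
#' @return An [HmmClassifier] with training-set class frequencies as
#'   priors.
#' @export
fitHmm <- function(reads, nRestarts = 5L, seed = 1L) {
    lab <- reads@cellLabel
    if (anyNA(lab)) stop("all reads must carry a cell label")
    classes <- sort(unique(lab))
    ## keep Normal last so that the tie rule resolves to it
    if ("Normal" %in% classes)
        classes <- c(setdiff(classes, "Normal"), "Normal")
    set.seed(seed)
    models <- list()
    for (cl in classes) {
        seqs <- as.list(reads@cpgStates[lab == cl])
        seqs <- seqs[lengths(seqs) >= 1L]
        if (length(seqs) == 0L)
            stop("cell type ", cl, " has no reads with CpGs")
        best <- NULL
        for (r in seq_len(nRestarts)) {
            init <- runif(2); init <- init / sum(init)
            trans <- matrix(runif(4, 0.1, 0.9), 2, 2)
            trans <- trans / rowSums(trans)
            emis <- matrix(runif(4, 0.1, 0.9), 2, 2)
            emis <- emis / rowSums(emis)
            fit <- .baumWelch(seqs, init, trans, emis)
            if (is.null(best) || fit$loglik > best$loglik) best <- fit
        }
        models[[cl]] <- best$model
    }
    priors <- table(factor(lab, levels = classes))
    new("HmmClassifier", models = models, classes = classes,
        priors = setNames(as.numeric(priors) / length(lab), classes))
}

#' Classify reads with the HMM baseline
#'
#' Each read is assigned to the cell type whose fitted HMM gives the
#' larger forward-algorithm likelihood of its CpG-state sequence (ties go
#' to Normal / the last class). Per-class log-likelihoods are converted to
#' pseudo-posteriors by normalised exponentiation so the output is
#' interchangeable with the Transformer's [PosteriorTable]. Reads without
#' CpGs are unclassifiable and dropped with a message.
#'
#' @param classifier an [HmmClassifier].
#' @param reads a [MethylReadSet].
#' @return A [PosteriorTable].
#' @export
classifyReadsHmm <- function(classifier, reads) {
    k <- S4Vectors::elementNROWS(reads@cpgStates)
    if (any(k == 0L)) {
        message(sum(k == 0L), " read(s) without CpGs are unclassifiable ",
                "and were dropped")
        reads <- reads[k > 0L]
    }
    n <- length(reads)
    C <- length(classifier@classes)
    ll <- matrix(0, n, C)
    for (i in seq_len(n)) for (j in seq_len(C))
        ll[i, j] <- hmmLoglik(classifier@models[[classifier@classes[j]]],
                              reads@cpgStates[[i]])
    ## ties (equal logliks) must go to the last class (Normal): argmax with
    ## ties.method = "last" via reversed max.col
    post <- exp(ll - apply(ll, 1L, max))
    post <- post / rowSums(post)
    colnames(post) <- classifier@classes
    ## nudge exact ties toward the last class so predictedLabel() respects
    ## the tie rule
    tie <- abs(post[, 1L] - post[, C]) < 1e-12 & C == 2L
    if (any(tie)) post[tie, C] <- post[tie, C] + 1e-9
    post <- post / rowSums(post)
    PosteriorTable(readId = readIds(reads),
                   regionIndex = reads@regionIndex, posterior = post,
                   priors = classifier@priors,
                   classes = classifier@classes,
                   trueLabel = reads@cellLabel)
}
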