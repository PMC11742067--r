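## Synthetic posterior generators for benchmarking the estimation stack
## independently of any trained classifier.
##
## Two-class reads are modelled through a calibrated Gaussian
## log-likelihood-ratio channel: for a read of true class T/N the log-LR is
## drawn from N(+mu, 2 mu) / N(-mu, 2 mu), which makes exp(lambda) the exact
## likelihood ratio of the observation, so the reported posteriors are
## calibrated by construction. Miscalibration is injected afterwards by
## sharpening (lambda * s) and shifting (lambda + b), and region-level
## contamination by biasing whole regions.

#' Simulate calibrated (or deliberately miscalibrated) two-class posteriors
#'
#' Region tumour shares are drawn around `tumourFraction` with an
#' overdispersion controlled by `regionConcentration`; per read the truth
#' is Bernoulli(region share) and the posterior comes from the calibrated
#' log-LR channel with separability `separation` (larger = sharper, more
#' informative posteriors). `sharpen`/`bias` distort all reads;
#' `nContaminated` whole regions additionally receive `contaminationBias`
#' on the log-LR scale (emulating non-specific DMRs where reads of either
#' class look tumour-like), which skews the region-purity distribution.
#'
#' @param nReads total reads.
#' @param tumourFraction ground-truth global tumour fraction.
#' @param nRegions number of regions (reads split evenly).
#' @param separation log-LR channel separation mu > 0.
#' @param regionConcentration Beta concentration of region shares around
#'   `tumourFraction` (larger = more homogeneous regions).
#' @param sharpen,bias global miscalibration: reported log-LR =
#'   `sharpen * lambda + bias`.
#' @param nContaminated number of contaminated regions.
#' @param contaminationBias log-LR shift applied in contaminated regions.
#' @param seed integer seed.
#' @return A [PosteriorTable] with classes Tumour/Normal, priors
#'   (`tumourFraction`, 1 - `tumourFraction`) and the truth in `trueLabel`.
#' @export
simulateCalibratedPosteriors <- function(nReads, tumourFraction,
                                         nRegions = 20L, separation = 2,
                                         regionConcentration = 30,
                                         sharpen = 1, bias = 0,
                                         nContaminated = 0L,
                                         contaminationBias = 3,
                                         seed = 1L) {
    stopifnot(separation > 0, tumourFraction >= 0, tumourFraction <= 1)
    set.seed(seed)
    perRegion <- rep(nReads %/% nRegions, nRegions)
    perRegion[seq_len(nReads %% nRegions)] <-
        perRegion[seq_len(nReads %% nRegions)] + 1L
    f <- if (tumourFraction %in% c(0, 1)) rep(tumourFraction, nRegions)
         else rbeta(nRegions, tumourFraction * regionConcentration,
                    (1 - tumourFraction) * regionConcentration)
    contam <- seq_len(nRegions) <= nContaminated
    reg <- rep(seq_len(nRegions), perRegion)
    truth <- rbinom(nReads, 1L, f[reg])
    lambda <- rnorm(nReads, mean = ifelse(truth == 1L, separation,
                                          -separation),
                    sd = sqrt(2 * separation))
    lambda <- sharpen * lambda + bias + contaminationBias * contam[reg]
    prior <- min(max(tumourFraction, 1e-3), 1 - 1e-3)
    pT <- prior * exp(lambda) / (prior * exp(lambda) + (1 - prior))
    pT <- pmin(pmax(pT, 1e-12), 1 - 1e-12)
    PosteriorTable(readId = sprintf("r%06d", seq_len(nReads)),
                   regionIndex = reg,
                   posterior = cbind(Tumour = pT, Normal = 1 - pT),
                   priors = c(Tumour = prior, Normal = 1 - prior),
                   trueLabel = ifelse(truth == 1L, "Tumour", "Normal"))
}

#' Simulate multi-class posteriors at a known mixing
#'
#' Read truths are multinomial at `fractions`; per read the true class
#' activation receives a `boost` on top of Gaussian noise and the posterior
#' is the softmax, giving a sharp but imperfect classifier.
#'
#' @param nReads total reads.
#' @param fractions named numeric mixing proportions (sum to 1).
#' @param boost activation margin of the true class.
#' @param noiseSd activation noise standard deviation.
#' @param nRegions number of regions (round-robin assignment).
#' @param seed integer seed.
#' @return A [PosteriorTable] with uniform priors and the truth in
#'   `trueLabel`.
#' @export
simulateMulticlassPosteriors <- function(nReads, fractions, boost = 6,
                                         noiseSd = 1.5, nRegions = 20L,
                                         seed = 1L) {
    stopifnot(abs(sum(fractions) - 1) < 1e-8)
    C <- length(fractions)
    classes <- names(fractions)
    if (is.null(classes)) classes <- paste0("cell", seq_len(C))
    set.seed(seed)
    truth <- sample.int(C, nReads, replace = TRUE, prob = fractions)
    x <- matrix(rnorm(nReads * C, sd = noiseSd), nReads, C)
    x[cbind(seq_len(nReads), truth)] <- x[cbind(seq_len(nReads), truth)] +
        boost
    post <- exp(x - apply(x, 1L, max))
    post <- post / rowSums(post)
    colnames(post) <- classes
    PosteriorTable(readId = sprintf("r%06d", seq_len(nReads)),
                   regionIndex = rep_len(seq_len(nRegions), nReads),
                   posterior = post, priors = rep(1 / C, C),
                   classes = classes, trueLabel = classes[truth])
}
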