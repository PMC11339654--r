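#' Create a simulation configuration
#'
#' Defaults describe the study conditions the package was designed around:
#' five diploid founders sampled ~22 generations after establishment, founder
#' ancestry drawn ~75% from source 1 (a taurine-like source) and ~25% from
#' source 2 (a zebu-like source), sources separated by 200 generations of
#' drift at diploid size 500, rapid geometric expansion to an effective size
#' of 1,500 after founding, five functional classes with purifying selection
#' on the deleterious ones, ~10x sequencing depth, and a uniform 1 cM/Mb map.
#'
#' @param nFounders,admixtureFraction,tBottleneck,tDivergence,tSisterSplit
#'   demography; see \linkS4class{SimConfig}.
#' @param sourceSize,ancestralSize,burnIn,expansionSize,growthRate population
#'   sizes (diploids) and growth.
#' @param nSites,nChrom,chromLength site layout.
#' @param classProportions,selectionS,selectionH per-class composition and
#'   selection (named by class).
#' @param nSampled,meanDepth,errorRate,mapRate,seed sampling and noise model.
#' @return a validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(nSites = 1000, seed = 7)
#' @export
simConfig <- function(nFounders = 5, admixtureFraction = 0.75,
                      tBottleneck = 22, tDivergence = 200,
                      tSisterSplit = 100, sourceSize = 500,
                      ancestralSize = 500, burnIn = 100,
                      expansionSize = 1500, growthRate = 3,
                      nSites = 50000, nChrom = 5, chromLength = 5e7,
                      classProportions = c(intergenic = 0.70,
                                           synonymous = 0.10,
                                           ns_tolerated = 0.10,
                                           ns_deleterious = 0.07,
                                           lof = 0.03),
                      selectionS = c(intergenic = 0, synonymous = 0,
                                     ns_tolerated = -0.001,
                                     ns_deleterious = -0.02, lof = -0.1),
                      selectionH = c(intergenic = 0.5, synonymous = 0.5,
                                     ns_tolerated = 0.5, ns_deleterious = 0.3,
                                     lof = 0.1),
                      nSampled = 8, meanDepth = 10, errorRate = 0.001,
                      mapRate = 1, seed = 1L) {
    cfg <- new("SimConfig", nFounders = nFounders,
               admixtureFraction = admixtureFraction,
               tBottleneck = tBottleneck, tDivergence = tDivergence,
               tSisterSplit = tSisterSplit, sourceSize = sourceSize,
               ancestralSize = ancestralSize, burnIn = burnIn,
               expansionSize = expansionSize, growthRate = growthRate,
               nSites = nSites, nChrom = nChrom, chromLength = chromLength,
               classProportions = classProportions[.variantClasses],
               selectionS = selectionS[.variantClasses],
               selectionH = selectionH[.variantClasses],
               nSampled = nSampled, meanDepth = meanDepth,
               errorRate = errorRate, mapRate = mapRate, seed = seed)
    validObject(cfg)
    cfg
}

#' Wright-Fisher drift of allele frequencies, with selection
#'
#' Evolves a vector of derived-allele frequencies through \code{generations}
#' rounds of Wright-Fisher binomial resampling in a diploid population of
#' size \code{size}, with genotype fitnesses 1, 1+hs, 1+s for 0, 1, 2 copies
#' of the derived allele. Vectorized over sites (sites are unlinked).
#'
#' @param p numeric vector of frequencies in [0, 1].
#' @param size diploid population size (scalar or per-generation vector).
#' @param generations number of generations.
#' @param s,h selection and dominance coefficients (scalars or per-site
#'   vectors).
#' @return frequency vector after drift.
#' @export
driftFrequencies <- function(p, size, generations, s = 0, h = 0.5) {
    if (generations <= 0) return(p)
    sizes <- rep_len(size, generations)
    for (g in seq_len(generations)) {
        q <- 1 - p
        w11 <- 1 + s; w01 <- 1 + h * s
        wbar <- p^2 * w11 + 2 * p * q * w01 + q^2
        psel <- p * (p * w11 + q * w01) / wbar
        p <- stats::rbinom(length(p), 2L * sizes[g], psel) / (2 * sizes[g])
    }
    p
}

.neutralInitFreq <- function(n, twoN) {
    k <- seq_len(twoN - 1L)
    sample(k, n, replace = TRUE, prob = 1 / k) / twoN
}

.sitePositions <- function(cfg) {
    perChrom <- diff(round(seq(0, cfg@nSites, length.out = cfg@nChrom + 1L)))
    chrom <- rep(as.character(seq_len(cfg@nChrom)), perChrom)
    pos <- unlist(lapply(perChrom, function(k)
        sort(sample.int(cfg@chromLength, k))), use.names = FALSE)
    list(chrom = chrom, pos = pos)
}

#' Simulate an admixed founder-bottleneck cohort
#'
#' Per-site Wright-Fisher frequency engine (sites are unlinked): ancestral
#' burn-in under class-specific purifying selection, divergence of two source
#' populations (with a sister population of source 1 and an outgroup for
#' F4-ratio designs), founding of the target from \code{nFounders} diploids
#' whose ancestry mixes the two sources, then geometric expansion under
#' continued selection. Phased haplotypes are sampled from the final
#' frequencies for five population samples: \code{TARGET}, the two source
#' controls \code{SRC1}/\code{SRC2}, the sister \code{SIS1} and \code{OUT}.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @return list with elements \code{panel} (\linkS4class{HaplotypePanel}) and
#'   \code{truth} (\linkS4class{SimTruth}).
#' @examples
#' sim <- simulateCohort(simConfig(nSites = 500, nSampled = 4, seed = 3))
#' sim$panel
#' @export
simulateCohort <- function(cfg) {
    validObject(cfg)
    set.seed(cfg@seed)
    n <- cfg@nSites
    classes <- sample(.variantClasses, n, replace = TRUE,
                      prob = cfg@classProportions)
    s <- cfg@selectionS[classes]
    h <- cfg@selectionH[classes]

    p <- .neutralInitFreq(n, 2L * cfg@ancestralSize)
    p <- driftFrequencies(p, cfg@ancestralSize, cfg@burnIn, s, h)

    tOut <- cfg@tDivergence + cfg@tBottleneck
    pOut <- driftFrequencies(p, cfg@sourceSize, tOut, s, h)

    tShared1 <- cfg@tDivergence - cfg@tSisterSplit
    p1pre <- driftFrequencies(p, cfg@sourceSize, tShared1, s, h)
    p1 <- driftFrequencies(p1pre, cfg@sourceSize, cfg@tSisterSplit, s, h)
    pSis <- driftFrequencies(p1pre, cfg@sourceSize, cfg@tSisterSplit, s, h)
    p2 <- driftFrequencies(p, cfg@sourceSize, cfg@tDivergence, s, h)

    pFounderExp <- cfg@admixtureFraction * p1 + (1 - cfg@admixtureFraction) * p2
    pFounder <- stats::rbinom(n, 2L * cfg@nFounders, pFounderExp) /
        (2 * cfg@nFounders)
    sizes <- pmin(cfg@expansionSize,
                  round(cfg@nFounders * cfg@growthRate^seq_len(cfg@tBottleneck)))
    pTarget <- driftFrequencies(pFounder, sizes, cfg@tBottleneck, s, h)

    p1 <- driftFrequencies(p1, cfg@sourceSize, cfg@tBottleneck, s, h)
    pSis <- driftFrequencies(pSis, cfg@sourceSize, cfg@tBottleneck, s, h)
    p2 <- driftFrequencies(p2, cfg@sourceSize, cfg@tBottleneck, s, h)

    freq <- cbind(TARGET = pTarget, SRC1 = p1, SRC2 = p2, SIS1 = pSis,
                  OUT = pOut)
    pops <- colnames(freq)
    nh <- 2L * cfg@nSampled
    haps <- matrix(0L, n, nh * length(pops))
    for (j in seq_along(pops)) {
        cols <- (j - 1L) * nh + seq_len(nh)
        haps[, cols] <- stats::rbinom(n * nh, 1L, freq[, j])
    }
    layout <- .sitePositions(cfg)
    panel <- HaplotypePanel(haps, chrom = layout$chrom, pos = layout$pos,
                            pop = rep(pops, each = nh), mapRate = cfg@mapRate)
    ancestry <- rep(c(cfg@admixtureFraction, 1, 0, 1, NA),
                    each = cfg@nSampled)
    names(ancestry) <- sprintf("%s_%02d", rep(pops, each = cfg@nSampled),
                               seq_len(cfg@nSampled))
    truth <- new("SimTruth", trueFreq = freq, founderFreq = pFounder,
                 classes = classes, ancestry = ancestry, config = cfg)
    list(panel = panel, truth = truth)
}

#' Simulate sequencing reads and genotype likelihoods from haplotypes
#'
#' Emulates whole-genome sequencing of the diploid individuals of a
#' haplotype panel: per-site read depth is Poisson(\code{meanDepth}), each
#' read reports the true allele with probability 1 - \code{errorRate}
#' (symmetric error), and the three genotype likelihoods follow the binomial
#' read model. Likelihoods are Phred-scaled, rounded to integer PL (capped at
#' 255) with the best genotype at PL 0, then stored back on the linear scale;
#' the hard call is the maximum-likelihood genotype. Zero-depth sites carry
#' three equal likelihoods and a missing call.
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param cfg a \linkS4class{SimConfig} supplying \code{meanDepth} and
#'   \code{errorRate}.
#' @param aa,class optional per-site ancestral allele and functional class to
#'   carry into the result (e.g. from \linkS4class{SimTruth}).
#' @return a \linkS4class{GenotypePanel} with an extra \code{dp} assay.
#' @export
emitSequencingData <- function(panel, cfg, aa = NULL, class = NULL) {
    stopifnot(cfg@meanDepth > 0)
    h <- haplotypes(panel)
    if (ncol(h) == 0) stop("empty haplotype panel")
    idx <- seq(1, ncol(h), by = 2)
    g <- h[, idx, drop = FALSE] + h[, idx + 1, drop = FALSE]
    n <- nrow(g); m <- ncol(g)
    dp <- matrix(stats::rpois(n * m, cfg@meanDepth), n, m)
    e <- cfg@errorRate
    pAlt <- c(e, 0.5, 1 - e)[g + 1L]
    altReads <- matrix(stats::rbinom(n * m, dp, pAlt), n, m)
    rl <- readLikelihoods(altReads, dp, e)
    pl <- rl$pl
    gl <- lapply(pl, function(x) 10^(-x / 10))
    call <- .mlCall(pl, dp)
    pop <- popLabels(panel)[idx]
    gp <- GenotypePanel(chrom = panel@chrom, pos = panel@pos, ref = "A",
                        alt = "C", dosage = call, gl = gl, pop = pop,
                        aa = aa, class = class)
    SummarizedExperiment::assay(gp, "dp", withDimnames = FALSE) <- dp
    gp
}

#' Binomial read-model genotype likelihoods
#'
#' Given alternate-allele read counts and depths, evaluates the symmetric-
#' error binomial likelihood of each genotype: with error rate e, a read
#' reports the alternate allele with probability e, 1/2, 1-e for genotypes
#' 0, 1, 2. Likelihoods are Phred-scaled as -10 log10(L/max L), rounded to
#' integers and capped at 255, so the best genotype has PL 0.
#'
#' @param altReads alternate-allele read counts (vector or matrix).
#' @param depth total read depths (same shape).
#' @param errorRate per-base error rate in [0, 0.5).
#' @return list with \code{gl} (linear likelihoods, three elements for
#'   dosage 0/1/2) and \code{pl} (integer Phred-scaled likelihoods).
#' @examples
#' readLikelihoods(5, 10, 0.01)$pl
#' @export
readLikelihoods <- function(altReads, depth, errorRate) {
    gl <- lapply(c(errorRate, 0.5, 1 - errorRate), function(pr) {
        g <- stats::dbinom(altReads, depth, pr)
        dim(g) <- dim(altReads)
        g
    })
    best <- pmax(gl[[1L]], gl[[2L]], gl[[3L]])
    pl <- lapply(gl, function(x) {
        v <- round(-10 * log10(x / best))
        v[!is.finite(v) | v > 255] <- 255
        v
    })
    list(gl = gl, pl = pl)
}

.mlCall <- function(pl, dp) {
    call <- matrix(NA_integer_, nrow(dp), ncol(dp))
    zero0 <- pl[[1L]] == 0; zero1 <- pl[[2L]] == 0; zero2 <- pl[[3L]] == 0
    call[zero0] <- 0L; call[zero1] <- 1L; call[zero2] <- 2L
    call[zero0 + zero1 + zero2 != 1L] <- NA_integer_  # ties are uninformative
    call[dp == 0L] <- NA_integer_
    call
}

#' Simulate linked phased haplotypes by forward Wright-Fisher with
#' recombination
#'
#' Individual-based forward simulator for a single chromosome: a diploid
#' population of constant size drifts for \code{generations} generations,
#' gametes recombining at a Poisson number of crossovers given the map
#' length. Optionally a focal site is placed under additive positive
#' selection to create a sweep (runs are restarted if the selected allele is
#' lost). Used for haplotype-based statistics (EHH, iHS, Rsb) where linkage
#' matters.
#'
#' @param nSnp number of SNPs.
#' @param ne diploid population size.
#' @param generations generations simulated.
#' @param lengthCm chromosome map length in cM.
#' @param sweepS selection coefficient of the focal allele (0 = neutral).
#' @param sweepPos SNP index of the selected site (default middle).
#' @param sweepCopies initial copies of the selected allele (default 2: a
#'   hard sweep from a nearly unique haplotype background).
#' @param initFreq function(n) drawing initial allele frequencies.
#' @param mutationRate per-site, per-gamete symmetric flip rate; keeps
#'   haplotype diversity from collapsing by drift alone.
#' @param pop population label.
#' @param chrom chromosome name.
#' @param maxTries restart budget for sweep runs.
#' @return a \linkS4class{HaplotypePanel} (2 * \code{ne} haplotypes).
#' @export
simulateLinkedHaplotypes <- function(nSnp = 300, ne = 50, generations = 40,
                                     lengthCm = 100, sweepS = 0,
                                     sweepPos = ceiling(nSnp / 2),
                                     sweepCopies = 2,
                                     initFreq = function(n)
                                         stats::runif(n, 0.1, 0.9),
                                     mutationRate = 1e-3,
                                     pop = "POP", chrom = "1",
                                     maxTries = 25) {
    pos <- sort(sample.int(round(lengthCm * 1e6), nSnp))
    cm <- pos / 1e6
    for (try in seq_len(maxTries)) {
        p0 <- initFreq(nSnp)
        H <- matrix(stats::rbinom(nSnp * 2L * ne, 1L, p0), nSnp)
        if (sweepS > 0) {
            H[sweepPos, ] <- 0L
            H[sweepPos, sample.int(2L * ne, sweepCopies)] <- 1L
        }
        ok <- TRUE
        for (g in seq_len(generations)) {
            if (sweepS > 0) {
                dos <- H[sweepPos, seq(1, 2 * ne, 2)] +
                    H[sweepPos, seq(2, 2 * ne, 2)]
                w <- 1 + sweepS * dos / 2
            } else w <- rep(1, ne)
            Hn <- matrix(0L, nSnp, 2L * ne)
            par1 <- sample.int(ne, ne, replace = TRUE, prob = w)
            par2 <- sample.int(ne, ne, replace = TRUE, prob = w)
            for (i in seq_len(ne)) {
                Hn[, 2L * i - 1L] <- .gamete(H, par1[i], cm)
                Hn[, 2L * i] <- .gamete(H, par2[i], cm)
            }
            if (mutationRate > 0) {
                nMut <- stats::rpois(1L, mutationRate * nSnp * 2 * ne)
                if (nMut > 0) {
                    at <- cbind(sample.int(nSnp, nMut, replace = TRUE),
                                sample.int(2L * ne, nMut, replace = TRUE))
                    at <- at[at[, 1L] != sweepPos | sweepS == 0, ,
                             drop = FALSE]
                    Hn[at] <- 1L - Hn[at]
                }
            }
            H <- Hn
            if (sweepS > 0 && sum(H[sweepPos, ]) == 0L) { ok <- FALSE; break }
        }
        if (ok) break
    }
    if (!ok) stop("selected allele lost in every attempted run")
    HaplotypePanel(H, chrom = chrom, pos = pos, cm = cm,
                   pop = rep(pop, 2L * ne))
}

.gamete <- function(H, parent, cm) {
    a <- H[, 2L * parent - 1L]; b <- H[, 2L * parent]
    nx <- stats::rpois(1L, (cm[length(cm)] - cm[1L]) / 100)
    phase <- stats::rbinom(1L, 1L, 0.5)
    if (nx == 0L) return(if (phase == 0L) a else b)
    xo <- sort(stats::runif(nx, cm[1L], cm[length(cm)]))
    phase <- (phase + findInterval(cm, xo)) %% 2L
    out <- a
    out[phase == 1L] <- b[phase == 1L]
    out
}

#' Generate a gene-environment association design with known truth
#'
#' Builds an environmental design of \code{nPops} populations described by
#' \code{nCov} bioclimatic-like covariables of latent rank \code{nPcs}, a
#' sparse true coefficient matrix B linking retained environmental PCs to
#' population allele-frequency deviations, and the resulting allele
#' frequencies. The generating truth (true B, affected SNPs, baseline
#' frequencies) is retained for recovery tests.
#'
#' @param nPops number of populations.
#' @param nPcs number of latent (and retained) environmental PCs.
#' @param effectScale standard deviation of non-zero B entries, on the
#'   allele-frequency scale per unit PC score (must be >= 0).
#' @param seed integer seed.
#' @param nSnps number of SNPs.
#' @param nCov number of environmental covariables.
#' @param affectedFraction fraction of SNPs carrying environmental effects.
#' @param noiseSd residual frequency noise.
#' @return an \linkS4class{EnvDesign} with \code{freq} and \code{truth} set.
#' @export
generateEnvironment <- function(nPops = 32, nPcs = 7, effectScale = 0.05,
                                seed = 1L, nSnps = 40426, nCov = 19,
                                affectedFraction = 0.2, noiseSd = 0.02) {
    if (nPcs < 1) stop("nPcs must be >= 1")
    if (effectScale < 0) stop("effectScale must be >= 0")
    set.seed(seed)
    Z <- matrix(stats::rnorm(nPops * nPcs), nPops, nPcs)
    Z <- Z %*% diag(sqrt(seq(nPcs, 1)), nPcs)  # ordered latent variances
    L <- qr.Q(qr(matrix(stats::rnorm(nCov * nPcs), nCov, nPcs)))
    sds <- stats::runif(nCov, 0.5, 3)
    centers <- stats::rnorm(nCov, 0, 5)
    cov <- Z %*% t(L)
    cov <- sweep(cov, 2, sds, "*")
    cov <- sweep(cov + matrix(stats::rnorm(nPops * nCov, 0, 0.05),
                              nPops, nCov), 2, centers, "+")
    colnames(cov) <- sprintf("bio%02d", seq_len(nCov))
    rownames(cov) <- sprintf("pop%02d", seq_len(nPops))
    design <- envPCA(cov, nKeep = nPcs)
    S <- envScores(design)

    nAffected <- round(affectedFraction * nSnps)
    affected <- sort(sample.int(nSnps, nAffected))
    B <- matrix(0, nSnps, nPcs)
    B[affected, ] <- stats::rnorm(nAffected * nPcs, 0, effectScale)
    p0 <- stats::runif(nSnps, 0.2, 0.8)
    freq <- outer(p0, rep(1, nPops)) + B %*% t(S) +
        matrix(stats::rnorm(nSnps * nPops, 0, noiseSd), nSnps, nPops)
    freq <- pmin(pmax(freq, 1e-4), 1 - 1e-4)
    colnames(freq) <- rownames(cov)
    design@freq <- freq
    design@truth <- list(B = B, affected = affected, baseline = p0,
                         scores = S, effectScale = effectScale)
    design
}
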