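#' EM estimate of the allele frequency at one site from genotype likelihoods
#'
#' Maximizes the marginal likelihood
#' \eqn{\sum_i \log \sum_g GL_i(g) P(g \mid q)} over the alternate-allele
#' frequency q, with Hardy-Weinberg genotype priors, by
#' expectation-maximization. Individuals whose three likelihoods are equal
#' (uninformative/missing) are dropped. The EM is initialized at the
#' GL-weighted naive estimate.
#'
#' @param l0,l1,l2 per-individual linear-scale genotype likelihoods for
#'   dosage 0, 1, 2 (any common scaling).
#' @param tol convergence tolerance on the frequency change.
#' @param maxIter maximum EM iterations.
#' @return list with \code{af}, \code{iterations}, \code{converged},
#'   \code{logLik}; \code{af} is NA when no individual is informative.
#' @examples
#' emAlleleFrequency(c(1, 1, 0), c(0, 0, 1), c(0, 0, 0))$af  # 2 hom-ref + 1 het
#' @export
emAlleleFrequency <- function(l0, l1, l2, tol = 1e-6, maxIter = 100) {
    tot <- l0 + l1 + l2
    inf <- is.finite(tot) & tot > 0 & !(l0 == l1 & l1 == l2)
    if (!any(inf))
        return(list(af = NA_real_, iterations = 0L, converged = FALSE,
                    logLik = NA_real_))
    l0 <- l0[inf] / tot[inf]; l1 <- l1[inf] / tot[inf]; l2 <- l2[inf] / tot[inf]
    n <- length(l0)
    naive <- sum(0.5 * l1 / (l0 + l1 + l2) + l2 / (l0 + l1 + l2)) / n
    # the marginal likelihood can be multimodal for very small n; a few
    # extra starts make the EM return the global maximizer
    starts <- unique(pmin(pmax(c(naive, 0.05, 0.5, 0.95), 1e-9), 1 - 1e-9))
    best <- NULL
    for (q0 in starts) {
        fit <- .emOne(l0, l1, l2, q0, tol, maxIter)
        if (is.null(best) || fit$logLik > best$logLik) best <- fit
    }
    best
}

.emOne <- function(l0, l1, l2, q, tol, maxIter) {
    n <- length(l0)
    converged <- FALSE; it <- 0L
    while (it < maxIter) {
        it <- it + 1L
        u0 <- l0 * (1 - q)^2; u1 <- l1 * 2 * q * (1 - q); u2 <- l2 * q^2
        norm <- u0 + u1 + u2
        qNew <- sum((u1 + 2 * u2) / norm) / (2 * n)
        if (abs(qNew - q) < tol) { q <- qNew; converged <- TRUE; break }
        q <- qNew
    }
    list(af = q, iterations = it, converged = converged,
         logLik = emLogLik(l0, l1, l2, q))
}

#' Marginal log-likelihood of an allele frequency under HW priors
#'
#' @param l0,l1,l2 genotype likelihoods of informative individuals.
#' @param q allele frequency.
#' @return scalar log-likelihood.
#' @export
emLogLik <- function(l0, l1, l2, q) {
    sum(log(l0 * (1 - q)^2 + l1 * 2 * q * (1 - q) + l2 * q^2))
}

#' Per-population allele and derived-allele frequencies from a panel
#'
#' Runs the genotype-likelihood EM site by site within each population
#' (vectorized across sites) and, where the ancestral allele is assigned,
#' orients frequencies to the derived allele.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param method \code{"em"} (genotype-likelihood EM, default) or
#'   \code{"counts"} (hard-call allele counts).
#' @param tol,maxIter EM controls.
#' @return list with matrices \code{af} (alternate-allele frequency,
#'   sites x populations), \code{derived} (derived-allele frequency, NA at
#'   unpolarized sites), logical \code{converged}, and per-population diploid
#'   counts \code{n}.
#' @export
populationFrequencies <- function(panel, method = c("em", "counts"),
                                  tol = 1e-6, maxIter = 100) {
    method <- match.arg(method)
    pops <- unique(popLabels(panel))
    nSites <- nrow(panel)
    af <- matrix(NA_real_, nSites, length(pops),
                 dimnames = list(rownames(panel), pops))
    conv <- matrix(TRUE, nSites, length(pops), dimnames = dimnames(af))
    nInd <- integer(length(pops)); names(nInd) <- pops
    gl <- genoLikelihoods(panel)
    d <- dosages(panel)
    for (j in seq_along(pops)) {
        cols <- popLabels(panel) == pops[j]
        nInd[j] <- sum(cols)
        if (method == "counts") {
            dj <- d[, cols, drop = FALSE]
            af[, j] <- rowMeans(dj, na.rm = TRUE) / 2
            af[, j][rowSums(!is.na(dj)) == 0] <- NA
        } else {
            fit <- .emMatrix(gl[[1L]][, cols, drop = FALSE],
                             gl[[2L]][, cols, drop = FALSE],
                             gl[[3L]][, cols, drop = FALSE], tol, maxIter)
            af[, j] <- fit$af
            conv[, j] <- fit$converged
        }
    }
    aa <- ancestralAllele(panel)
    alt <- mcols(rowRanges(panel))$alt
    derived <- af
    derived[is.na(aa), ] <- NA
    flip <- !is.na(aa) & aa == alt
    derived[flip, ] <- 1 - derived[flip, , drop = FALSE]
    list(af = af, derived = derived, converged = conv, n = nInd)
}

# Vectorized-over-sites EM with per-entry informativeness mask.
.emMatrix <- function(l0, l1, l2, tol = 1e-6, maxIter = 100) {
    tot <- l0 + l1 + l2
    M <- is.finite(tot) & tot > 0 & !(l0 == l1 & l1 == l2)
    l0 <- ifelse(M, l0 / tot, 0); l1 <- ifelse(M, l1 / tot, 0)
    l2 <- ifelse(M, l2 / tot, 0)
    nInf <- rowSums(M)
    q <- rowSums(0.5 * l1 + l2) / pmax(nInf, 1)
    q <- pmin(pmax(q, 1e-9), 1 - 1e-9)
    active <- nInf > 0
    converged <- rep(FALSE, nrow(l0))
    for (it in seq_len(maxIter)) {
        u0 <- l0 * (1 - q)^2; u1 <- l1 * 2 * q * (1 - q); u2 <- l2 * q^2
        norm <- u0 + u1 + u2
        norm[norm == 0] <- 1
        qNew <- rowSums(ifelse(M, (u1 + 2 * u2) / norm, 0)) / (2 * pmax(nInf, 1))
        done <- abs(qNew - q) < tol
        converged <- converged | (done & active)
        q <- qNew
        if (all(done[active])) break
    }
    q[!active] <- NA_real_
    list(af = q, converged = converged)
}

#' Polarize sites from outgroup genotypes
#'
#' Calls the ancestral allele of each site as the allele all non-missing
#' outgroup individuals are homozygous for, provided at most one outgroup is
#' missing; any heterozygous outgroup, disagreement among outgroups, more
#' than one missing outgroup, or no called outgroup leaves the site
#' unassigned.
#'
#' @param outDosage sites x outgroups matrix of alternate-allele dosages
#'   (0/1/2, NA = missing).
#' @param ref,alt per-site alleles.
#' @return character vector of ancestral alleles (NA = unassigned).
#' @export
polarizeSites <- function(outDosage, ref, alt) {
    outDosage <- as.matrix(outDosage)
    nMiss <- rowSums(is.na(outDosage))
    nRef <- rowSums(outDosage == 0L, na.rm = TRUE)
    nAlt <- rowSums(outDosage == 2L, na.rm = TRUE)
    nHet <- rowSums(outDosage == 1L, na.rm = TRUE)
    nCalled <- ncol(outDosage) - nMiss
    aa <- rep(NA_character_, nrow(outDosage))
    okRef <- nMiss <= 1 & nHet == 0 & nCalled > 0 & nRef == nCalled
    okAlt <- nMiss <= 1 & nHet == 0 & nCalled > 0 & nAlt == nCalled
    aa[okRef] <- rep_len(as.character(ref), nrow(outDosage))[okRef]
    aa[okAlt] <- rep_len(as.character(alt), nrow(outDosage))[okAlt]
    aa
}

#' Count segregating and fixed-derived sites per population
#'
#' Segregating sites are those with 0.001 < AF < 0.999 (strict inequalities).
#' The number of fixed-derived sites is extrapolated as the proportion of
#' polarized sites whose derived-allele frequency exceeds 0.999, multiplied
#' by the total site count.
#'
#' @param freqs result of \code{\link{populationFrequencies}}.
#' @param lower,upper segregation thresholds.
#' @param denominator \code{"polarized"} (default): the fixed-derived
#'   proportion is computed among polarized sites; \code{"all"}: among all
#'   sites (unpolarized counted as not fixed-derived).
#' @return data.frame with per-population \code{segregating},
#'   \code{fixedDerived} and the underlying proportion.
#' @export
countSegregatingFixed <- function(freqs, lower = 0.001, upper = 0.999,
                                  denominator = c("polarized", "all")) {
    denominator <- match.arg(denominator)
    nTotal <- nrow(freqs$af)
    seg <- colSums(freqs$af > lower & freqs$af < upper, na.rm = TRUE)
    polarized <- !is.na(freqs$derived)
    fixedHits <- colSums(freqs$derived > upper, na.rm = TRUE)
    denom <- if (denominator == "polarized") colSums(polarized) else
        rep(nTotal, ncol(freqs$af))
    prop <- ifelse(denom > 0, fixedHits / denom, NA_real_)
    data.frame(pop = colnames(freqs$af), segregating = as.integer(seg),
               fixedDerivedProportion = prop,
               fixedDerived = prop * nTotal, row.names = NULL)
}

#' Probabilistic site-frequency spectrum from genotype probabilities
#'
#' For one population of n diploids, computes at each usable site the
#' probability that exactly k derived-allele copies are present
#' (k = 0, ..., 2n) by combining per-individual genotype probabilities, then
#' averages over sites. Usable sites have an assigned ancestral allele and no
#' missing genotype in the population. The default path multiplies the
#' per-individual probability generating functions (a convolution); the
#' enumeration path sums over all 3^n genotype configurations and is
#' retained as an exact cross-check for small n.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param pop population label.
#' @param method \code{"convolution"} (default) or \code{"enumeration"}.
#' @param maxEnum refuse enumeration beyond this many individuals.
#' @return list with \code{sfs} (mean probability of 1..2n-1 derived copies),
#'   \code{mass} (mean probability of 0..2n copies), \code{nSites},
#'   \code{nConfigurations} (enumeration only), \code{n} diploids.
#' @export
probabilisticSFS <- function(panel, pop, method = c("convolution",
                                                    "enumeration"),
                             maxEnum = 10) {
    method <- match.arg(method)
    cols <- popLabels(panel) == pop
    n <- sum(cols)
    if (n == 0) stop("no individuals in population ", pop)
    d <- derivedDosages(panel)[, cols, drop = FALSE]
    keep <- !is.na(ancestralAllele(panel)) &
        rowSums(is.na(dosages(panel)[, cols, drop = FALSE])) == 0
    gp <- genoProbabilities(panel)
    aa <- ancestralAllele(panel)
    alt <- mcols(rowRanges(panel))$alt
    flip <- !is.na(aa) & aa == alt
    g0 <- gp[[1L]][, cols, drop = FALSE]; g1 <- gp[[2L]][, cols, drop = FALSE]
    g2 <- gp[[3L]][, cols, drop = FALSE]
    tmp <- g0[flip, , drop = FALSE]
    g0[flip, ] <- g2[flip, , drop = FALSE]; g2[flip, ] <- tmp
    g0 <- g0[keep, , drop = FALSE]; g1 <- g1[keep, , drop = FALSE]
    g2 <- g2[keep, , drop = FALSE]
    nSites <- nrow(g0)
    mass <- numeric(2L * n + 1L)
    nConf <- NULL
    if (method == "convolution") {
        for (i in seq_len(nSites)) {
            poly <- 1
            for (j in seq_len(n))
                poly <- .polyMul3(poly, g0[i, j], g1[i, j], g2[i, j])
            mass <- mass + poly
        }
    } else {
        if (n > maxEnum)
            stop("enumeration over 3^", n, " configurations refused; ",
                 "use the convolution method")
        conf <- as.matrix(expand.grid(rep(list(0:2), n)))
        nConf <- nrow(conf)
        kPerConf <- factor(rowSums(conf), levels = 0:(2L * n))
        for (i in seq_len(nSites)) {
            gpSite <- rbind(g0[i, ], g1[i, ], g2[i, ])
            pConf <- apply(conf, 1L, function(g)
                prod(gpSite[cbind(g + 1L, seq_len(n))]))
            mass <- mass + as.vector(tapply(pConf, kPerConf, sum))
        }
    }
    mass <- if (nSites > 0) mass / nSites else mass
    names(mass) <- 0:(2L * n)
    list(sfs = mass[2:(2L * n)], mass = mass, nSites = nSites,
         nConfigurations = nConf, n = n)
}

# multiply polynomial coefficients by (a + b x + c x^2)
.polyMul3 <- function(poly, a, b, c) {
    k <- length(poly)
    out <- numeric(k + 2L)
    out[seq_len(k)] <- poly * a
    out[1L + seq_len(k)] <- out[1L + seq_len(k)] + poly * b
    out[2L + seq_len(k)] <- out[2L + seq_len(k)] + poly * c
    out
}

#' Unbiased expected heterozygosity
#'
#' Mean over sites of \eqn{2\hat p(1-\hat p) \cdot 2n/(2n-1)} for a sample of
#' n diploids.
#'
#' @param freq vector of allele frequencies (NA dropped).
#' @param nDiploid diploid sample size.
#' @return scalar expected heterozygosity.
#' @export
expectedHeterozygosity <- function(freq, nDiploid) {
    freq <- freq[!is.na(freq)]
    if (!length(freq)) return(0)
    mean(2 * freq * (1 - freq)) * 2 * nDiploid / (2 * nDiploid - 1)
}
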