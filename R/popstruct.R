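#' Block scheme of contiguous fixed-size SNP chunks
#'
#' Assigns genome-ordered SNPs to contiguous blocks of \code{blockSize} SNPs
#' (default 250, the block size used for all f-/F-statistic jackknives); the
#' final short block is kept.
#'
#' @param n number of SNPs in genome order.
#' @param blockSize SNPs per block.
#' @return integer block id per SNP.
#' @export
blockScheme <- function(n, blockSize = 250) {
    ceiling(seq_len(n) / blockSize)
}

# Weir-Cockerham per-SNP variance components for r populations.
# counts: list with per-pop n (diploids called), p (alt freq), h (obs het
# rate); each a vector over SNPs.
.wcComponents <- function(nMat, pMat, hMat) {
    r <- ncol(nMat)
    nbar <- rowMeans(nMat)
    sumN <- rowSums(nMat)
    nc <- (sumN - rowSums(nMat^2) / sumN) / (r - 1)
    pbar <- rowSums(nMat * pMat) / sumN
    s2 <- rowSums(nMat * (pMat - pbar)^2) / ((r - 1) * nbar)
    hbar <- rowSums(nMat * hMat) / sumN
    a <- nbar / nc *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    c <- hbar / 2
    list(a = a, b = b, c = c)
}

.popSummaries <- function(panel, pops) {
    d <- dosages(panel)
    lab <- popLabels(panel)
    nMat <- pMat <- hMat <- matrix(NA_real_, nrow(d), length(pops),
                                   dimnames = list(NULL, pops))
    for (j in seq_along(pops)) {
        dj <- d[, lab == pops[j], drop = FALSE]
        nMat[, j] <- rowSums(!is.na(dj))
        pMat[, j] <- rowMeans(dj, na.rm = TRUE) / 2
        hMat[, j] <- rowMeans(dj == 1L, na.rm = TRUE)
    }
    list(n = nMat, p = pMat, h = hMat)
}

.ratioJackknife <- function(num, den, blocks) {
    est <- sum(num) / sum(den)
    ids <- sort(unique(blocks))
    pseudo <- vapply(ids, function(b) {
        keep <- blocks != b
        sum(num[keep]) / sum(den[keep])
    }, numeric(1))
    se <- .jackknifeSE(pseudo)
    c(estimate = est, se = se, ci_lower = est - 1.96 * se,
      ci_upper = est + 1.96 * se)
}

#' Weir-Cockerham F-statistics with block-jackknife standard errors
#'
#' Estimates global FST, FIT and FIS over all populations, pairwise FST, and
#' per-population FIS under the analysis-of-variance framework, combining
#' SNPs as ratios of summed variance components. Standard errors come from a
#' leave-one-block-out jackknife over contiguous blocks of
#' \code{blockSize} SNPs, and 95% CIs are estimate +/- 1.96 SE.
#'
#' SNPs monomorphic across all populations are excluded; every population
#' must have at least two genotyped diploids.
#'
#' @param panel a \linkS4class{GenotypePanel} with hard calls.
#' @param blockSize SNPs per jackknife block.
#' @return list with data.frames \code{global} (FST, FIT, FIS),
#'   \code{pairwise} (FST per population pair) and \code{perPop} (FIS per
#'   population), plus \code{nSnpsUsed}.
#' @export
wcFStatistics <- function(panel, blockSize = 250) {
    pops <- unique(popLabels(panel))
    if (length(pops) < 2) stop("need at least two populations")
    small <- table(popLabels(panel))[pops] < 2
    if (any(small))
        stop("populations with fewer than 2 individuals: ",
             paste(pops[small], collapse = ", "))
    sm <- .popSummaries(panel, pops)
    poly <- rowSums(sm$n * sm$p) > 0 & rowSums(sm$n * sm$p) < rowSums(sm$n) &
        rowSums(sm$n >= 1) == length(pops) & rowSums(sm$n) > length(pops)
    nMat <- sm$n[poly, , drop = FALSE]
    pMat <- sm$p[poly, , drop = FALSE]
    hMat <- sm$h[poly, , drop = FALSE]
    blocks <- blockScheme(nrow(nMat), blockSize)
    comp <- .wcComponents(nMat, pMat, hMat)
    tot <- comp$a + comp$b + comp$c
    oneMinus <- function(jk)
        c(estimate = 1 - jk[["estimate"]], se = jk[["se"]],
          ci_lower = 1 - jk[["ci_upper"]], ci_upper = 1 - jk[["ci_lower"]])
    global <- rbind(
        FST = .ratioJackknife(comp$a, tot, blocks),
        FIT = oneMinus(.ratioJackknife(comp$c, tot, blocks)),
        FIS = oneMinus(.ratioJackknife(comp$c, comp$b + comp$c, blocks)))
    global <- data.frame(stat = rownames(global), global, row.names = NULL)
    pairs <- utils::combn(pops, 2)
    pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
        j <- match(pairs[, k], pops)
        use <- rowSums(nMat[, j] * pMat[, j]) > 0 &
            rowSums(nMat[, j] * pMat[, j]) < rowSums(nMat[, j])
        cp <- .wcComponents(nMat[use, j, drop = FALSE],
                            pMat[use, j, drop = FALSE],
                            hMat[use, j, drop = FALSE])
        jk <- .ratioJackknife(cp$a, cp$a + cp$b + cp$c,
                              blockScheme(sum(use), blockSize))
        data.frame(popA = pairs[1, k], popB = pairs[2, k], t(jk))
    }))
    perPop <- do.call(rbind, lapply(seq_along(pops), function(j) {
        use <- nMat[, j] > 1 & pMat[, j] > 0 & pMat[, j] < 1
        n <- nMat[use, j]; p <- pMat[use, j]; h <- hMat[use, j]
        b <- n / (n - 1) * (p * (1 - p) - (2 * n - 1) / (4 * n) * h)
        cc <- h / 2
        jk <- .ratioJackknife(cc, b + cc, blockScheme(sum(use), blockSize))
        data.frame(pop = pops[j], FIS = 1 - jk[["estimate"]],
                   se = jk[["se"]],
                   ci_lower = 1 - jk[["ci_upper"]],
                   ci_upper = 1 - jk[["ci_lower"]])
    }))
    list(global = global, pairwise = pairwise, perPop = perPop,
         nSnpsUsed = nrow(nMat))
}

.alleleStats <- function(panel, pops) {
    d <- dosages(panel)
    lab <- popLabels(panel)
    out <- lapply(pops, function(pp) {
        dj <- d[, lab == pp, drop = FALSE]
        nAll <- 2 * rowSums(!is.na(dj))
        p <- rowSums(dj, na.rm = TRUE) / nAll
        list(p = p, n = nAll)
    })
    names(out) <- pops
    out
}

.hCorrection <- function(p, n) {
    # unbiased estimate of p(1-p)/n from n sampled alleles
    p * (1 - p) / (n - 1)
}

#' Patterson f-statistics with block-jackknife Z-scores
#'
#' Computes the sample-size-corrected f2, f3 and f4 statistics from
#' hard-call allele counts, averaged over SNPs, with a leave-one-block-out
#' jackknife SE over contiguous \code{blockSize}-SNP blocks. A population
#' triplet is called admixed when the f3 Z-score is below -1.65 (95%
#' significance threshold).
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param type "f2", "f3" or "f4".
#' @param pops population labels: (A, B) for f2; (A; B, C) for f3;
#'   (A, B; C, D) for f4. Labels must be distinct.
#' @param blockSize SNPs per jackknife block.
#' @return one-row data.frame with \code{estimate}, \code{se}, \code{z},
#'   \code{ci_lower}, \code{ci_upper} (and \code{admixed} for f3).
#' @export
fStat <- function(panel, type = c("f2", "f3", "f4"), pops,
                  blockSize = 250) {
    type <- match.arg(type)
    need <- c(f2 = 2L, f3 = 3L, f4 = 4L)[[type]]
    if (length(pops) != need || anyDuplicated(pops))
        stop(type, " requires ", need, " distinct population labels")
    st <- .alleleStats(panel, pops)
    ok <- Reduce(`&`, lapply(st, function(x) x$n >= 2))
    st <- lapply(st, function(x) list(p = x$p[ok], n = x$n[ok]))
    num <- switch(type,
        f2 = (st[[1]]$p - st[[2]]$p)^2 -
            .hCorrection(st[[1]]$p, st[[1]]$n) -
            .hCorrection(st[[2]]$p, st[[2]]$n),
        f3 = (st[[1]]$p - st[[2]]$p) * (st[[1]]$p - st[[3]]$p) -
            .hCorrection(st[[1]]$p, st[[1]]$n),
        f4 = (st[[1]]$p - st[[2]]$p) * (st[[3]]$p - st[[4]]$p))
    blocks <- blockScheme(length(num), blockSize)
    est <- mean(num)
    ids <- sort(unique(blocks))
    pseudo <- vapply(ids, function(b) mean(num[blocks != b]), numeric(1))
    se <- .jackknifeSE(pseudo)
    out <- data.frame(type = type,
                      config = paste(pops, collapse = ","),
                      estimate = est, se = se, z = est / se,
                      ci_lower = est - 1.96 * se,
                      ci_upper = est + 1.96 * se)
    if (type == "f3") out$admixed <- out$z < -1.65
    out
}

#' F4-ratio estimate of an admixture proportion
#'
#' Estimates the mixing proportion alpha as
#' f4(numerator quadruplet) / f4(denominator quadruplet), with a
#' leave-one-block-out jackknife 95% CI on the ratio. For a target X admixed
#' between sources related to B and C, with A a sister of B and O an
#' outgroup, the standard design is numerator (A, O; X, C) and denominator
#' (A, O; B, C).
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param numerator,denominator character(4) of population labels.
#' @param blockSize SNPs per jackknife block.
#' @return one-row data.frame with \code{alpha}, \code{se}, \code{ci_lower},
#'   \code{ci_upper}; NA with a warning when the denominator f4 is ~0.
#' @export
f4Ratio <- function(panel, numerator, denominator, blockSize = 250) {
    stopifnot(length(numerator) == 4, length(denominator) == 4)
    pops <- unique(c(numerator, denominator))
    st <- .alleleStats(panel, pops)
    ok <- Reduce(`&`, lapply(st, function(x) x$n >= 2))
    p <- vapply(st, function(x) x$p, numeric(length(ok)))[ok, , drop = FALSE]
    f4terms <- function(q) (p[, q[1]] - p[, q[2]]) * (p[, q[3]] - p[, q[4]])
    num <- f4terms(numerator)
    den <- f4terms(denominator)
    if (abs(sum(den)) < 1e-12) {
        warning("denominator f4 is approximately zero")
        return(data.frame(alpha = NA_real_, se = NA_real_,
                          ci_lower = NA_real_, ci_upper = NA_real_))
    }
    jk <- .ratioJackknife(num, den, blockScheme(length(num), blockSize))
    data.frame(alpha = jk[["estimate"]], se = jk[["se"]],
               ci_lower = jk[["ci_lower"]], ci_upper = jk[["ci_upper"]])
}

#' Allele-sharing distance matrix between individuals
#'
#' Per-site distance between two diploid genotypes: 0 for identical
#' homozygotes, 0.5 when exactly one allele is shared (including the
#' heterozygote/heterozygote pair), 1 for opposite homozygotes; ASD is the
#' mean over pairwise-complete sites.
#'
#' @param panel a \linkS4class{GenotypePanel} with hard calls.
#' @return symmetric matrix with zero diagonal; NA for pairs with no
#'   co-called site.
#' @export
asdMatrix <- function(panel) {
    d <- dosages(panel)
    m <- ncol(d)
    out <- matrix(0, m, m, dimnames = list(colnames(d), colnames(d)))
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
        gi <- d[, i]; gj <- d[, j]
        ok <- !is.na(gi) & !is.na(gj)
        if (!any(ok)) { out[i, j] <- out[j, i] <- NA; next }
        dist <- abs(gi[ok] - gj[ok]) / 2
        dist[gi[ok] == 1L & gj[ok] == 1L] <- 0.5
        out[i, j] <- out[j, i] <- mean(dist)
    }
    out
}

#' KING-robust kinship coefficient
#'
#' Estimates the kinship coefficient phi between two diploid individuals
#' from heterozygote and opposite-homozygote counts over co-called SNPs,
#' using the within-pair robust estimator
#' \deqn{\hat\phi = \frac{N_{Aa,Aa} - 2N_{AA,aa}}{2\,\min(N^i_{Aa}, N^j_{Aa})}
#'   + \frac12 - \frac{N^i_{Aa} + N^j_{Aa}}{4\,\min(N^i_{Aa}, N^j_{Aa})}}
#' which is robust to population structure and symmetric in the pair.
#'
#' @param panel a \linkS4class{GenotypePanel} with hard calls.
#' @param i,j individual indices or names.
#' @param minSnps warn below this number of co-called SNPs.
#' @return scalar phi estimate.
#' @export
kinship <- function(panel, i, j, minSnps = 1000) {
    d <- dosages(panel)
    gi <- d[, i]; gj <- d[, j]
    ok <- !is.na(gi) & !is.na(gj)
    if (sum(ok) < minSnps)
        warning("only ", sum(ok), " co-called SNPs; kinship may be unstable")
    gi <- gi[ok]; gj <- gj[ok]
    nHetI <- sum(gi == 1L); nHetJ <- sum(gj == 1L)
    nHH <- sum(gi == 1L & gj == 1L)
    nOpp <- sum(abs(gi - gj) == 2L)
    minHet <- min(nHetI, nHetJ)
    if (minHet == 0) return(NA_real_)
    (nHH - 2 * nOpp) / (2 * minHet) + 0.5 - (nHetI + nHetJ) / (4 * minHet)
}

#' Kinship matrix over all individual pairs
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param minSnps passed to \code{\link{kinship}}.
#' @return symmetric matrix of phi estimates (diagonal 0.5).
#' @export
kinshipMatrix <- function(panel, minSnps = 1000) {
    m <- ncol(panel)
    out <- matrix(0.5, m, m, dimnames = list(colnames(panel), colnames(panel)))
    for (i in seq_len(m - 1)) for (j in (i + 1):m)
        out[i, j] <- out[j, i] <- suppressWarnings(kinship(panel, i, j,
                                                           minSnps))
    out
}

#' Classify a relationship degree from a kinship coefficient
#'
#' Powers-of-two kinship bounds, closed on the lower end:
#' duplicate/self >= 2^(-3/2) (0.354); first degree [2^(-5/2), 2^(-3/2)) =
#' [0.177, 0.354); second degree [2^(-7/2), 2^(-5/2)) = [0.0884, 0.177);
#' third degree [2^(-9/2), 2^(-7/2)); below 2^(-9/2), more distant than
#' third degree. Every finite phi maps to exactly one class.
#'
#' @param phi kinship coefficient(s).
#' @return character vector in {"duplicate", "first", "second", "third",
#'   "unrelated"}.
#' @examples
#' classifyDegree(c(0.5, 0.25, 0.144, 0.01))
#' @export
classifyDegree <- function(phi) {
    stopifnot(all(is.finite(phi)))
    cut(phi, breaks = c(-Inf, 2^(-9/2), 2^(-7/2), 2^(-5/2), 2^(-3/2), Inf),
        labels = c("unrelated", "third", "second", "first", "duplicate"),
        right = FALSE) |> as.character()
}

#' Kinship degree bounds
#'
#' The closed lower bounds of the duplicate, first-, second- and
#' third-degree kinship intervals (2^(-3/2), 2^(-5/2), 2^(-7/2), 2^(-9/2)).
#'
#' @return named numeric vector.
#' @export
kinshipDegreeBounds <- function() {
    c(duplicate = 2^(-3/2), first = 2^(-5/2), second = 2^(-7/2),
      third = 2^(-9/2))
}
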