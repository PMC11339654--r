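#' Contiguous equal-size jackknife blocks
#'
#' Splits n genome-ordered SNPs into \code{nBlocks} contiguous blocks with
#' the same number of SNPs; remainder SNPs are assigned to the last block.
#'
#' @param n number of SNPs.
#' @param nBlocks number of blocks.
#' @return integer block id per SNP.
#' @export
equalBlocks <- function(n, nBlocks) {
    size <- n %/% nBlocks
    if (size < 1) stop("fewer SNPs than blocks")
    id <- rep(seq_len(nBlocks), each = size)
    c(id, rep(nBlocks, n - length(id)))
}

.jackknifeSE <- function(pseudo) {
    B <- length(pseudo)
    sqrt((B - 1) / B * sum((pseudo - mean(pseudo))^2))
}

#' Per-individual nonsynonymous/synonymous heterozygosity ratio
#'
#' Ratio of the (expected) number of heterozygous genotypes at
#' nonsynonymous sites to that at synonymous sites, per individual.
#' Heterozygote counts are taken as expectations over genotype probabilities
#' (the default) or as hard-call counts.
#'
#' @param panel a \linkS4class{GenotypePanel} with \code{class} filled.
#' @param nsClasses,sClass class labels counted as NS and S.
#' @param useGP expectation over genotype probabilities (TRUE) or hard calls.
#' @return named numeric vector (NA where an individual has no expected S
#'   heterozygote, with a warning).
#' @export
nsSHetRatio <- function(panel, nsClasses = c("ns_tolerated", "ns_deleterious"),
                        sClass = "synonymous", useGP = TRUE) {
    cls <- variantClass(panel)
    ns <- cls %in% nsClasses
    s <- cls %in% sClass
    if (!any(ns) || !any(s))
        stop("both NS and S classes must be present in the panel")
    hetExp <- .hetMatrix(panel, useGP)
    nsHet <- colSums(hetExp[ns, , drop = FALSE], na.rm = TRUE)
    sHet <- colSums(hetExp[s, , drop = FALSE], na.rm = TRUE)
    out <- ifelse(sHet > 0, nsHet / sHet, NA_real_)
    if (anyNA(out))
        warning("individuals with zero synonymous heterozygotes: ",
                paste(names(out)[is.na(out)], collapse = ", "))
    names(out) <- colnames(panel)
    out
}

.hetMatrix <- function(panel, useGP) {
    if (useGP) {
        gp <- genoProbabilities(panel)
        h <- gp[[2L]]
        h[is.na(dosages(panel))] <- NA  # only called genotypes contribute
        h
    } else {
        (dosages(panel) == 1L) * 1
    }
}

#' Masked and realized genetic load per individual
#'
#' For one functional class, the masked load of an individual is the
#' proportion of its called genotypes in that class that are heterozygous,
#' and the realized load the proportion homozygous for the derived allele;
#' both are computed as expectations over genotype probabilities (or hard
#' calls), over polarized sites of the class only.
#'
#' @param panel a \linkS4class{GenotypePanel} with \code{class} and ancestral
#'   alleles filled.
#' @param class functional class label(s).
#' @param useGP expectation over genotype probabilities (TRUE) or hard calls.
#' @return data.frame with \code{individual}, \code{masked}, \code{realized},
#'   \code{homAncestral}, \code{nSites}; load values are NA for individuals
#'   with no called site of the class.
#' @export
maskedRealizedLoad <- function(panel, class, useGP = TRUE) {
    keep <- variantClass(panel) %in% class & !is.na(ancestralAllele(panel))
    if (!any(keep)) stop("no polarized site of class ", paste(class, collapse = "/"))
    sub <- panel[keep, ]
    dd <- derivedDosages(sub)
    called <- !is.na(dd)
    if (useGP) {
        gp <- genoProbabilities(sub)
        aa <- ancestralAllele(sub); alt <- mcols(rowRanges(sub))$alt
        flip <- !is.na(aa) & aa == alt
        pHomDer <- gp[[3L]]; pHomDer[flip, ] <- gp[[1L]][flip, , drop = FALSE]
        pHomAnc <- gp[[1L]]; pHomAnc[flip, ] <- gp[[3L]][flip, , drop = FALSE]
        pHet <- gp[[2L]]
    } else {
        pHet <- (dd == 1L) * 1
        pHomDer <- (dd == 2L) * 1
        pHomAnc <- (dd == 0L) * 1
    }
    pHet[!called] <- NA; pHomDer[!called] <- NA; pHomAnc[!called] <- NA
    n <- colSums(called)
    masked <- colMeans(pHet, na.rm = TRUE)
    realized <- colMeans(pHomDer, na.rm = TRUE)
    homAnc <- colMeans(pHomAnc, na.rm = TRUE)
    masked[n == 0] <- NA; realized[n == 0] <- NA; homAnc[n == 0] <- NA
    data.frame(individual = colnames(panel), masked = masked,
               realized = realized, homAncestral = homAnc, nSites = n,
               row.names = NULL)
}

#' Relative number of derived alleles RX/Y with block-jackknife CI
#'
#' The raw statistic is \eqn{\sum_s f_X(1-f_Y) / \sum_s f_Y(1-f_X)} over the
#' class sites; values above 1 indicate relatively more derived alleles in X
#' (relaxed purifying selection in X for deleterious classes). When
#' normalizer sites are supplied (typically intergenic variants) the
#' standardized statistic is raw(class)/raw(normalizer). The 95% CI is a
#' leave-one-block-out jackknife over contiguous equal-SNP blocks
#' (+/- 1.96 SE), removing the b-th class block and b-th normalizer block
#' together.
#'
#' @param fx,fy derived-allele frequency vectors in X and Y (genome order,
#'   NA dropped pairwise).
#' @param classIdx indices of class sites within \code{fx}/\code{fy}.
#' @param normIdx indices of normalizer sites (NULL: no standardization).
#' @param nBlocks number of jackknife blocks.
#' @return list with \code{raw}, \code{standardized}, \code{se}, \code{ci},
#'   \code{nBlocks}; NA with a warning when a denominator sum is zero.
#' @export
rxy <- function(fx, fy, classIdx, normIdx = NULL, nBlocks = 100) {
    ratio <- function(ix, iy = ix, drop = NULL) {
        i <- setdiff(ix, drop)
        num <- sum(fx[i] * (1 - fy[i]), na.rm = TRUE)
        den <- sum(fy[i] * (1 - fx[i]), na.rm = TRUE)
        if (den == 0) return(NA_real_)
        num / den
    }
    ok <- !is.na(fx) & !is.na(fy)
    classIdx <- classIdx[ok[classIdx]]
    if (!is.null(normIdx)) normIdx <- normIdx[ok[normIdx]]
    raw <- ratio(classIdx)
    if (is.na(raw)) { warning("zero denominator in RX/Y"); }
    std <- raw
    if (!is.null(normIdx)) std <- raw / ratio(normIdx)
    nBlocks <- min(nBlocks, length(classIdx),
                   if (is.null(normIdx)) Inf else length(normIdx))
    bClass <- equalBlocks(length(classIdx), nBlocks)
    bNorm <- if (!is.null(normIdx)) equalBlocks(length(normIdx), nBlocks)
    pseudo <- vapply(seq_len(nBlocks), function(b) {
        r <- ratio(classIdx[bClass != b])
        if (is.null(normIdx)) r else r / ratio(normIdx[bNorm != b])
    }, numeric(1))
    se <- .jackknifeSE(pseudo)
    list(raw = raw, standardized = std, se = se,
         ci = std + c(-1.96, 1.96) * se, nBlocks = nBlocks)
}

#' Genomic prediction of breeding values from an effect table
#'
#' Sums allele dosage times reported allele effect over matched SNPs, per
#' individual. Effect-table rows are matched to panel sites by chromosome
#' and position; the effect allele must equal the panel's ref or alt allele
#' (dosage is flipped when it equals ref), otherwise the row is dropped and
#' counted.
#'
#' @param panel a \linkS4class{GenotypePanel} (hard calls used; missing
#'   genotypes contribute 0).
#' @param effects data.frame with columns \code{chrom}, \code{pos},
#'   \code{allele}, \code{effect}.
#' @return list with \code{values} (named per-individual breeding values),
#'   \code{byPop} (per-population mean/min/max), \code{nUsed},
#'   \code{nDropped}.
#' @export
predictHeight <- function(panel, effects) {
    key <- sprintf("%s:%d", as.character(GenomicRanges::seqnames(rowRanges(panel))),
                   GenomicRanges::start(rowRanges(panel)))
    hit <- match(sprintf("%s:%d", as.character(effects$chrom),
                         as.integer(effects$pos)), key)
    ref <- mcols(rowRanges(panel))$ref
    alt <- mcols(rowRanges(panel))$alt
    use <- !is.na(hit) &
        (effects$allele == ref[hit] | effects$allele == alt[hit])
    nDropped <- sum(!use)
    hit <- hit[use]
    beta <- effects$effect[use]
    flip <- effects$allele[use] == ref[hit]
    d <- dosages(panel)[hit, , drop = FALSE]
    d[flip, ] <- 2L - d[flip, , drop = FALSE]
    d[is.na(d)] <- 0L
    values <- as.numeric(crossprod(d, beta))
    names(values) <- colnames(panel)
    pop <- popLabels(panel)
    byPop <- do.call(rbind, lapply(split(values, pop), function(v)
        data.frame(mean = mean(v), min = min(v), max = max(v))))
    byPop <- data.frame(pop = rownames(byPop), byPop, row.names = NULL)
    list(values = values, byPop = byPop, nUsed = sum(use),
         nDropped = nDropped)
}
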