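#' EHH decay curve and integrated haplotype homozygosity at a focal SNP
#'
#' The extended haplotype homozygosity of an allele at distance d is the
#' probability that two random haplotypes carrying that allele are identical
#' over the whole interval between the focal SNP and d. Curves are walked
#' outward in both directions until EHH drops below \code{cutoff} and
#' integrated over the genetic map by the trapezoidal rule to give iHH per
#' allele; iES is the analogous integral of the site-EHH (EHHS, computed
#' over all haplotypes and normalized to 1 at the focal SNP).
#'
#' @param panel a \linkS4class{HaplotypePanel} restricted to one chromosome
#'   (and typically one population).
#' @param focal SNP index.
#' @param cutoff EHH value below which integration stops.
#' @param minCarriers alleles carried by fewer haplotypes get NA curves.
#' @return list with per-allele curves (data.frames index/cm/ehh),
#'   \code{ihh0}, \code{ihh1}, \code{ies}, and the focal allele frequency
#'   \code{freq1}.
#' @export
ehhStats <- function(panel, focal, cutoff = 0.05, minCarriers = 2) {
    h <- haplotypes(panel)
    cm <- panel@cm
    if (length(unique(panel@chrom)) > 1)
        stop("ehhStats expects a single chromosome")
    alleles <- h[focal, ]
    out <- list(freq1 = mean(alleles == 1L))
    for (a in 0:1) {
        carriers <- which(alleles == a)
        if (length(carriers) < minCarriers) {
            out[[paste0("curve", a)]] <- NULL
            out[[paste0("ihh", a)]] <- NA_real_
            next
        }
        cv <- .ehhWalk(h[, carriers, drop = FALSE], cm, focal, cutoff,
                       grouped = FALSE)
        out[[paste0("curve", a)]] <- cv$curve
        out[[paste0("ihh", a)]] <- cv$integral
    }
    es <- .ehhWalk(h, cm, focal, cutoff, grouped = TRUE)
    out$curveS <- es$curve
    out$ies <- es$integral
    out
}

# Walk outward from the focal SNP refining haplotype groups; grouped = TRUE
# computes the site-EHH (EHHS) normalized by the focal-site homozygosity.
.ehhWalk <- function(h, cm, focal, cutoff, grouped) {
    n <- ncol(h)
    pairs <- function(id) {
        tab <- tabulate(id)
        sum(tab * (tab - 1))
    }
    denom <- if (grouped) {
        id0 <- h[focal, ] + 1L
        d <- pairs(id0)
        if (d == 0) return(list(curve = NULL, integral = NA_real_))
        d
    } else n * (n - 1)
    walk <- function(idxSeq) {
        id <- if (grouped) h[focal, ] + 1L else rep(1L, n)
        ehh <- numeric(0); at <- integer(0)
        for (i in idxSeq) {
            key <- id * 2L + h[i, ]
            id <- match(key, unique(key))
            v <- pairs(id) / denom
            ehh <- c(ehh, v); at <- c(at, i)
            if (v < cutoff) break
        }
        list(ehh = ehh, at = at)
    }
    nSnp <- nrow(h)
    right <- if (focal < nSnp) walk((focal + 1L):nSnp) else
        list(ehh = numeric(0), at = integer(0))
    left <- if (focal > 1L) walk((focal - 1L):1L) else
        list(ehh = numeric(0), at = integer(0))
    idx <- c(rev(left$at), focal, right$at)
    ehh <- c(rev(left$ehh), 1, right$ehh)
    curve <- data.frame(index = idx, cm = cm[idx], ehh = ehh)
    integrate <- function(at, vals) {
        x <- c(cm[focal], cm[at]); y <- pmax(c(1, vals), 0)
        sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
    }
    int <- 0
    if (length(right$at)) int <- int + integrate(right$at, right$ehh)
    if (length(left$at))
        int <- int + abs(integrate(left$at, left$ehh))
    list(curve = curve, integral = abs(int))
}

#' Genome-wide iHS scan
#'
#' For every SNP passing the minor-allele-frequency filter, computes the
#' log-ratio of the integrated EHH of allele 1 (the panel's alternate
#' allele; alleles are not polarized) over allele 0, then standardizes
#' genome-wide in a single frequency bin (mean 0, SD 1). SNPs with a zero or
#' undefined iHH are skipped and counted.
#'
#' @param panel a \linkS4class{HaplotypePanel} (one population).
#' @param minMaf minor-allele-frequency threshold (SNPs with MAF <=
#'   \code{minMaf} are excluded).
#' @param cutoff EHH integration cutoff.
#' @return data.frame with chrom, pos, index, freq1, ihh0, ihh1, uniHS
#'   (unstandardized), ihs (standardized); attribute \code{nSkipped}.
#' @export
ihsScan <- function(panel, minMaf = 0.01, cutoff = 0.05) {
    h <- haplotypes(panel)
    freq1 <- rowMeans(h)
    maf <- pmin(freq1, 1 - freq1)
    keep <- which(maf > minMaf)
    res <- lapply(keep, function(i) {
        sub <- .chromSlice(panel, panel@chrom[i])
        st <- ehhStats(sub$panel, sub$map[i], cutoff = cutoff)
        c(ihh0 = st$ihh0, ihh1 = st$ihh1)
    })
    ihh0 <- vapply(res, `[[`, numeric(1), "ihh0")
    ihh1 <- vapply(res, `[[`, numeric(1), "ihh1")
    uni <- log(ihh1 / ihh0)
    ok <- is.finite(uni)
    ihs <- rep(NA_real_, length(uni))
    ihs[ok] <- (uni[ok] - mean(uni[ok])) / stats::sd(uni[ok])
    out <- data.frame(chrom = panel@chrom[keep], pos = panel@pos[keep],
                      index = keep, freq1 = freq1[keep], ihh0 = ihh0,
                      ihh1 = ihh1, uniHS = uni, ihs = ihs)
    attr(out, "nSkipped") <- sum(!ok)
    out
}

.chromSlice <- function(panel, chrom) {
    idx <- which(panel@chrom == chrom)
    sub <- new("HaplotypePanel",
               haplotypes = panel@haplotypes[idx, , drop = FALSE],
               chrom = panel@chrom[idx], pos = panel@pos[idx],
               cm = panel@cm[idx], pop = panel@pop)
    map <- integer(length(panel@chrom))
    map[idx] <- seq_along(idx)
    list(panel = sub, map = map)
}

#' Rsb scan between two populations
#'
#' Log-ratio of the integrated site-EHH (iES) of population X over
#' population Y at each shared SNP, standardized genome-wide; positive
#' values indicate extended haplotype homozygosity in X. SNPs monomorphic in
#' both populations are excluded.
#'
#' @param panelX,panelY \linkS4class{HaplotypePanel}s on identical SNPs.
#' @param cutoff EHH integration cutoff.
#' @return data.frame with chrom, pos, index, iesX, iesY, unRsb, rsb.
#' @export
rsbScan <- function(panelX, panelY, cutoff = 0.05) {
    stopifnot(nrow(haplotypes(panelX)) == nrow(haplotypes(panelY)))
    fX <- rowMeans(haplotypes(panelX)); fY <- rowMeans(haplotypes(panelY))
    keep <- which(!(fX %in% c(0, 1) & fY %in% c(0, 1)))
    ies <- function(panel, i) {
        sub <- .chromSlice(panel, panel@chrom[i])
        ehhStats(sub$panel, sub$map[i], cutoff = cutoff)$ies
    }
    iesX <- vapply(keep, function(i) ies(panelX, i), numeric(1))
    iesY <- vapply(keep, function(i) ies(panelY, i), numeric(1))
    uni <- log(iesX / iesY)
    ok <- is.finite(uni)
    rsb <- rep(NA_real_, length(uni))
    rsb[ok] <- (uni[ok] - mean(uni[ok])) / stats::sd(uni[ok])
    data.frame(chrom = panelX@chrom[keep], pos = panelX@pos[keep],
               index = keep, iesX = iesX, iesY = iesY, unRsb = uni,
               rsb = rsb)
}

#' Transform standardized scan statistics to -log10 p-value scores
#'
#' Two-sided for iHS: \eqn{p_{iHS} = -\log_{10}(1 - 2|\Phi(x) - 0.5|)};
#' one-sided for Rsb: \eqn{p_{Rsb} = -\log_{10}(1 - \Phi(x))}; Phi is the
#' standard normal CDF. Non-finite inputs yield NA.
#'
#' @param stat standardized statistic vector.
#' @param mode "ihs" (two-sided) or "rsb" (one-sided).
#' @return numeric vector of -log10 p scores.
#' @export
pTransform <- function(stat, mode = c("ihs", "rsb")) {
    mode <- match.arg(mode)
    out <- rep(NA_real_, length(stat))
    ok <- is.finite(stat)
    if (mode == "ihs") {
        lp <- stats::pnorm(abs(stat[ok]), lower.tail = FALSE, log.p = TRUE)
        out[ok] <- -(lp + log(2)) / log(10)
    } else {
        lp <- stats::pnorm(stat[ok], lower.tail = FALSE, log.p = TRUE)
        out[ok] <- -lp / log(10)
    }
    out
}

#' Lindley local-score segmentation of a -log10 p profile
#'
#' Builds the Lindley process \eqn{L_i = \max(0, L_{i-1} + (p_i - \xi))}
#' from per-SNP scores \eqn{p_i - \xi} (p on the -log10 scale), derives a
#' per-chromosome significance threshold as the (1 - alpha) quantile of the
#' maximum Lindley value under a Monte-Carlo null, and reports every maximal
#' excursion whose peak exceeds the threshold. The default null
#' (\code{permMode = "unif"}) draws iid uniform p-values — the distribution
#' standardized scan statistics imply under neutrality — giving exactly
#' calibrated per-chromosome thresholds; \code{"shuffle"}/\code{"rotate"}
#' permute the observed scores instead and are conservative when a single
#' large score dominates the excursion maximum.
#' The peak is the leftmost argmax within the excursion; window
#' bounds follow the excursion by default (first SNP after the process
#' leaves 0 to the last SNP before it returns), or the first
#' positive-score SNP convention when \code{boundary = "first_positive"}.
#'
#' @param p per-SNP -log10 p-values of one chromosome, in position order.
#' @param pos physical positions (defaults to the SNP index).
#' @param xi score shift (default 2 = p-values below 0.01 score positively).
#' @param alpha per-chromosome significance level of the threshold.
#' @param nPerm number of Monte-Carlo null profiles.
#' @param permMode "unif" (iid uniform p-values, default), "shuffle"
#'   (random permutation of the observed scores) or "rotate" (circular
#'   rotation).
#' @param boundary window-bound convention.
#' @param threshold optional precomputed threshold (skips permutation).
#' @return list with \code{windows} (data.frame incl. the peak's exact
#'   Monte-Carlo \code{pvalue}), \code{threshold} (the (1-alpha) permutation
#'   quantile, for reference), \code{lindley}, \code{score}.
#' @examples
#' localScore(c(3, 1.5, 4), xi = 2, nPerm = 10)$lindley  # 1, 0.5, 2.5
#' @export
localScore <- function(p, pos = seq_along(p), xi = 2, alpha = 0.01,
                       nPerm = 1000, permMode = c("unif", "shuffle",
                                                  "rotate"),
                       boundary = c("excursion", "first_positive"),
                       threshold = NULL) {
    boundary <- match.arg(boundary)
    permMode <- match.arg(permMode)
    keep <- is.finite(p)
    s <- p[keep] - xi
    posK <- pos[keep]
    idxK <- which(keep)
    if (!length(s)) {
        empty <- data.frame(startIndex = integer(0), endIndex = integer(0),
                            startPos = numeric(0), endPos = numeric(0),
                            nSnps = integer(0), peakIndex = integer(0),
                            peakPos = numeric(0), peakScore = numeric(0),
                            pvalue = numeric(0))
        return(list(windows = empty, threshold = NA_real_,
                    lindley = numeric(0), score = s))
    }
    L <- .lindley(s)
    maxima <- NULL
    if (is.null(threshold)) {
        n <- length(s)
        maxima <- vapply(seq_len(nPerm), function(k) {
            perm <- switch(permMode,
                unif = -log10(stats::runif(n)) - xi,
                shuffle = s[sample.int(n)],
                rotate = {
                    off <- sample.int(n, 1L)
                    s[((seq_len(n) + off - 1L) %% n) + 1L]
                })
            max(.lindley(perm))
        }, numeric(1))
        threshold <- stats::quantile(maxima, 1 - alpha, names = FALSE)
    }
    runs <- .excursions(L)
    windows <- NULL
    if (nrow(runs)) {
        runs$peakRel <- vapply(seq_len(nrow(runs)), function(k) {
            seg <- L[runs$start[k]:runs$end[k]]
            which.max(seg)  # leftmost on ties
        }, integer(1))
        runs$peak <- runs$start + runs$peakRel - 1L
        runs$score <- L[runs$peak]
        if (!is.null(maxima)) {
            # exact Monte-Carlo p-value per excursion peak
            runs$pvalue <- vapply(runs$score, function(x)
                (1 + sum(maxima >= x)) / (nPerm + 1), numeric(1))
            sig <- runs[runs$pvalue <= alpha, , drop = FALSE]
        } else {
            runs$pvalue <- NA_real_
            sig <- runs[runs$score > threshold, , drop = FALSE]
        }
        if (nrow(sig)) {
            start <- sig$start
            if (boundary == "first_positive") {
                start <- vapply(seq_len(nrow(sig)), function(k) {
                    seg <- sig$start[k]:sig$end[k]
                    seg[which(s[seg] > 0)[1]]
                }, integer(1))
            }
            windows <- data.frame(
                startIndex = idxK[start], endIndex = idxK[sig$end],
                startPos = posK[start], endPos = posK[sig$end],
                nSnps = sig$end - start + 1L,
                peakIndex = idxK[sig$peak], peakPos = posK[sig$peak],
                peakScore = sig$score, pvalue = sig$pvalue)
        }
    }
    if (is.null(windows))
        windows <- data.frame(startIndex = integer(0), endIndex = integer(0),
                              startPos = numeric(0), endPos = numeric(0),
                              nSnps = integer(0), peakIndex = integer(0),
                              peakPos = numeric(0), peakScore = numeric(0),
                              pvalue = numeric(0))
    list(windows = windows, threshold = threshold, lindley = L, score = s)
}

.lindley <- function(s) {
    S <- cumsum(s)
    S - pmin(0, cummin(S))
}

.excursions <- function(L) {
    pos <- L > 0
    if (!any(pos)) return(data.frame(start = integer(0), end = integer(0)))
    r <- rle(pos)
    end <- cumsum(r$lengths)
    start <- end - r$lengths + 1L
    data.frame(start = start[r$values], end = end[r$values])
}

#' Annotate candidate windows with their nearest gene
#'
#' For each window, reports the gene nearest to the peak position: distance
#' 0 when the peak lies inside the gene, otherwise the gap to the closer
#' gene boundary in kb. Equidistant genes are all reported and the window is
#' flagged ambiguous.
#'
#' @param windows data.frame as returned by \code{\link{localScore}}, plus a
#'   \code{chrom} column (added if absent via the \code{chrom} argument).
#' @param genes a \code{GRanges} of gene intervals with a \code{gene_name}
#'   metadata column (or a data.frame with chrom/start/end/name).
#' @param chrom chromosome of the windows when not a column.
#' @return the windows with \code{nearestGene}, \code{distanceKb},
#'   \code{ambiguous} appended (one row per window-gene tie).
#' @export
annotateRegions <- function(windows, genes, chrom = NULL) {
    if (is.data.frame(genes))
        genes <- GRanges(genes$chrom, IRanges(genes$start, genes$end),
                         gene_name = genes$name)
    if (!nrow(windows)) {
        windows$nearestGene <- character(0)
        windows$distanceKb <- numeric(0)
        windows$ambiguous <- logical(0)
        return(windows)
    }
    if (is.null(windows$chrom)) windows$chrom <- chrom
    out <- lapply(seq_len(nrow(windows)), function(k) {
        w <- windows[k, , drop = FALSE]
        if (length(genes) == 0)
            return(cbind(w, nearestGene = NA_character_,
                         distanceKb = NA_real_, ambiguous = FALSE))
        peak <- GRanges(w$chrom, IRanges(w$peakPos, width = 1))
        dists <- suppressWarnings(
            GenomicRanges::distance(rep(peak, length(genes)), genes))
        if (all(is.na(dists)))
            return(cbind(w, nearestGene = NA_character_,
                         distanceKb = NA_real_, ambiguous = FALSE))
        gi <- which(dists == min(dists, na.rm = TRUE))  # keep all ties
        dist <- dists[gi] / 1000
        cbind(w[rep(1, length(gi)), , drop = FALSE],
              nearestGene = S4Vectors::mcols(genes)$gene_name[gi],
              distanceKb = dist, ambiguous = length(gi) > 1)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}
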