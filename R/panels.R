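#' Construct a GenotypePanel
#'
#' Builds the central genotype container from per-site coordinates, hard
#' calls and (optionally) genotype likelihoods. When no likelihoods are
#' given, certainty likelihoods are derived from the calls (1 for the called
#' genotype, 0 elsewhere; uniform for missing calls).
#'
#' @param chrom,pos,ref,alt per-site coordinates and alleles (pos 1-based).
#' @param dosage sites x individuals integer matrix of alternate-allele
#'   dosages (0/1/2, NA = missing).
#' @param gl optional list of three sites x individuals matrices of
#'   linear-scale genotype likelihoods for dosages 0, 1, 2.
#' @param pop population label per individual.
#' @param aa optional ancestral-allele call per site (NA = unassigned).
#' @param class optional functional class per site.
#' @param sample optional sample names.
#' @return a \linkS4class{GenotypePanel}.
#' @examples
#' gp <- GenotypePanel(chrom = "1", pos = 1:3, ref = "A", alt = "C",
#'                     dosage = matrix(c(0L, 1L, 2L, 0L, 0L, 1L), ncol = 2),
#'                     pop = c("P1", "P2"))
#' dosages(gp)
#' @export
GenotypePanel <- function(chrom, pos, ref, alt, dosage, gl = NULL, pop,
                          aa = NULL, class = NULL, sample = NULL) {
    dosage <- as.matrix(dosage)
    storage.mode(dosage) <- "integer"
    n <- nrow(dosage); m <- ncol(dosage)
    chrom <- rep_len(as.character(chrom), n)
    ref <- rep_len(as.character(ref), n)
    alt <- rep_len(as.character(alt), n)
    if (is.null(gl)) {
        gl <- .certaintyGL(dosage)
    } else {
        gl <- lapply(gl, as.matrix)
        tot <- gl[[1L]] + gl[[2L]] + gl[[3L]]
        gl <- lapply(gl, function(g) g / tot)
    }
    if (is.null(sample)) sample <- sprintf("ind%03d", seq_len(m))
    rr <- GRanges(chrom, IRanges(start = as.integer(pos), width = 1L))
    mcols(rr)$ref <- ref
    mcols(rr)$alt <- alt
    mcols(rr)$aa <- if (is.null(aa)) rep(NA_character_, n) else
        rep_len(as.character(aa), n)
    mcols(rr)$class <- if (is.null(class)) rep(NA_character_, n) else
        rep_len(as.character(class), n)
    names(rr) <- sprintf("%s:%d", chrom, as.integer(pos))
    dimnames(dosage) <- list(names(rr), sample)
    gl <- lapply(gl, function(g) { dimnames(g) <- dimnames(dosage); g })
    se <- SummarizedExperiment(
        assays = SimpleList(dosage = dosage, gl0 = gl[[1L]], gl1 = gl[[2L]],
                            gl2 = gl[[3L]]),
        rowRanges = rr,
        colData = DataFrame(pop = rep_len(as.character(pop), m),
                            row.names = sample))
    new("GenotypePanel", se)
}

.certaintyGL <- function(dosage) {
    gl <- lapply(0:2, function(g) {
        m <- (dosage == g) * 1
        m[is.na(m)] <- 1 / 3
        m
    })
    gl
}

#' @rdname GenotypePanel-class
#' @export
setMethod("dosages", "GenotypePanel", function(x) assay(x, "dosage"))

#' @rdname GenotypePanel-class
#' @export
setMethod("genoLikelihoods", "GenotypePanel", function(x)
    list(assay(x, "gl0"), assay(x, "gl1"), assay(x, "gl2")))

#' @rdname GenotypePanel-class
#' @export
setMethod("popLabels", "GenotypePanel", function(x) colData(x)$pop)

#' @rdname GenotypePanel-class
#' @export
setMethod("ancestralAllele", "GenotypePanel", function(x) mcols(rowRanges(x))$aa)

#' @rdname GenotypePanel-class
#' @export
setMethod("variantClass", "GenotypePanel", function(x) mcols(rowRanges(x))$class)

#' Genotype posterior probabilities under a flat genotype prior
#'
#' Renormalizes the stored likelihood triples to per-genotype probabilities
#' (GP). Sites/individuals with uninformative likelihoods get 1/3 each.
#'
#' @param x a \linkS4class{GenotypePanel}.
#' @return list of three sites x individuals matrices (dosage 0, 1, 2).
#' @export
genoProbabilities <- function(x) {
    gl <- genoLikelihoods(x)
    tot <- gl[[1L]] + gl[[2L]] + gl[[3L]]
    lapply(gl, function(g) g / tot)
}

#' Derived-allele dosage orientation
#'
#' Returns dosage counted on the derived allele: identical to alt dosage when
#' the ancestral allele equals ref, flipped (2 - dosage) when ancestral = alt,
#' and NA rows when the site is unpolarized.
#'
#' @param x a \linkS4class{GenotypePanel}.
#' @return sites x individuals matrix.
#' @export
derivedDosages <- function(x) {
    d <- dosages(x)
    aa <- ancestralAllele(x)
    ref <- mcols(rowRanges(x))$ref
    alt <- mcols(rowRanges(x))$alt
    flip <- !is.na(aa) & aa == alt
    none <- is.na(aa) | (aa != ref & aa != alt)
    d[flip, ] <- 2L - d[flip, , drop = FALSE]
    d[none, ] <- NA_integer_
    d
}

setMethod("show", "GenotypePanel", function(object) {
    cat(sprintf("GenotypePanel: %d sites x %d individuals\n",
                nrow(object), ncol(object)))
    tab <- table(popLabels(object))
    cat("populations:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
    cat(sprintf("polarized sites: %d / %d\n",
                sum(!is.na(ancestralAllele(object))), nrow(object)))
})

#' Construct a HaplotypePanel
#'
#' @param haplotypes SNPs x haplotypes 0/1 integer matrix (two columns per
#'   diploid individual, consecutive).
#' @param chrom,pos chromosome and physical position (bp) per SNP.
#' @param cm genetic-map position per SNP; when NULL, derived from \code{pos}
#'   at \code{mapRate} cM/Mb.
#' @param pop population label per haplotype.
#' @param mapRate map rate in cM/Mb used when \code{cm} is NULL.
#' @return a \linkS4class{HaplotypePanel}.
#' @export
HaplotypePanel <- function(haplotypes, chrom, pos, cm = NULL, pop,
                           mapRate = 1) {
    haplotypes <- as.matrix(haplotypes)
    storage.mode(haplotypes) <- "integer"
    n <- nrow(haplotypes)
    chrom <- rep_len(as.character(chrom), n)
    pos <- as.numeric(pos)
    if (is.null(cm)) cm <- pos / 1e6 * mapRate
    new("HaplotypePanel", haplotypes = haplotypes, chrom = chrom, pos = pos,
        cm = as.numeric(cm), pop = rep_len(as.character(pop),
                                           ncol(haplotypes)))
}

#' @rdname HaplotypePanel-class
#' @export
setMethod("haplotypes", "HaplotypePanel", function(x) x@haplotypes)

#' @rdname HaplotypePanel-class
#' @export
setMethod("mapTable", "HaplotypePanel", function(x)
    data.frame(chrom = x@chrom, pos = x@pos, cm = x@cm))

#' @rdname HaplotypePanel-class
#' @export
setMethod("popLabels", "HaplotypePanel", function(x) x@pop)

setMethod("show", "HaplotypePanel", function(object) {
    cat(sprintf("HaplotypePanel: %d SNPs x %d haplotypes on %d chromosome(s)\n",
                nrow(object@haplotypes), ncol(object@haplotypes),
                length(unique(object@chrom))))
    tab <- table(object@pop)
    cat("populations:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
})

#' Subset a haplotype panel by population
#'
#' @param x a \linkS4class{HaplotypePanel}.
#' @param pop population label(s) to keep.
#' @export
subsetPop <- function(x, pop) {
    keep <- x@pop %in% pop
    new("HaplotypePanel", haplotypes = x@haplotypes[, keep, drop = FALSE],
        chrom = x@chrom, pos = x@pos, cm = x@cm, pop = x@pop[keep])
}

#' Collapse a haplotype panel to a genotype panel of hard calls
#'
#' Pairs consecutive haplotype columns into diploid individuals and sums
#' alleles into alternate-allele dosages (allele 1 is taken as alternate).
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param aa optional ancestral-allele call per site ("ref"/"alt" alleles are
#'   generated as A/C).
#' @param class optional functional class per site.
#' @return a \linkS4class{GenotypePanel} of certain genotypes.
#' @export
haplotypesToGenotypes <- function(panel, aa = NULL, class = NULL) {
    h <- haplotypes(panel)
    stopifnot(ncol(h) %% 2 == 0)
    idx <- seq(1, ncol(h), by = 2)
    dos <- h[, idx, drop = FALSE] + h[, idx + 1, drop = FALSE]
    pop <- popLabels(panel)[idx]
    GenotypePanel(chrom = panel@chrom, pos = panel@pos, ref = "A", alt = "C",
                  dosage = dos, pop = pop, aa = aa, class = class)
}

#' @rdname EnvDesign-class
#' @export
setMethod("envScores", "EnvDesign", function(x)
    x@scores[, seq_len(x@nKeep), drop = FALSE])

#' @rdname EnvDesign-class
#' @export
setMethod("geaCoefficients", "EnvDesign", function(x) x@B)

setMethod("show", "EnvDesign", function(object) {
    cat(sprintf("EnvDesign: %d populations x %d covariables, %d PCs retained (%.1f%% variance)\n",
                nrow(object@covariates), ncol(object@covariates), object@nKeep,
                100 * sum(object@varExplained[seq_len(object@nKeep)])))
    if (!is.null(object@B))
        cat(sprintf("GEA coefficients: %d SNPs x %d PCs\n",
                    nrow(object@B), ncol(object@B)))
})

setMethod("show", "SimConfig", function(object) {
    cat(sprintf("SimConfig: %d founders, admixture %.2f, bottleneck %d generations, %d sites\n",
                object@nFounders, object@admixtureFraction,
                object@tBottleneck, object@nSites))
})

setMethod("show", "SimTruth", function(object) {
    cat(sprintf("SimTruth: %d sites x %d populations; classes: %s\n",
                nrow(object@trueFreq), ncol(object@trueFreq),
                paste(names(table(object@classes)), collapse = ", ")))
})
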