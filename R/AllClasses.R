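#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges colData rowRanges<- assay<-
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Simulation configuration for synthetic founder-bottleneck cohorts
#'
#' Holds every knob of the cohort simulator: the demography (two diverged
#' source populations, an admixed founder group, rapid post-founding
#' expansion), the per-class selection regime, and the sequencing-noise model.
#' Defaults reproduce the study conditions of a five-founder island herd
#' established ~22 generations before sampling from a ~75/25 taurine/zebu
#' admixture, sequenced at ~10x.
#'
#' @slot nFounders number of diploid founders of the target population.
#' @slot admixtureFraction proportion of source-1 ancestry among founders.
#' @slot tBottleneck generations between founding and sampling.
#' @slot tDivergence generations separating the two source populations.
#' @slot tSisterSplit generations ago (before founding) at which the sister
#'   population of source 1 split; used by F4-ratio designs.
#' @slot sourceSize diploid size of each source population.
#' @slot ancestralSize diploid size of the ancestral population (burn-in).
#' @slot burnIn burn-in generations in the ancestral population.
#' @slot expansionSize diploid size the target expands to after founding.
#' @slot growthRate per-generation geometric growth factor after founding.
#' @slot nSites number of bi-allelic sites.
#' @slot nChrom number of chromosomes the sites are spread over.
#' @slot chromLength chromosome length in bp.
#' @slot classProportions named proportions of the five functional classes.
#' @slot selectionS named selection coefficients (<= 0) per class.
#' @slot selectionH named dominance coefficients per class.
#' @slot nSampled diploid sample size per emitted population.
#' @slot meanDepth mean sequencing depth (reads/site).
#' @slot errorRate per-base sequencing error rate.
#' @slot mapRate genetic map rate in cM per Mb.
#' @slot seed integer seed.
#' @export
setClass("SimConfig", representation(
    nFounders = "numeric", admixtureFraction = "numeric",
    tBottleneck = "numeric", tDivergence = "numeric", tSisterSplit = "numeric",
    sourceSize = "numeric", ancestralSize = "numeric", burnIn = "numeric",
    expansionSize = "numeric", growthRate = "numeric",
    nSites = "numeric", nChrom = "numeric", chromLength = "numeric",
    classProportions = "numeric", selectionS = "numeric", selectionH = "numeric",
    nSampled = "numeric", meanDepth = "numeric", errorRate = "numeric",
    mapRate = "numeric", seed = "numeric"))

.variantClasses <- c("intergenic", "synonymous", "ns_tolerated",
                     "ns_deleterious", "lof")

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@nFounders < 2)
        msg <- c(msg, "nFounders must be >= 2")
    if (object@admixtureFraction < 0 || object@admixtureFraction > 1)
        msg <- c(msg, "admixtureFraction must lie in [0, 1]")
    if (abs(sum(object@classProportions) - 1) > 1e-8)
        msg <- c(msg, "classProportions must sum to 1")
    if (!identical(names(object@classProportions), .variantClasses))
        msg <- c(msg, "classProportions must be named intergenic, synonymous, ns_tolerated, ns_deleterious, lof")
    if (any(object@selectionS[c("ns_deleterious", "lof")] > 0))
        msg <- c(msg, "selectionS must be <= 0 for deleterious classes")
    if (object@nSites < 1) msg <- c(msg, "nSites must be positive")
    if (object@meanDepth < 0) msg <- c(msg, "meanDepth must be >= 0")
    if (object@errorRate < 0 || object@errorRate >= 0.5)
        msg <- c(msg, "errorRate must lie in [0, 0.5)")
    if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated cohort
#'
#' Carries the quantities the simulator knows exactly and the estimators are
#' later judged against: true derived-allele frequencies per population,
#' per-site functional class, per-individual expected source-1 ancestry, and
#' the founder allele frequencies of the target population.
#'
#' @slot trueFreq matrix (sites x populations) of true derived-allele
#'   frequencies at sampling time.
#' @slot founderFreq derived-allele frequency among the target founders.
#' @slot classes character vector of per-site functional classes.
#' @slot ancestry named per-individual expected source-1 ancestry dosage.
#' @slot config the \linkS4class{SimConfig} used.
#' @export
setClass("SimTruth", representation(
    trueFreq = "matrix", founderFreq = "numeric", classes = "character",
    ancestry = "numeric", config = "SimConfig"))

#' Genotype panel: calls and genotype likelihoods with population labels
#'
#' A \linkS4class{RangedSummarizedExperiment} with assays \code{dosage}
#' (alternate-allele dosage 0/1/2, \code{NA} = missing), and \code{gl0},
#' \code{gl1}, \code{gl2} (linear-scale genotype likelihoods, rescaled so the
#' best genotype has likelihood 1; equal values at uninformative sites).
#' Row ranges carry \code{ref}, \code{alt}, the ancestral-allele call
#' \code{aa} (NA when unassigned) and the functional \code{class}; column
#' data carries the population label \code{pop}.
#'
#' @export
setClass("GenotypePanel", contains = "RangedSummarizedExperiment")

setValidity("GenotypePanel", function(object) {
    msg <- character()
    need <- c("dosage", "gl0", "gl1", "gl2")
    if (!all(need %in% names(assays(object))))
        return("assays dosage, gl0, gl1, gl2 are required")
    d <- assay(object, "dosage")
    if (!all(d %in% c(0L, 1L, 2L, NA)))
        msg <- c(msg, "dosage values must be 0, 1, 2 or NA")
    for (a in c("gl0", "gl1", "gl2"))
        if (any(assay(object, a) < 0, na.rm = TRUE))
            msg <- c(msg, sprintf("%s contains negative likelihoods", a))
    tot <- assay(object, "gl0") + assay(object, "gl1") + assay(object, "gl2")
    if (any(tot <= 0, na.rm = TRUE))
        msg <- c(msg, "likelihood triples must not be all zero")
    if (!"pop" %in% names(colData(object)))
        msg <- c(msg, "colData must contain a 'pop' column")
    if (length(msg)) msg else TRUE
})

#' Phased haplotype panel on a genetic map
#'
#' Binary phased haplotypes (rows = SNPs, columns = haplotypes; two columns
#' per diploid individual) together with physical and genetic-map positions
#' and a population label per haplotype.
#'
#' @slot haplotypes integer matrix of 0/1 alleles, SNPs x haplotypes.
#' @slot chrom chromosome per SNP.
#' @slot pos physical position (bp, 1-based) per SNP.
#' @slot cm genetic-map position (cM) per SNP, non-decreasing per chromosome.
#' @slot pop population label per haplotype.
#' @export
setClass("HaplotypePanel", representation(
    haplotypes = "matrix", chrom = "character", pos = "numeric",
    cm = "numeric", pop = "character"))

setValidity("HaplotypePanel", function(object) {
    msg <- character()
    h <- object@haplotypes
    if (!all(h %in% c(0L, 1L)))
        msg <- c(msg, "haplotype alleles must be 0 or 1")
    n <- nrow(h)
    if (length(object@chrom) != n || length(object@pos) != n ||
        length(object@cm) != n)
        msg <- c(msg, "chrom, pos and cm must have one entry per SNP")
    if (length(object@pop) != ncol(h))
        msg <- c(msg, "pop must have one entry per haplotype")
    for (ch in unique(object@chrom)) {
        i <- object@chrom == ch
        if (is.unsorted(object@cm[i]))
            msg <- c(msg, sprintf("map positions not non-decreasing on %s", ch))
    }
    if (length(msg)) msg else TRUE
})

#' Environmental design for genetic-offset computation
#'
#' Stores the environmental PCA (centering/scaling, loadings, scores,
#' variance explained), the retained-PC scores per population, and optionally
#' the SNP x PC gene-environment association coefficient matrix B plus, for
#' simulated designs, the generating truth.
#'
#' @slot covariates population x covariable matrix (raw scale).
#' @slot center,scale centering and scaling used for the PCA.
#' @slot loadings covariable x PC orthonormal loading matrix.
#' @slot scores population x PC score matrix (all PCs).
#' @slot varExplained proportion of variance explained per PC.
#' @slot nKeep number of retained PCs.
#' @slot B SNP x PC coefficient matrix (or NULL before fitting).
#' @slot freq SNP x population allele-frequency matrix (or NULL).
#' @slot truth list with generating truth for simulated designs.
#' @export
setClass("EnvDesign", representation(
    covariates = "matrix", center = "numeric", scale = "numeric",
    loadings = "matrix", scores = "matrix", varExplained = "numeric",
    nKeep = "numeric", B = "matrixOrNULL", freq = "matrixOrNULL",
    truth = "list"))

setValidity("EnvDesign", function(object) {
    msg <- character()
    if (ncol(object@loadings) != ncol(object@scores))
        msg <- c(msg, "loadings and scores disagree on the number of PCs")
    if (!is.null(object@B) && ncol(object@B) != object@nKeep)
        msg <- c(msg, "B column count must equal the number of retained PCs")
    if (object@nKeep < 1 || object@nKeep > ncol(object@scores))
        msg <- c(msg, "nKeep out of range")
    if (length(msg)) msg else TRUE
})
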