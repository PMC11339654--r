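#' @importFrom VariantAnnotation readVcf geno
NULL

.plFromGL <- function(gl) {
    best <- pmax(gl[[1L]], gl[[2L]], gl[[3L]])
    lapply(gl, function(g) {
        v <- round(-10 * log10(g / best))
        v[!is.finite(v) | v > 255] <- 255L
        v
    })
}

.gtString <- function(dosage) {
    out <- c("0/0", "0/1", "1/1")[dosage + 1L]
    out[is.na(dosage)] <- "./."
    out
}

#' Write a cohort fixture set to standard-format text files
#'
#' Emits a VCF 4.2 (GT, PL and, when available, DP fields; best genotype at
#' PL 0), a variant-annotation TSV (CHROM, POS, REF, ALT, AA, CLASS), a
#' population map, the genetic map (CHROM, POS, CM), and optionally an
#' environment table and a gene-interval table. All files round-trip through
#' the package readers.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param outDir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param env optional \linkS4class{EnvDesign} (writes the covariate table).
#' @param genes optional \code{GRanges} with \code{gene_name} (writes the
#'   gene-interval table, 1-based inclusive coordinates).
#' @param mapRate cM/Mb used for the genetic map.
#' @return named character vector of file paths.
#' @export
writeFixtures <- function(panel, outDir, prefix = "cohort", env = NULL,
                          genes = NULL, mapRate = 1) {
    if (!dir.exists(outDir) &&
        !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create output directory ", outDir)
    rr <- rowRanges(panel)
    chrom <- as.character(GenomicRanges::seqnames(rr))
    pos <- GenomicRanges::start(rr)
    ref <- mcols(rr)$ref; alt <- mcols(rr)$alt
    files <- c(vcf = file.path(outDir, paste0(prefix, ".vcf")),
               annotation = file.path(outDir, paste0(prefix, "_annotation.tsv")),
               populations = file.path(outDir, paste0(prefix, "_populations.tsv")),
               map = file.path(outDir, paste0(prefix, "_map.tsv")))

    pl <- .plFromGL(genoLikelihoods(panel))
    hasDP <- "dp" %in% names(assays(panel))
    gt <- apply(dosages(panel), 2, .gtString)
    plStr <- matrix(paste(pl[[1L]], pl[[2L]], pl[[3L]], sep = ","),
                    nrow(panel), ncol(panel))
    body <- matrix(paste(gt, plStr, sep = ":"), nrow(panel), ncol(panel))
    format <- "GT:PL"
    if (hasDP) {
        body <- matrix(paste(body, assay(panel, "dp"), sep = ":"),
                       nrow(panel), ncol(panel))
        format <- "GT:PL:DP"
    }
    header <- c("##fileformat=VCFv4.2",
        "##source=feralpopgen",
        sprintf("##contig=<ID=%s>", unique(chrom)),
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred-scaled genotype likelihoods\">",
        if (hasDP) "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", colnames(panel)), collapse = "\t"))
    lines <- paste(chrom, pos, ".", ref, alt, ".", "PASS", ".", format,
                   apply(body, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(c(header, lines), files["vcf"])

    utils::write.table(
        data.frame(CHROM = chrom, POS = pos, REF = ref, ALT = alt,
                   AA = ifelse(is.na(ancestralAllele(panel)), ".",
                               ancestralAllele(panel)),
                   CLASS = ifelse(is.na(variantClass(panel)), ".",
                                  variantClass(panel))),
        files["annotation"], sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
        data.frame(sample = colnames(panel), pop = popLabels(panel)),
        files["populations"], sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
        data.frame(CHROM = chrom, POS = pos, CM = pos / 1e6 * mapRate),
        files["map"], sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(env)) {
        files["environment"] <- file.path(outDir,
                                          paste0(prefix, "_environment.tsv"))
        utils::write.table(
            data.frame(pop = rownames(env@covariates), env@covariates),
            files["environment"], sep = "\t", quote = FALSE,
            row.names = FALSE)
    }
    if (!is.null(genes)) {
        files["genes"] <- file.path(outDir, paste0(prefix, "_genes.tsv"))
        utils::write.table(
            data.frame(chrom = as.character(GenomicRanges::seqnames(genes)),
                       start = GenomicRanges::start(genes),
                       end = GenomicRanges::end(genes),
                       name = mcols(genes)$gene_name),
            files["genes"], sep = "\t", quote = FALSE, row.names = FALSE)
    }
    files
}

#' Read a genotype VCF (GT + PL) into a GenotypePanel
#'
#' Parses the VCF through \code{VariantAnnotation::readVcf}; PL fields are
#' de-Phred-scaled as 10^(-PL/10) and renormalized; missing PL gives
#' uniform likelihoods. Population labels come from a two-column
#' sample/pop table, ancestral alleles and classes from the annotation TSV.
#'
#' @param vcfPath path to a VCF file.
#' @param popPath optional population-table path (columns sample, pop).
#' @param annotationPath optional annotation TSV (CHROM, POS, REF, ALT, AA,
#'   CLASS; "." = unassigned).
#' @return a \linkS4class{GenotypePanel}.
#' @export
readGenotypeVCF <- function(vcfPath, popPath = NULL, annotationPath = NULL) {
    vcf <- readVcf(vcfPath)
    rr <- SummarizedExperiment::rowRanges(vcf)
    chrom <- as.character(GenomicRanges::seqnames(rr))
    pos <- GenomicRanges::start(rr)
    ref <- as.character(rr$REF)
    alt <- vapply(rr$ALT, function(a) as.character(a)[1], character(1))
    gt <- geno(vcf)$GT
    dosage <- matrix(NA_integer_, nrow(gt), ncol(gt))
    dosage[gt %in% c("0/0", "0|0")] <- 0L
    dosage[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    dosage[gt %in% c("1/1", "1|1")] <- 2L
    gl <- NULL
    if ("PL" %in% names(geno(vcf))) {
        plRaw <- geno(vcf)$PL
        getPL <- function(k) {
            if (is.array(plRaw) && length(dim(plRaw)) == 3)
                m <- plRaw[, , k]
            else
                m <- matrix(vapply(plRaw, function(v)
                    if (length(v) >= k) as.numeric(v[k]) else NA_real_,
                    numeric(1)), nrow(gt), ncol(gt))
            m[is.na(m)] <- 0
            10^(-m / 10)
        }
        gl <- list(getPL(1), getPL(2), getPL(3))
    }
    pop <- rep("POP", ncol(gt))
    if (!is.null(popPath)) {
        pt <- utils::read.table(popPath, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
        pop <- pt$pop[match(colnames(gt), pt$sample)]
    }
    aa <- cls <- NULL
    if (!is.null(annotationPath)) {
        ann <- readAnnotationTable(annotationPath)
        key <- sprintf("%s:%d", ann$CHROM, ann$POS)
        hit <- match(sprintf("%s:%d", chrom, pos), key)
        aa <- ann$AA[hit]
        cls <- ann$CLASS[hit]
    }
    GenotypePanel(chrom = chrom, pos = pos, ref = ref, alt = alt,
                  dosage = dosage, gl = gl, pop = pop, aa = aa, class = cls,
                  sample = colnames(gt))
}

#' Read the variant-annotation table
#' @param path annotation TSV path.
#' @return data.frame with CHROM, POS, REF, ALT, AA, CLASS (NA for ".").
#' @export
readAnnotationTable <- function(path) {
    ann <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE,
                             colClasses = c(CHROM = "character"))
    ann$AA[ann$AA == "."] <- NA_character_
    ann$CLASS[ann$CLASS == "."] <- NA_character_
    ann
}

#' Read a population map (sample, pop)
#' @param path TSV path.
#' @return data.frame.
#' @export
readPopulationTable <- function(path)
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)

#' Read an environment table (pop + covariate columns)
#' @param path TSV path.
#' @return numeric matrix with population rownames.
#' @export
readEnvironmentTable <- function(path) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab[[1]]
    m
}

#' Read a genetic map (CHROM, POS, CM)
#' @param path TSV path.
#' @return data.frame.
#' @export
readGeneticMap <- function(path)
    utils::read.table(path, header = TRUE, sep = "\t",
                      colClasses = c(CHROM = "character"))

#' Read gene intervals into a GRanges
#' @param path TSV path with chrom, start, end, name (1-based inclusive).
#' @return \code{GRanges} with a \code{gene_name} column.
#' @export
readGeneIntervals <- function(path) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE,
                             colClasses = c(chrom = "character"))
    GRanges(tab$chrom, IRanges(tab$start, tab$end), gene_name = tab$name)
}

#' Generate random gene intervals for annotation exercises
#'
#' @param nChrom,chromLength chromosome layout.
#' @param nGenesPerChrom genes per chromosome.
#' @param meanLength mean gene length (bp).
#' @return \code{GRanges} with \code{gene_name}.
#' @export
generateGeneIntervals <- function(nChrom = 5, chromLength = 5e7,
                                  nGenesPerChrom = 20, meanLength = 5e4) {
    start <- unlist(lapply(seq_len(nChrom), function(ch)
        sort(sample.int(chromLength - 2 * meanLength, nGenesPerChrom))))
    len <- pmax(1000, stats::rpois(nChrom * nGenesPerChrom, meanLength))
    chrom <- rep(as.character(seq_len(nChrom)), each = nGenesPerChrom)
    GRanges(chrom, IRanges(start, width = len),
            gene_name = sprintf("GENE%s_%02d", chrom,
                                rep(seq_len(nGenesPerChrom), nChrom)))
}
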