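#' Pipeline configuration
#'
#' Declarative configuration for \code{\link{runPipeline}}: stage toggles,
#' input paths (when not simulating), the simulation configuration and the
#' analysis defaults (250-SNP jackknife blocks for f-/F-statistics, 100
#' RX/Y blocks, local-score xi = 2, MAF filter 0.01, 7 environmental PCs,
#' segregation thresholds 0.001/0.999).
#'
#' @param outDir output directory.
#' @param stages character vector of enabled stages among simulate, freqs,
#'   load, fstats, kinship, offset, scan, chrono.
#' @param sim a \linkS4class{SimConfig} for the simulate stage.
#' @param inputs named list of file paths (vcf, populations, annotation,
#'   map, environment, genes) used when simulate is disabled.
#' @param blockSize,rxyBlocks,xi,minMaf,nPcs,segLower,segUpper analysis
#'   defaults.
#' @param seed master seed recorded in all outputs.
#' @return a list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(outDir, stages = c("simulate", "freqs", "load",
                                              "fstats", "kinship", "offset",
                                              "scan", "chrono"),
                           sim = simConfig(nSites = 20000, seed = seed),
                           inputs = list(), blockSize = 250, rxyBlocks = 100,
                           xi = 2, minMaf = 0.01, nPcs = 7,
                           segLower = 0.001, segUpper = 0.999, seed = 1L) {
    cfg <- list(outDir = outDir, stages = stages, sim = sim, inputs = inputs,
                blockSize = blockSize, rxyBlocks = rxyBlocks, xi = xi,
                minMaf = minMaf, nPcs = nPcs, segLower = segLower,
                segUpper = segUpper, seed = seed)
    class(cfg) <- "PipelineConfig"
    if (!"simulate" %in% stages) {
        need <- c("vcf", "populations", "annotation")
        for (f in need)
            if (is.null(inputs[[f]]))
                stop("stage inputs require a '", f, "' path")
        for (f in names(inputs))
            if (!file.exists(inputs[[f]]))
                stop("input file for '", f, "' not found: ", inputs[[f]])
    }
    cfg
}

.configHash <- function(config) {
    tmp <- tempfile()
    on.exit(unlink(tmp))
    saveRDS(config[setdiff(names(config), "outDir")], tmp)
    unname(tools::md5sum(tmp))
}

.writeStageTable <- function(tab, path, hash, seed) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# config=%s seed=%d", hash, seed), con)
    utils::write.table(tab, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
}

#' Validate pipeline input files
#'
#' Checks the VCF for parseability and sorted positions, and the population
#' table for consistency with the VCF samples. Problems are returned as a
#' diagnostics table with levels \code{"error"} (fatal for the pipeline) and
#' \code{"warning"}.
#'
#' @param paths named list with at least \code{vcf}; optionally
#'   \code{populations} and \code{map}.
#' @return data.frame with columns \code{level}, \code{message}.
#' @export
validateInputs <- function(paths) {
    diags <- data.frame(level = character(0), message = character(0))
    note <- function(level, message)
        rbind(diags, data.frame(level = level, message = message))
    for (f in names(paths))
        if (!file.exists(paths[[f]]))
            diags <- note("error", sprintf("missing %s file: %s", f,
                                           paths[[f]]))
    if (nrow(diags)) return(diags)
    vcf <- tryCatch(readVcf(paths$vcf), error = function(e) e)
    if (inherits(vcf, "error"))
        return(note("error", sprintf("malformed VCF %s: %s", paths$vcf,
                                     conditionMessage(vcf))))
    rr <- SummarizedExperiment::rowRanges(vcf)
    chrom <- as.character(GenomicRanges::seqnames(rr))
    pos <- GenomicRanges::start(rr)
    for (ch in unique(chrom))
        if (is.unsorted(pos[chrom == ch]))
            diags <- note("error",
                          sprintf("VCF positions unsorted on chromosome %s", ch))
    if (!is.null(paths$populations)) {
        pt <- readPopulationTable(paths$populations)
        absent <- setdiff(pt$sample, colnames(geno(vcf)$GT))
        if (length(absent))
            diags <- note("warning",
                          sprintf("population table names absent sample(s): %s",
                                  paste(absent, collapse = ", ")))
    }
    if (!is.null(paths$map)) {
        mp <- readGeneticMap(paths$map)
        for (ch in unique(mp$CHROM))
            if (is.unsorted(mp$CM[mp$CHROM == ch]))
                diags <- note("error",
                              sprintf("genetic map not monotone on chromosome %s",
                                      ch))
    }
    diags
}

#' Run the simulate/estimate/report pipeline
#'
#' Executes the enabled stages in dependency order on either a simulated
#' cohort or user-supplied inputs, writing one TSV per result table (each
#' stamped with the configuration hash and seed) plus a per-stage log of
#' site counts and exclusions. Rerunning with an identical configuration
#' reproduces the tables byte for byte.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return invisible list with the result objects, the per-stage log and the
#'   written file paths.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    if (!dir.exists(config$outDir))
        dir.create(config$outDir, recursive = TRUE)
    hash <- .configHash(config)
    seed <- config$seed
    set.seed(seed)
    log <- list()
    out <- list()
    files <- character(0)
    emit <- function(tab, name) {
        path <- file.path(config$outDir, paste0(name, ".tsv"))
        .writeStageTable(tab, path, hash, seed)
        files[[name]] <<- path
    }
    stage <- function(name, expr) {
        if (!name %in% config$stages) return(invisible(NULL))
        res <- tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
        res
    }

    panel <- NULL; truth <- NULL
    if ("simulate" %in% config$stages) {
        sim <- stage("simulate", simulateCohort(config$sim))
        truth <- sim$truth
        gpanel <- emitSequencingData(sim$panel, config$sim,
                                     class = truth@classes)
        outCols <- which(popLabels(gpanel) == "OUT")[1:4]
        aa <- polarizeSites(dosages(gpanel)[, outCols, drop = FALSE],
                            ref = mcols(rowRanges(gpanel))$ref,
                            alt = mcols(rowRanges(gpanel))$alt)
        mcols(rowRanges(gpanel))$aa <- aa
        panel <- gpanel
        log$simulate <- list(nSites = nrow(panel),
                             nPolarized = sum(!is.na(aa)),
                             pops = table(popLabels(panel)))
        fx <- writeFixtures(panel, config$outDir, prefix = "cohort",
                            mapRate = config$sim@mapRate)
        files <- c(files, fx)
    } else {
        diags <- validateInputs(config$inputs)
        if (any(diags$level == "error"))
            stop("input validation failed: ",
                 paste(diags$message[diags$level == "error"],
                       collapse = "; "))
        panel <- readGenotypeVCF(config$inputs$vcf,
                                 config$inputs$populations,
                                 config$inputs$annotation)
        log$read <- list(nSites = nrow(panel), nInd = ncol(panel))
    }

    freqs <- NULL
    if ("freqs" %in% config$stages) {
        freqs <- stage("freqs", populationFrequencies(panel))
        counts <- countSegregatingFixed(freqs, config$segLower,
                                        config$segUpper)
        pops <- colnames(freqs$af)
        het <- vapply(pops, function(pp)
            expectedHeterozygosity(freqs$af[, pp], freqs$n[[pp]]), numeric(1))
        counts$expectedHet <- het
        emit(counts, "diversity")
        sfsTab <- do.call(rbind, lapply(pops, function(pp) {
            sf <- probabilisticSFS(panel, pp)
            data.frame(pop = pp, k = as.integer(names(sf$sfs)),
                       probability = sf$sfs, nSites = sf$nSites)
        }))
        emit(sfsTab, "sfs")
        out$diversity <- counts; out$sfs <- sfsTab
        log$freqs <- list(nSites = nrow(freqs$af),
                          nConverged = sum(freqs$converged))
    }

    if ("load" %in% config$stages && !is.null(freqs)) {
        ratio <- stage("load", nsSHetRatio(panel))
        loadTabs <- do.call(rbind, lapply(
            c("ns_deleterious", "lof"), function(cl)
                cbind(class = cl, maskedRealizedLoad(panel, cl))))
        emit(data.frame(individual = names(ratio), nsS = ratio), "ns_s_ratio")
        emit(loadTabs, "load")
        dx <- freqs$derived[, "TARGET"]; dy <- freqs$derived[, "SRC2"]
        cls <- variantClass(panel)
        rx <- do.call(rbind, lapply(c("ns_deleterious", "lof"), function(cl) {
            r <- rxy(dx, dy, which(cls == cl), which(cls == "intergenic"),
                     nBlocks = config$rxyBlocks)
            data.frame(class = cl, raw = r$raw, standardized = r$standardized,
                       ci_lower = r$ci[1], ci_upper = r$ci[2])
        }))
        emit(rx, "rxy")
        out$nsS <- ratio; out$load <- loadTabs; out$rxy <- rx
        log$load <- list(classes = table(cls))
    }

    if ("fstats" %in% config$stages) {
        wc <- stage("fstats", wcFStatistics(panel, config$blockSize))
        emit(wc$global, "fstats_global")
        emit(wc$pairwise, "fstats_pairwise")
        f3 <- fStat(panel, "f3", c("TARGET", "SRC1", "SRC2"),
                    config$blockSize)
        emit(f3, "f3_admixture")
        out$wc <- wc; out$f3 <- f3
        if (all(c("SIS1", "OUT") %in% popLabels(panel))) {
            fr <- f4Ratio(panel, c("SIS1", "OUT", "TARGET", "SRC2"),
                          c("SIS1", "OUT", "SRC1", "SRC2"),
                          config$blockSize)
            emit(fr, "f4_ratio")
            out$f4Ratio <- fr
        }
        log$fstats <- list(nSnpsUsed = wc$nSnpsUsed)
    }

    if ("kinship" %in% config$stages) {
        tgt <- panel[, popLabels(panel) == "TARGET"]
        km <- stage("kinship", kinshipMatrix(tgt, minSnps = 100))
        pairs <- which(upper.tri(km), arr.ind = TRUE)
        kin <- data.frame(indA = colnames(km)[pairs[, 1]],
                          indB = colnames(km)[pairs[, 2]],
                          phi = km[pairs],
                          degree = classifyDegree(km[pairs]))
        emit(kin, "kinship")
        out$kinship <- kin
    }

    if ("offset" %in% config$stages) {
        env <- stage("offset", generateEnvironment(nPops = 24,
                                                   nPcs = config$nPcs,
                                                   nSnps = 5000,
                                                   seed = seed))
        env <- estimateGeaCoefficients(env)
        sc <- envScores(env)
        ref <- sc[1, ]
        go <- data.frame(pop = rownames(sc),
                         go = apply(sc, 1, function(e)
                             geneticOffset(env@B, e, ref)),
                         delta = apply(sc, 1, function(e)
                             environmentalDistance(e, ref)))
        emit(go, "genetic_offset")
        out$go <- go
    }

    if ("scan" %in% config$stages) {
        hap <- stage("scan", simulateLinkedHaplotypes(
            nSnp = 400, ne = 40, generations = 30, sweepS = 0.5,
            pop = "TARGET"))
        scan <- ihsScan(hap, minMaf = config$minMaf)
        p <- pTransform(scan$ihs, "ihs")
        ls <- localScore(p, pos = scan$pos, xi = config$xi, nPerm = 200)
        genes <- generateGeneIntervals(nChrom = 1,
                                       chromLength = max(hap@pos))
        win <- annotateRegions(ls$windows, genes, chrom = "1")
        emit(win, "scan_windows")
        out$scan <- list(ihs = scan, windows = win,
                         threshold = ls$threshold)
        log$scan <- list(nSnps = nrow(scan), nWindows = nrow(ls$windows))
    }

    if ("chrono" %in% config$stages) {
        chron <- stage("chrono", data.frame(
            quantity = c("admixture_year", "implied_generation_time",
                         "hbd_classes"),
            value = c(generationsToYear(config$sim@tBottleneck, 6, 1992),
                      impliedGenerationTime(1992, 1871,
                                            config$sim@tBottleneck),
                      length(hbdRateGrid()))))
        emit(chron, "chronology")
        out$chronology <- chron
    }

    logPath <- file.path(config$outDir, "pipeline_log.txt")
    writeLines(c(sprintf("config=%s seed=%d", hash, seed),
                 utils::capture.output(utils::str(log))), logPath)
    invisible(list(results = out, log = log, files = files, hash = hash))
}
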