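test_that("invalid configurations are rejected with the violated invariant named", {
    expect_error(simConfig(admixtureFraction = 1.5), "admixtureFraction")
    expect_error(simConfig(nFounders = 1), "nFounders")
    expect_error(simConfig(classProportions = c(intergenic = 0.5,
                                                synonymous = 0.1,
                                                ns_tolerated = 0.1,
                                                ns_deleterious = 0.1,
                                                lof = 0.1)),
                 "sum to 1")
    expect_error(simConfig(selectionS = c(intergenic = 0, synonymous = 0,
                                          ns_tolerated = 0,
                                          ns_deleterious = 0.1, lof = 0)),
                 "deleterious")
})

test_that("neutral single-source target is indistinguishable from its source", {
    # no selection, all founder ancestry from source 1, no founder bottleneck
    fst <- vapply(1:5, function(r) {
        cfg <- simConfig(nSites = 2000, nFounders = 500, tBottleneck = 5,
                         admixtureFraction = 1, expansionSize = 500,
                         selectionS = c(intergenic = 0, synonymous = 0,
                                        ns_tolerated = 0, ns_deleterious = 0,
                                        lof = 0),
                         nSampled = 8, seed = 100 + r)
        sim <- simulateCohort(cfg)
        gp <- haplotypesToGenotypes(sim$panel)
        wc <- wcFStatistics(gp[, popLabels(gp) %in% c("TARGET", "SRC1")])
        wc$pairwise$estimate
    }, numeric(1))
    # mean FST across replicates at sampling-noise level, far below the
    # source-source differentiation
    expect_lt(abs(mean(fst)), 0.01)
})

test_that("the bottleneck flattens the target SFS relative to controls", {
    cfg <- simConfig(nSites = 6000, seed = 21)
    sim <- simulateCohort(cfg)
    gp <- haplotypesToGenotypes(sim$panel, aa = "A")
    singletonProp <- function(pop) {
        d <- dosages(gp)[, popLabels(gp) == pop]
        k <- rowSums(d)
        seg <- k > 0 & k < ncol(d) * 2
        sum(k == 1) / sum(seg)
    }
    expect_lt(singletonProp("TARGET"), singletonProp("SRC1"))
    expect_lt(singletonProp("TARGET"), singletonProp("SRC2"))
})

test_that("neutral drift loses heterozygosity at the closed-form rate", {
    set.seed(42)
    N <- 50; t <- 20; p0 <- 0.5
    nRep <- 4000  # independent sites stand in for replicate runs
    p <- driftFrequencies(rep(p0, nRep), N, t)
    expected <- 2 * p0 * (1 - p0) * (1 - 1 / (2 * N))^t
    observed <- mean(2 * p * (1 - p))
    expect_equal(observed, expected, tolerance = 0.03)
})

test_that("per-class selection leaves deleterious classes rarer than neutral ones", {
    cfg <- simConfig(nSites = 8000, seed = 33)
    sim <- simulateCohort(cfg)
    fr <- sim$truth@trueFreq[, "SRC1"]
    cls <- sim$truth@classes
    expect_lt(mean(fr[cls == "lof"]), mean(fr[cls == "intergenic"]))
    expect_lt(mean(fr[cls == "ns_deleterious"]), mean(fr[cls == "intergenic"]))
})

test_that("noiseless sequencing reproduces the true genotypes", {
    cfg <- simConfig(nSites = 400, nSampled = 4, errorRate = 0,
                     meanDepth = 30, seed = 5)
    sim <- simulateCohort(cfg)
    gp <- emitSequencingData(sim$panel, cfg)
    h <- haplotypes(sim$panel)
    idx <- seq(1, ncol(h), by = 2)
    truth <- h[, idx] + h[, idx + 1]
    called <- dosages(gp)
    covered <- !is.na(called)
    expect_gt(mean(covered), 0.9)
    expect_equal(called[covered], truth[covered])
})

test_that("zero-depth sites are uninformative and flagged missing", {
    rl <- readLikelihoods(0, 0, 0.01)
    expect_equal(unlist(rl$pl), c(0L, 0L, 0L), ignore_attr = TRUE)
    cfg <- simConfig(nSites = 300, nSampled = 4, meanDepth = 1, seed = 8)
    sim <- simulateCohort(cfg)
    gp <- emitSequencingData(sim$panel, cfg)
    dp <- SummarizedExperiment::assay(gp, "dp")
    expect_true(all(is.na(dosages(gp)[dp == 0])))
    gl <- genoLikelihoods(gp)
    zero <- dp == 0
    expect_true(all(gl[[1]][zero] == gl[[2]][zero] &
                    gl[[2]][zero] == gl[[3]][zero]))
})

test_that("PL values match the hand-computed binomial read model", {
    # one heterozygote, 10 reads split 5/5, error 0.01
    rl <- readLikelihoods(5, 10, 0.01)
    lik <- dbinom(5, 10, c(0.01, 0.5, 0.99))
    plHand <- round(-10 * log10(lik / max(lik)))
    expect_equal(unlist(rl$pl), plHand, ignore_attr = TRUE)
    expect_equal(rl$pl[[2]], 0)
    # a clean hom-alt pull
    rl2 <- readLikelihoods(12, 12, 0.001)
    expect_equal(rl2$pl[[3]], 0)
    expect_gt(rl2$pl[[1]], rl2$pl[[2]])
})

test_that("environment generation retains recoverable truth and honours edge cases", {
    expect_error(generateEnvironment(effectScale = -1), "effectScale")
    # strong single-PC effect: frequency/environment correlation sign
    # matches the true coefficient sign at almost all affected SNPs
    env <- generateEnvironment(nPops = 30, nPcs = 1, effectScale = 0.08,
                               nSnps = 2000, seed = 4, noiseSd = 0.01)
    tr <- env@truth
    s <- envScores(env)[, 1]
    signs <- vapply(tr$affected, function(i)
        sign(cor(env@freq[i, ], s)) == sign(tr$B[i, 1]), logical(1))
    expect_gt(mean(signs), 0.95)
    # no-association case: GO between two environments is noise-level
    env0 <- generateEnvironment(nPops = 20, nPcs = 3, effectScale = 0,
                                nSnps = 1000, seed = 6)
    env0 <- estimateGeaCoefficients(env0)
    sc <- envScores(env0)
    goNull <- geneticOffset(geaCoefficients(env0), sc[1, ], sc[2, ])
    envS <- generateEnvironment(nPops = 20, nPcs = 3, effectScale = 0.08,
                                nSnps = 1000, seed = 6)
    envS <- estimateGeaCoefficients(envS)
    scS <- envScores(envS)
    goStrong <- geneticOffset(geaCoefficients(envS), scS[1, ], scS[2, ])
    expect_lt(goNull, goStrong / 5)
    # identical environments give exactly zero offset
    expect_equal(geneticOffset(geaCoefficients(envS), scS[1, ], scS[1, ]), 0)
})

test_that("fixtures are bit-identical under a fixed seed and round-trip", {
    make <- function(dir) {
        cfg <- simConfig(nSites = 250, nSampled = 4, seed = 77)
        sim <- simulateCohort(cfg)
        gp <- emitSequencingData(sim$panel, cfg, class = sim$truth@classes)
        writeFixtures(gp, dir, mapRate = cfg@mapRate)
    }
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    f1 <- make(d1); f2 <- make(d2)
    for (k in names(f1))
        expect_identical(readLines(f1[[k]]), readLines(f2[[k]]), label = k)

    gp2 <- readGenotypeVCF(f1["vcf"], f1["populations"], f1["annotation"])
    cfg <- simConfig(nSites = 250, nSampled = 4, seed = 77)
    sim <- simulateCohort(cfg)
    gp <- emitSequencingData(sim$panel, cfg, class = sim$truth@classes)
    expect_identical(dosages(gp), dosages(gp2))
    expect_identical(popLabels(gp), popLabels(gp2))
    expect_identical(variantClass(gp), variantClass(gp2))

    # every written PL triple names a best genotype with PL 0
    vcfLines <- readLines(f1[["vcf"]])
    body <- vcfLines[!startsWith(vcfLines, "#")]
    plField <- regmatches(body, regexpr("[0-9]+,[0-9]+,[0-9]+", body))
    expect_true(all(vapply(strsplit(plField, ","),
                           function(x) min(as.integer(x)) == 0, logical(1))))

    # annotation class counts match the simulated truth exactly
    ann <- readAnnotationTable(f1["annotation"])
    expect_equal(table(ann$CLASS)[names(table(sim$truth@classes))],
                 table(sim$truth@classes), ignore_attr = TRUE)
})
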