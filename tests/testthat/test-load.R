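test_that("NS/S heterozygosity ratio counts as expected", {
    cls <- c(rep("ns_deleterious", 6), rep("synonymous", 3), "intergenic")
    # individual 1: het at all NS and all S -> 6/3 = 2
    # individual 2: het at 2 NS and 2 S -> 1
    dos <- cbind(c(rep(1L, 9), 0L),
                 c(1L, 1L, 0L, 0L, 0L, 0L, 1L, 1L, 0L, 2L))
    gp <- certainPanel(dos, pop = "ISL", class = cls)
    r <- nsSHetRatio(gp)
    expect_equal(unname(r), c(2, 1))
    # zero synonymous heterozygotes flagged
    dos2 <- cbind(c(rep(1L, 6), 0L, 0L, 0L, 0L))
    gp2 <- certainPanel(dos2, pop = "ISL", class = cls)
    expect_warning(r2 <- nsSHetRatio(gp2), "zero synonymous")
    expect_true(is.na(r2[1]))
})

test_that("NS/S ratio with soft genotypes equals the summed GP expectation", {
    gp <- softPanel(nSites = 10, nInd = 2, seed = 17)
    cls <- c(rep("ns_deleterious", 5), rep("synonymous", 5))
    SummarizedExperiment::rowRanges(gp)$class <- cls
    gpp <- genoProbabilities(gp)
    hand <- colSums(gpp[[2]][1:5, ]) / colSums(gpp[[2]][6:10, ])
    expect_equal(unname(nsSHetRatio(gp)), unname(hand))
})

test_that("masked and realized load cover the limiting and mixed cases", {
    cls <- rep("lof", 10)
    allHet <- certainPanel(matrix(1L, 10, 1), pop = "ISL", aa = "A",
                           class = cls)
    r <- maskedRealizedLoad(allHet, "lof")
    expect_equal(r$masked, 1); expect_equal(r$realized, 0)
    allHom <- certainPanel(matrix(2L, 10, 1), pop = "ISL", aa = "A",
                           class = cls)
    r <- maskedRealizedLoad(allHom, "lof")
    expect_equal(r$masked, 0); expect_equal(r$realized, 1)
    # 2 het / 3 hom-derived / 5 hom-ancestral
    mixed <- certainPanel(matrix(c(1L, 1L, 2L, 2L, 2L, 0L, 0L, 0L, 0L, 0L),
                                 10, 1), pop = "ISL", aa = "A", class = cls)
    r <- maskedRealizedLoad(mixed, "lof")
    expect_equal(r$masked, 0.2); expect_equal(r$realized, 0.3)
    expect_equal(r$homAncestral, 0.5)
    # polarization flips hom-derived when the ancestral allele is alt
    flipped <- certainPanel(matrix(c(1L, 1L, 0L, 0L, 0L, 2L, 2L, 2L, 2L, 2L),
                                   10, 1), pop = "ISL", aa = "C", class = cls)
    r <- maskedRealizedLoad(flipped, "lof")
    expect_equal(r$realized, 0.3)
})

test_that("masked + realized + hom-ancestral sums to one with soft GPs", {
    gp <- softPanel(nSites = 30, nInd = 5, seed = 23)
    SummarizedExperiment::rowRanges(gp)$class <- "ns_deleterious"
    r <- maskedRealizedLoad(gp, "ns_deleterious")
    expect_true(all(abs(r$masked + r$realized + r$homAncestral - 1) < 1e-9))
})

test_that("RX/Y reproduces hand computations and symmetry limits", {
    # symmetric frequencies give exactly 1
    f <- runif(50, 0.1, 0.9)
    r <- rxy(f, f, seq_along(f), nBlocks = 10)
    expect_equal(r$raw, 1)
    # 3-site toy: sum fx(1-fy) = 0.18+0.25+0.045 = 0.475,
    #             sum fy(1-fx) = 0.08+0.25+0.095 = 0.425
    fx <- c(0.2, 0.5, 0.9); fy <- c(0.1, 0.5, 0.95)
    r <- rxy(fx, fy, 1:3, nBlocks = 3)
    expect_equal(r$raw, 0.475 / 0.425, tolerance = 1e-12)
    # identical class and normalizer site sets standardize to exactly 1
    set.seed(5)
    fx <- runif(200); fy <- runif(200)
    r <- rxy(fx, fy, 1:200, 1:200, nBlocks = 50)
    expect_equal(r$standardized, 1)
    # the jackknife CI contains the point estimate
    r2 <- rxy(fx, fy, 1:100, 101:200, nBlocks = 20)
    expect_true(r2$ci[1] <= r2$standardized && r2$standardized <= r2$ci[2])
})

test_that("RX/Y exceeds one when purifying selection is relaxed in X", {
    # X drifts neutrally, Y keeps purifying selection on the class
    set.seed(61)
    hits <- vapply(1:10, function(r) {
        p0 <- rbeta(600, 0.4, 0.8) * 0.5
        px <- driftFrequencies(p0, 200, 50, s = 0, h = 0.5)
        py <- driftFrequencies(p0, 200, 50, s = -0.05, h = 0.3)
        pn <- driftFrequencies(p0, 200, 50, s = 0, h = 0.5)
        pn2 <- driftFrequencies(p0, 200, 50, s = 0, h = 0.5)
        rxy(c(px, pn), c(py, pn2), 1:600, 601:1200, nBlocks = 30)$standardized > 1
    }, logical(1))
    expect_gt(mean(hits), 0.5)
})

test_that("breeding-value prediction sums dosage times effect", {
    dos <- matrix(c(0L, 1L, 2L), 3, 1)
    gp <- certainPanel(dos, pop = "ISL")
    eff <- data.frame(chrom = "1", pos = c(1000, 2000, 3000),
                      allele = "C", effect = c(0.1, -0.2, 0.3))
    out <- predictHeight(gp, eff)
    expect_equal(unname(out$values), 0.4)
    expect_equal(out$nUsed, 3); expect_equal(out$nDropped, 0)
    # zero effects and the single-SNP case
    eff0 <- transform(eff, effect = 0)
    expect_equal(unname(predictHeight(gp, eff0)$values), 0)
    one <- predictHeight(certainPanel(matrix(2L, 1, 1), pop = "ISL"),
                         data.frame(chrom = "1", pos = 1000, allele = "C",
                                    effect = 1.5))
    expect_equal(unname(one$values), 3)
    # effect reported on the ref allele flips the dosage; mismatches drop
    eff2 <- data.frame(chrom = "1", pos = c(1000, 2000, 3000),
                       allele = c("A", "G", "C"), effect = c(1, 1, 1))
    out2 <- predictHeight(gp, eff2)
    expect_equal(out2$nDropped, 1)
    expect_equal(unname(out2$values), (2 - 0) + 2)
})
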