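test_that("pairwise FST is one for fixed differences", {
    dos <- cbind(matrix(0L, 60, 6), matrix(2L, 60, 6))
    gp <- certainPanel(dos, pop = rep(c("A", "B"), each = 6))
    wc <- wcFStatistics(gp, blockSize = 20)
    expect_equal(wc$pairwise$estimate, 1)
    expect_equal(wc$global$estimate[wc$global$stat == "FST"], 1)
})

test_that("single-population FIS matches the hand-computed variance components", {
    # genotype counts (AA, Aa, aa) = (4, 2, 4): n = 10, p = 0.5, Hobs = 0.2
    dos <- matrix(rep(c(rep(0L, 4), rep(1L, 2), rep(2L, 4)), 30), 30, 10,
                  byrow = TRUE)
    # a second population so the estimator runs; make it identical
    gp <- certainPanel(cbind(dos, dos), pop = rep(c("A", "B"), each = 10))
    wc <- wcFStatistics(gp, blockSize = 10)
    n <- 10; p <- 0.5; h <- 0.2
    b <- n / (n - 1) * (p * (1 - p) - (2 * n - 1) / (4 * n) * h)
    cc <- h / 2
    fisHand <- 1 - cc / (b + cc)
    expect_equal(wc$perPop$FIS, rep(fisHand, 2), tolerance = 1e-12)
})

test_that("random splits of one panmictic pool give FST near zero", {
    set.seed(19)
    p <- runif(400, 0.1, 0.9)
    dos <- matrix(rbinom(400 * 20, 2, p), 400, 20)
    fst <- vapply(1:50, function(r) {
        lab <- sample(rep(c("A", "B"), each = 10))
        gp <- certainPanel(dos, pop = lab)
        wcFStatistics(gp, blockSize = 100)$pairwise$estimate
    }, numeric(1))
    expect_lt(abs(mean(fst)), 0.005)
})

test_that("jackknife SE vanishes when per-block estimates are constant", {
    blockDos <- cbind(matrix(0L, 10, 6), matrix(2L, 10, 6))
    dos <- do.call(rbind, rep(list(blockDos), 5))  # 5 identical blocks
    gp <- certainPanel(dos, pop = rep(c("A", "B"), each = 6))
    wc <- wcFStatistics(gp, blockSize = 10)
    expect_equal(wc$pairwise$se, 0)
})

test_that("f4 is antisymmetric and f2 of a population with itself is near zero", {
    set.seed(29)
    p <- matrix(runif(600, 0.1, 0.9), 300, 2)
    freqs <- cbind(A = p[, 1], B = p[, 1], C = p[, 2], D = runif(300))
    gp <- freqPanel(freqs, nInd = 10, seed = 30)
    f4a <- fStat(gp, "f4", c("A", "B", "C", "D"), blockSize = 100)
    f4b <- fStat(gp, "f4", c("A", "B", "D", "C"), blockSize = 100)
    expect_equal(f4a$estimate, -f4b$estimate)
    # A and B are independent samples from identical frequencies
    f2 <- fStat(gp, "f2", c("A", "B"), blockSize = 100)
    expect_lt(abs(f2$estimate), 3 * f2$se + 0.002)
})

test_that("f3 flags a fresh 50/50 admixture and not a drifted copy", {
    set.seed(37)
    nSnp <- 4000
    pB <- runif(nSnp, 0.05, 0.95)
    pC <- runif(nSnp, 0.05, 0.95)
    # target founded one generation ago as a 50/50 mix, minimal drift
    pA <- driftFrequencies((pB + pC) / 2, size = 5000, generations = 1)
    gp <- freqPanel(cbind(A = pA, B = pB, C = pC), nInd = 12, seed = 38)
    f3 <- fStat(gp, "f3", c("A", "B", "C"))
    expect_lt(f3$z, -1.65)
    expect_true(f3$admixed)
    # drift-only: A is a drifted copy of B
    pA2 <- driftFrequencies(pB, size = 100, generations = 30)
    gp2 <- freqPanel(cbind(A = pA2, B = pB, C = pC), nInd = 12, seed = 39)
    f3d <- fStat(gp2, "f3", c("A", "B", "C"))
    expect_gt(f3d$estimate, -2 * f3d$se)
})

test_that("the F4-ratio recovers admixture proportions", {
    # pure-source target: alpha = 1 within jackknife noise
    cfg <- simConfig(nSites = 6000, admixtureFraction = 1, nFounders = 100,
                     expansionSize = 500, seed = 41)
    sim <- simulateCohort(cfg)
    gp <- haplotypesToGenotypes(sim$panel)
    fr <- f4Ratio(gp, c("SIS1", "OUT", "TARGET", "SRC2"),
                  c("SIS1", "OUT", "SRC1", "SRC2"))
    expect_lt(abs(fr$alpha - 1), 0.15)
    expect_true(fr$ci_lower <= fr$alpha && fr$alpha <= fr$ci_upper)
    # alpha = 0 null
    cfg0 <- simConfig(nSites = 6000, admixtureFraction = 0, nFounders = 100,
                      expansionSize = 500, seed = 43)
    sim0 <- simulateCohort(cfg0)
    gp0 <- haplotypesToGenotypes(sim0$panel)
    fr0 <- f4Ratio(gp0, c("SIS1", "OUT", "TARGET", "SRC2"),
                   c("SIS1", "OUT", "SRC1", "SRC2"))
    expect_lt(abs(fr0$alpha), 0.15)
    # the study design: alpha = 0.75 recovered (CI-coverage over replicates
    # is exercised by the acceptance suite)
    cfg75 <- simConfig(nSites = 8000, seed = 45)
    sim75 <- simulateCohort(cfg75)
    gp75 <- haplotypesToGenotypes(sim75$panel)
    fr75 <- f4Ratio(gp75, c("SIS1", "OUT", "TARGET", "SRC2"),
                    c("SIS1", "OUT", "SRC1", "SRC2"))
    expect_lt(abs(fr75$alpha - 0.75), 0.2)
})

test_that("allele-sharing distances follow the documented convention", {
    # toy pair over 4 sites: AA/AA, AA/Aa, AA/aa, Aa/Aa
    dos <- cbind(c(0L, 0L, 0L, 1L), c(0L, 1L, 2L, 1L))
    gp <- certainPanel(dos, pop = "P")
    asd <- asdMatrix(gp)
    expect_equal(asd[1, 2], 0.5)
    expect_equal(diag(asd), c(0, 0), ignore_attr = TRUE)
    # identical genotypes and opposite homozygotes
    gp2 <- certainPanel(cbind(c(0L, 2L), c(0L, 2L), c(2L, 0L)), pop = "P")
    asd2 <- asdMatrix(gp2)
    expect_equal(asd2[1, 2], 0)
    expect_equal(asd2[1, 3], 1)
})

test_that("KING-robust kinship recovers duplicates, parent-offspring and unrelated", {
    set.seed(47)
    p <- runif(3000, 0.1, 0.9)
    mum <- rbinom(3000, 2, p)
    dad <- rbinom(3000, 2, p)
    passAllele <- function(g) ifelse(g == 1L, rbinom(3000, 1, 0.5), g / 2)
    kid <- passAllele(mum) + passAllele(dad)
    other <- rbinom(3000, 2, p)
    dos <- cbind(mum, kid, other, mum)
    gp <- certainPanel(dos, pop = "ISL")
    expect_equal(kinship(gp, 1, 4), 0.5)           # duplicated individual
    phiPO <- kinship(gp, 1, 2)
    expect_gt(phiPO, 0.177); expect_lt(phiPO, 0.354)
    expect_lt(abs(kinship(gp, 1, 3)), 0.05)        # unrelated pair
    km <- kinshipMatrix(gp)
    expect_equal(km[1, 2], km[2, 1])
})

test_that("relationship degrees partition the kinship line at powers of two", {
    expect_equal(classifyDegree(0.144), "second")
    expect_equal(classifyDegree(0.25), "first")
    expect_equal(classifyDegree(0.01), "unrelated")
    expect_equal(classifyDegree(0.5), "duplicate")
    # closed lower boundaries
    expect_equal(classifyDegree(2^(-5/2)), "first")
    expect_equal(classifyDegree(2^(-7/2)), "second")
    expect_equal(classifyDegree(2^(-9/2)), "third")
    # partition: every finite phi maps to exactly one class
    phis <- seq(-0.2, 0.6, by = 0.013)
    cls <- classifyDegree(phis)
    expect_false(anyNA(cls))
    expect_equal(length(cls), length(phis))
    bounds <- kinshipDegreeBounds()
    expect_equal(unname(round(bounds[c("second", "duplicate")], 4)),
                 c(0.0884, 0.3536))
})
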