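test_that("EHH is one for identical haplotypes and decays monotonically", {
    h <- matrix(rep(c(0L, 1L, 0L, 1L, 1L), 6), 5, 6)  # all columns identical
    p <- hapPanel(h)
    st <- ehhStats(p, 2)  # focal allele 1 carried by every haplotype
    expect_true(all(st$curve1$ehh == 1))
    # iHH spans the whole map
    expect_equal(st$ihh1, max(p@cm) - min(p@cm))
    # focal EHH is 1 by definition, and curves never increase outward
    set.seed(61)
    hr <- matrix(rbinom(40 * 20, 1, 0.5), 40, 20)
    hr[20, ] <- rep(c(0L, 1L), each = 10)
    pr <- hapPanel(hr)
    str <- ehhStats(pr, 20, cutoff = 0)
    for (cv in list(str$curve0, str$curve1)) {
        expect_equal(cv$ehh[cv$index == 20], 1)
        right <- cv$ehh[cv$index >= 20]
        left <- rev(cv$ehh[cv$index <= 20])
        expect_true(all(diff(right) <= 1e-12))
        expect_true(all(diff(left) <= 1e-12))
    }
})

test_that("EHH values equal brute-force pairwise identity counting", {
    set.seed(63)
    # small panel with recombinant haplotypes
    h <- matrix(rbinom(15 * 8, 1, 0.5), 15, 8)
    p <- hapPanel(h)
    focal <- 8
    for (a in 0:1) {
        carriers <- which(h[focal, ] == a)
        if (length(carriers) < 2) next
        st <- ehhStats(p, focal, cutoff = 0)
        curve <- st[[paste0("curve", a)]]
        for (i in seq_len(nrow(curve))) {
            expect_equal(curve$ehh[i],
                         bruteEHH(h, carriers, focal, curve$index[i]),
                         tolerance = 1e-12)
        }
    }
    # an allele with fewer than two carriers has no defined curve
    h2 <- h; h2[focal, ] <- c(1L, rep(0L, 7))
    st2 <- ehhStats(hapPanel(h2), focal)
    expect_true(is.na(st2$ihh1))
})

test_that("iHS filters by MAF, is label-symmetric and standardizes", {
    set.seed(65)
    hap <- simulateLinkedHaplotypes(nSnp = 120, ne = 40, generations = 25)
    freq <- rowMeans(haplotypes(hap))
    sc <- ihsScan(hap, minMaf = 0.01)
    expect_true(all(pmin(sc$freq1, 1 - sc$freq1) > 0.01))
    rare <- which(pmin(freq, 1 - freq) <= 0.01)
    expect_false(any(sc$index %in% rare))
    # standardized scores have mean 0 and unit SD genome-wide
    expect_lt(abs(mean(sc$ihs, na.rm = TRUE)), 1e-10)
    expect_equal(sd(sc$ihs, na.rm = TRUE), 1, tolerance = 1e-10)
    # relabeling alleles at every SNP flips the sign of the raw statistic
    hFlip <- 1L - haplotypes(hap)
    hapF <- HaplotypePanel(hFlip, chrom = hap@chrom, pos = hap@pos,
                           cm = hap@cm, pop = popLabels(hap))
    scF <- ihsScan(hapF, minMaf = 0.01)
    expect_equal(scF$uniHS, -sc$uniHS, tolerance = 1e-10)
})

test_that("Rsb is zero on self-comparison and antisymmetric", {
    set.seed(67)
    hap <- simulateLinkedHaplotypes(nSnp = 80, ne = 30, generations = 20)
    hapY <- simulateLinkedHaplotypes(nSnp = 80, ne = 30, generations = 20)
    hapY@chrom <- hap@chrom; hapY@pos <- hap@pos; hapY@cm <- hap@cm
    self <- rsbScan(hap, hap)
    expect_true(all(abs(self$unRsb) < 1e-12))
    ab <- rsbScan(hap, hapY)
    ba <- rsbScan(hapY, hap)
    expect_equal(ab$unRsb, -ba$unRsb, tolerance = 1e-12)
})

test_that("Rsb localizes a simulated sweep near the selected site", {
    # hard sweep (2-4 founder copies) on a 100 cM chromosome; at this SNP
    # density (0.5 Mb spacing) localization is checked at 10 Mb = 10 cM,
    # the scale of the expected sweep footprint
    set.seed(71)
    hits <- vapply(1:5, function(r) {
        swept <- simulateLinkedHaplotypes(nSnp = 200, ne = 150,
                                          generations = 15, lengthCm = 100,
                                          sweepS = 1.2, sweepCopies = 4,
                                          mutationRate = 2e-3, pop = "X")
        neutral <- simulateLinkedHaplotypes(nSnp = 200, ne = 150,
                                            generations = 15, lengthCm = 100,
                                            mutationRate = 2e-3, pop = "Y")
        neutral@chrom <- swept@chrom
        neutral@pos <- swept@pos; neutral@cm <- swept@cm
        rs <- rsbScan(swept, neutral)
        top <- rs$pos[which.max(rs$rsb)]
        abs(top - swept@pos[100]) < 1e7
    }, logical(1))
    expect_gte(sum(hits), 4)
})

test_that("p-value transforms match the normal CDF", {
    expect_equal(pTransform(0, "ihs"), 0)
    expect_equal(pTransform(0, "rsb"), -log10(0.5), tolerance = 1e-12)
    x <- seq(-3, 3, by = 0.5)
    expect_equal(pTransform(x, "ihs"), pTransform(-x, "ihs"))
    expect_equal(pTransform(1.96, "ihs"), -log10(2 * pnorm(-1.96)),
                 tolerance = 1e-12)
    expect_true(is.na(pTransform(NA_real_, "ihs")))
})

test_that("the Lindley process and excursions match brute force", {
    ls <- localScore(c(3, 1.5, 4), xi = 2, nPerm = 10)
    expect_equal(ls$lindley, c(1, 0.5, 2.5))
    # reported maximum equals the maximum over all contiguous intervals
    set.seed(73)
    for (r in 1:5) {
        p <- runif(300, 0, 4)
        ls <- localScore(p, xi = 2, nPerm = 10)
        expect_equal(max(ls$lindley), bruteMaxSegment(p - 2),
                     tolerance = 1e-12)
    }
    # all p-values above 1% score non-positively: no excursions
    sub <- localScore(runif(100, 0, 2), xi = 2, nPerm = 10)
    expect_true(all(sub$lindley == 0))
    expect_equal(nrow(sub$windows), 0)
})

test_that("window reporting uses excursion bounds and leftmost tie peaks", {
    p <- c(0, 5, 1, 5, 0, 0)
    ls <- localScore(p, xi = 2, nPerm = 50, threshold = 0.5)
    expect_equal(nrow(ls$windows), 1)
    # Lindley is (0,3,2,5,3,1): the excursion spans indices 2..6 and peaks
    # at index 4
    expect_equal(ls$windows$startIndex, 2)
    expect_equal(ls$windows$endIndex, 6)
    expect_equal(ls$windows$peakIndex, 4)
    # exact tie in the Lindley maximum: leftmost reported
    p2 <- c(4, 0, 4, 2)
    ls2 <- localScore(p2, xi = 2, nPerm = 10, threshold = 0.5)
    # Lindley: 2, 0, 2, 2 -> two excursions; first peak at index 1
    expect_equal(ls2$windows$peakIndex[1], 1)
    expect_equal(ls2$windows$peakIndex[2], 3)  # tie 2,2 -> leftmost
})

test_that("neutral score profiles rarely produce significant windows", {
    set.seed(75)
    n <- 0
    for (r in 1:20) {
        stat <- rnorm(300)
        ls <- localScore(pTransform(stat, "ihs"), xi = 2, nPerm = 200)
        if (nrow(ls$windows) > 0) n <- n + 1
    }
    expect_lte(n, 3)  # ~1% expected rate; allow binomial slack
})

test_that("windows are annotated with the nearest gene and kb distances", {
    genes <- data.frame(chrom = "1", start = c(50000, 200000),
                        end = c(60000, 210000), name = c("G1", "G2"))
    win <- data.frame(startIndex = 1L, endIndex = 3L, startPos = 52000,
                      endPos = 58000, nSnps = 3L, peakIndex = 2L,
                      peakPos = 55000, peakScore = 4)
    ann <- annotateRegions(win, genes, chrom = "1")
    expect_equal(ann$nearestGene, "G1")
    expect_equal(ann$distanceKb, 0)  # peak inside the gene
    win$peakPos <- 42000  # 8 kb left of G1's start
    ann2 <- annotateRegions(win, genes, chrom = "1")
    expect_equal(ann2$nearestGene, "G1")
    expect_equal(ann2$distanceKb, 8, tolerance = 0.001)
    # equidistant genes are both reported and flagged
    win$peakPos <- 130000  # 70 kb from G1 end and G2 start
    ann3 <- annotateRegions(win, genes, chrom = "1")
    expect_equal(nrow(ann3), 2)
    expect_true(all(ann3$ambiguous))
    # empty gene set leaves the annotation blank
    ann4 <- annotateRegions(win, genes[0, ], chrom = "1")
    expect_true(is.na(ann4$nearestGene))
})
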