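# Shared in-code fixtures for the suite: small panels built deterministically.

# Panel of certain genotypes from an explicit dosage matrix.
certainPanel <- function(dosage, pop, aa = NULL, class = NULL,
                         chrom = "1", pos = NULL) {
    dosage <- as.matrix(dosage)
    if (is.null(pos)) pos <- seq_len(nrow(dosage)) * 1000
    GenotypePanel(chrom = chrom, pos = pos, ref = "A", alt = "C",
                  dosage = dosage, pop = pop, aa = aa, class = class)
}

# Panel with random soft genotype likelihoods (Dirichlet-ish via gamma).
softPanel <- function(nSites, nInd, pop = "P1", seed = 1, aa = "A") {
    set.seed(seed)
    gl <- lapply(1:3, function(k)
        matrix(stats::rgamma(nSites * nInd, 1), nSites, nInd))
    dosage <- matrix(sample(0:2, nSites * nInd, replace = TRUE),
                     nSites, nInd)
    GenotypePanel(chrom = "1", pos = seq_len(nSites) * 100, ref = "A",
                  alt = "C", dosage = dosage, gl = gl, pop = pop, aa = aa)
}

# Two-population panel of certain genotypes drawn from given frequencies.
freqPanel <- function(freqs, nInd, seed = 1) {
    set.seed(seed)
    pops <- colnames(freqs)
    dos <- do.call(cbind, lapply(pops, function(pp)
        matrix(stats::rbinom(nrow(freqs) * nInd, 2, freqs[, pp]),
               nrow(freqs), nInd)))
    certainPanel(dos, pop = rep(pops, each = nInd), aa = "A")
}

# Tiny single-chromosome haplotype panel from an explicit matrix.
hapPanel <- function(haps, pop = "P", cm = NULL) {
    HaplotypePanel(haps, chrom = "1", pos = seq_len(nrow(haps)) * 1e5,
                   cm = cm, pop = rep_len(pop, ncol(haps)))
}

# Independent grid-search oracle for the EM allele frequency.
gridSearchAF <- function(l0, l1, l2, step = 1e-4) {
    qs <- seq(0, 1, by = step)
    ll <- vapply(qs, function(q)
        sum(log(l0 * (1 - q)^2 + l1 * 2 * q * (1 - q) + l2 * q^2)),
        numeric(1))
    qs[which.max(ll)]
}

# Brute-force maximum over all contiguous intervals of cumulative scores.
bruteMaxSegment <- function(s) {
    n <- length(s)
    best <- 0
    for (i in seq_len(n)) for (j in i:n)
        best <- max(best, sum(s[i:j]))
    best
}

# Brute-force EHH by pairwise identity counting over an interval.
bruteEHH <- function(h, carriers, from, to) {
    sub <- h[min(from, to):max(from, to), carriers, drop = FALSE]
    n <- length(carriers)
    same <- 0L
    for (a in seq_len(n - 1)) for (b in (a + 1):n)
        if (all(sub[, a] == sub[, b])) same <- same + 1L
    2 * same / (n * (n - 1))
}
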