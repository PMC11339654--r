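---
title: "Statistical methods for founder-bottleneck population genomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for founder-bottleneck population genomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feralpopgen)
```

# Scope

`feralpopgen` implements the statistical layer needed to characterise a
recently founded, admixed population — the archetype being a feral island
herd established by a handful of animals of mixed taurine/zebu ancestry and
sampled some twenty generations later. The package covers: allele-frequency
and site-frequency-spectrum (SFS) estimation from genotype likelihoods;
genetic-load statistics by functional class; Weir–Cockerham F-statistics and
Patterson f-statistics with block-jackknife uncertainty; KING-robust kinship
and relationship degrees; a genetic-offset statistic built on
gene–environment association (GEA) coefficients; an EHH-based selection scan
segmented by a Lindley local score; and the small deterministic conversions
between genetic and calendar time. A simulator generates cohorts with the
statistical structure all of these estimators assume, providing ground truth
for validation.

# The cohort simulator

## Demography and selection

`simulateCohort()` runs a per-site Wright–Fisher frequency process. Sites
are unlinked, so each site's derived-allele frequency evolves independently
by binomial resampling of `2N` gametes per generation, with genotype
fitnesses `1, 1+hs, 1+s`. The demography is fixed by `simConfig()`:

* an ancestral population (diploid size 500) is burnt in for 100
  generations under class-specific selection, starting from a neutral
  `1/k`-shaped frequency spectrum;
* two source populations split and drift for 200 generations at size 500
  (giving pairwise FST between sources of roughly 0.2, the differentiation
  scale of taurine vs. Indian-Ocean zebu cattle); a sister population of
  source 1 splits halfway along, and an outgroup branches at the root —
  both exist so that F4-ratio designs have the required topology;
* the target population is founded by 5 diploids whose expected allele
  frequencies mix the two sources 75:25, then grows geometrically
  (factor 3 per generation, capped at 1,500) for 22 generations.

Defaults reproduce the study conditions the package was designed around
(5 founders, 22 generations, 75% source-1 ancestry, effective size ~1,500
after expansion). Five functional classes are simulated; their proportions
(70% intergenic, 10% synonymous, 10% tolerated nonsynonymous, 7%
deleterious nonsynonymous, 3% loss-of-function) and selection coefficients
(`s = 0, 0, -0.001, -0.02, -0.1`, with dominance `0.5, 0.5, 0.5, 0.3, 0.1`)
were chosen once as field-typical values: mildly deleterious missense
variants have |hs| of order 10^-3 to 10^-2, loss-of-function variants are
strongly deleterious and partially recessive.

A design note: one engine serves all classes. A coalescent would be faster
for the neutral classes, but with unlinked sites the per-site forward
frequency process produces the same marginal statistics, and a single code
path keeps neutral and selected classes exactly comparable. Haplotypes are
drawn from the final frequencies independently per site, so the main panel
carries **no linkage disequilibrium**; every statistic except the haplotype
scan is LD-free by construction, and the block jackknife is exercised on
blocks that are independent (its SEs are then, if anything, conservative
relative to real LD).

For the haplotype statistics a second, individual-based simulator
(`simulateLinkedHaplotypes()`) runs a forward Wright–Fisher population with
Poisson-recombination gametes, symmetric mutation (default 10^-3 per site
per gamete, which keeps haplotype diversity from collapsing by drift) and an
optional positively selected focal allele starting from two copies — a hard
sweep. Sweep runs that lose the allele are restarted.

## Sequencing noise

`emitSequencingData()` emulates whole-genome sequencing: per-site depths are
Poisson (default mean 10, matching a 5–20x filter), reads report the true
allele with probability `1 - errorRate` (symmetric error, default 10^-3),
and genotype likelihoods follow the binomial read model
(`readLikelihoods()`). Likelihoods are Phred-scaled, rounded to integer PL
capped at 255 with the best genotype at 0 — exactly what a VCF stores — and
de-Phred-scaled back, so the in-memory panel and a written-then-read VCF are
identical. Zero-depth sites carry three equal likelihoods and a missing
call.

## What the simulator does not emulate

Real WGS data have LD, sequencing-error haplotype structure, mapping
artefacts, reference bias and variant-calling error; the simulator has none
of these. Passing recovery tests therefore demonstrates the estimators are
correct under their own model assumptions — unbiasedness of the f-statistics
under drift, calibration of the jackknife under independence — not that they
are robust to artefacts of real pipelines.

# Allele frequencies and spectra from genotype likelihoods

`emAlleleFrequency()` maximises the marginal likelihood
`sum_i log sum_g GL_i(g) P(g | q)` under Hardy–Weinberg priors by EM.
Individuals with three equal likelihoods (no reads) are dropped, not
imputed. The EM is initialised at the likelihood-weighted naive estimate
with tolerance 10^-6 on the frequency and at most 100 iterations; for very
small samples (two or three individuals) the marginal likelihood can be
bimodal, so the single-site function adds three fixed extra starts and
returns the best mode (a fine grid search is the test oracle). The
panel-wide `populationFrequencies()` keeps the naive start: with eight or
more individuals multimodality was never observed.

Polarization follows the outgroup-unanimity rule: the ancestral allele is
called when all non-missing outgroups are homozygous for the same allele and
at most one of the (up to four) outgroups is missing. Segregating sites are
those with `0.001 < AF < 0.999` (strict), and fixed-derived counts
extrapolate the proportion of *polarized* sites with derived frequency
above 0.999 to the total site count — the denominator choice is exposed as
a flag (`denominator = "all"`) since either reading is defensible.

The probabilistic SFS treats each usable site (ancestral allele assigned, no
missing genotype in the population) as a sum over genotype configurations:
the probability that exactly `k` derived copies are present is the
coefficient of `x^k` in the product of per-individual generating functions
`GP0 + GP1 x + GP2 x^2`. The convolution path is `O(n^2)` per site; the
`3^n` enumeration (6,561 configurations for eight diploids) is retained as
an exact oracle and agrees with the convolution to 10^-12.

# Genetic load

Per-individual statistics use genotype probabilities ("expected counts") by
default, with hard calls as an option: the NS/S ratio divides expected
heterozygote counts at nonsynonymous sites by those at synonymous sites;
masked load is the proportion of an individual's called class genotypes that
are heterozygous, realized load the proportion homozygous-derived (the two
plus the homozygous-ancestral proportion sum to one).

`rxy()` computes `sum fX(1-fY) / sum fY(1-fX)` over the class sites and
standardizes by the same ratio over intergenic sites. Its CI is a
leave-one-block-out jackknife over 100 contiguous equal-SNP blocks (block b
of the class list and block b of the normalizer list are removed together;
remainder SNPs join the last block), reported as estimate ± 1.96 SE. At
desk-scale site counts this normal-approximation CI is mildly
anti-conservative — it covers the truth slightly less often than the nominal
95% under a symmetric neutral simulation (the acceptance script reports the
measured rate); a log-scale jackknife did not improve it, so the
conventional natural-scale CI is kept.

`predictHeight()` is the dosage-times-effect sum over SNPs matched to an
effect table by position and allele identity; unmatched alleles are dropped
and counted.

# F- and f-statistics

`wcFStatistics()` implements the analysis-of-variance estimator with
variance components a (among populations), b (among individuals within
populations) and c (within individuals), combined over SNPs as ratios of
sums; pairwise FST uses the two-population components, per-population FIS
the single-population reduction `1 - c/(b+c)`. SNPs monomorphic across all
populations are excluded. All standard errors are leave-one-block-out
jackknives over contiguous 250-SNP blocks (the final short block is kept),
with 95% CIs as ±1.96 SE.

`fStat()` computes the allele-count unbiased f-statistics: the
heterozygosity correction `p(1-p)/(n-1)` (n = sampled alleles) is subtracted
once per population in f2 and once for the target in f3; f4 needs no
correction. A triplet is called admixed when the f3 Z-score is below -1.65.
`f4Ratio()` estimates the mixing proportion as a ratio of f4 sums with a
jackknife CI; in the simulator's topology the design is
`f4(SIS1, OUT; TARGET, SRC2) / f4(SIS1, OUT; SRC1, SRC2)`. Its CI shares
RX/Y's mild anti-conservativeness; the acceptance script measures the
coverage at 20,000 sites.

`asdMatrix()` uses the sharing convention in which one shared allele —
including the heterozygote/heterozygote pair — scores distance 0.5 (several
dialects exist; this one makes the four-site toy AA/AA, AA/Aa, AA/aa, Aa/Aa
average exactly 0.5). `kinship()` is the KING-robust estimator from
heterozygote and opposite-homozygote counts; `classifyDegree()` partitions
the kinship line at powers of two (closed on the lower end), adding a
"duplicate" class above 2^(-3/2) so every finite value maps to exactly one
class. IBD-segment-based upgrading of relationship calls is out of scope.

# Genetic offset

`envPCA()` centers and scales the covariables (19 bioclimatic ones in the
motivating design) and retains 7 PCs by default, or the smallest number
reaching a variance-explained threshold. `estimateGeaCoefficients()` fits
per-SNP linear regressions of population allele frequencies on the retained
PC scores — a deliberately simple stand-in for a hierarchical Bayesian GEA
model. Raw frequencies are regressed by default (an arcsine-sqrt transform was
considered and left out: recovery on simulated truth is already nearly
perfect under the raw-scale model). Correctness is defined by recovery: on simulated
designs the estimated coefficients correlate > 0.8 with the truth at
effect-carrying SNPs, and offsets computed with the estimated matrix
rank-correlate > 0.9 with truth-based offsets across query environments.

The offset itself is the quadratic form `GO = d' B'B d / nsnp` with
`d = e_j - e_ref`; the unweighted environmental distance is
`sqrt(d'd / ne)`. `goSurface()` projects grid covariates with the training
loadings and evaluates GO per cell, skipping incomplete rows.

# Selection scan

EHH at distance d is the probability that two random haplotypes carrying the
focal allele are identical over the whole interval; curves are walked
outward until they drop below 0.05 and integrated by the trapezoidal rule
(iHH). The site-EHH (EHHS) is computed over all haplotypes, normalized to 1
at the focal SNP, and integrated to iES. iHS is `ln(iHH_1/iHH_0)` with
allele 1 = the panel's alternate allele (alleles are not polarized; the sign
is arbitrary and label-flips only flip it), standardized genome-wide in a
single frequency bin after a MAF > 0.01 filter. Rsb is `ln(iES_X/iES_Y)`
standardized genome-wide. Genetic positions default to 1 cM/Mb when no map
is given.

P-value transforms assume the standardized statistic is standard normal
under neutrality: two-sided for iHS, one-sided (X-specific) for Rsb. The
Lindley process accumulates `-log10(p) - xi` with xi = 2; maximal positive
excursions are candidate windows, the leftmost argmax is the peak, and
window bounds follow the excursion (a `first_positive` convention is
available, since the literature does not fix the boundary choice).

Per-chromosome significance is Monte-Carlo: the default null draws iid
uniform p-values — the distribution a correctly standardized statistic
implies under neutrality — and compares the observed excursion maximum
against the simulated maxima through an exact Monte-Carlo p-value. This
choice is deliberate: permuting the observed scores instead (also available
as `permMode = "shuffle"`/`"rotate"`) conditions on the score multiset, and
because the excursion maximum is often determined by a single large score
that survives any reordering, the permutation test is conservative. Under
the uniform null the empirical rate matches the nominal level within
binomial error (the calibration is asserted by the test suite and the
measured rate reported by the acceptance script). A closed-form Gumbel
approximation of the threshold is noted as future work.

`annotateRegions()` reports the gene nearest to each window peak — distance
0 when the peak lies inside a gene, otherwise the gap to the closer boundary
in kb; equidistant genes are all reported and flagged.

# Chronology

Pure functions: `generationsToYear()` (year = reference − t × generation
time, rounded to whole years, e.g. 22.02 generations before 1992 at 6
years/generation → 1860), `impliedGenerationTime()` ((1992 − 1871)/22 = 5.5
years), `hbdClassProperties()` (an HBD class with rate Rc has expected
segment length 1/Rc Morgans and groups ancestors ~Rc/2 generations back)
and `hbdRateGrid()` (the doubling grid 2…8192, 13 classes). Fitting the HBD
HMM itself is out of scope.

# Pipeline

`runPipeline()` chains simulate → frequencies → load → F/f-statistics →
kinship → offset → scan → chronology, writing one TSV per result, each
stamped with an MD5 hash of the configuration and the seed; reruns with the
same configuration are byte-identical. `validateInputs()` checks VCF
parseability and position order and the population table against the VCF
samples, returning a diagnostics table (errors are fatal to the pipeline).
Input files use VCF 4.2 (GT, PL, DP) plus plain TSVs for annotations,
population labels, environments, genetic maps and gene intervals; VCF
positions are 1-based.

# Problem sizes and numerical choices

The validation suites run at "desk scale", chosen so that each property is
measured with useful precision: F4-ratio coverage uses 100 cohorts of
20,000 sites; RX/Y coverage 200 replicates of 1,000 class + 1,000
normalizer sites; SFS flattening 20 cohorts of 4,000 sites; scan
calibration 1,000 neutral chromosomes of 300 SNPs with 500 Monte-Carlo
profiles each. EM tolerance is 10^-6 on the frequency; SFS convolution and
enumeration agree to 10^-12; jackknife blocks are 250 SNPs (f-/F-statistics)
and 100 equal blocks (RX/Y). Degenerate inputs are defined, not errors:
all-missing sites give NA frequencies, monomorphic panels give zero
heterozygosity, alleles with fewer than two carriers give NA EHH, empty
gene sets give blank annotations.

# Known limitations

* The main panel has no LD; jackknife SEs are validated under independence.
* The GEA estimator is linear and per-SNP; it does not model the neutral
  covariance of populations, so its coefficients are exchangeable with a
  hierarchical model's only through the recovery guarantees above.
* The scan's analytic (Gumbel) threshold mode is not implemented; thresholds
  are Monte-Carlo.
* KING's IBD-segment sharing, admixture-graph search, LD-decay dating and
  HBD-HMM fitting are consumed concepts, not implemented methods.
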