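# hbdpart

Age-based partitioning of individual genomic inbreeding from SNP
genotypes.

## The problem

The inbreeding coefficient *F* of an individual is the probability that
the two alleles at a locus descend from a single ancestral allele
(homozygosity-by-descent, HBD).  *F* is only defined relative to a base
population: a segment inherited through an inbreeding loop of *g*
generations has expected genetic length ≈ 1/*g* Morgans on each path, so
long HBD segments betray recent common ancestors and short ones ancient
ancestry.  Single-number estimators (pedigree *F*, genomic-relationship
diagonals, homozygosity, runs of homozygosity) mix these time scales or
fix one by rule-of-thumb parameters.

`hbdpart` implements a mixture hidden Markov model that decodes each
genome into one non-HBD and several age-related HBD classes.  Class *k*
has segment lengths Exp(*R<sub>k</sub>*) with *R<sub>k</sub>* ≈ twice the
generations to the common ancestor, and mixing proportion
*m<sub>k</sub>*; over an inter-marker distance *d* the transition kernel
is

    a(k,l) = exp(-R_k d) [k = l] + (1 - exp(-R_k d)) m_l

Emissions inside an HBD class are P(AA) = f<sub>A</sub>(1−ε),
P(BB) = (1−f<sub>A</sub>)(1−ε), P(AB) = ε (ε = genotyping-error term);
the non-HBD class emits Hardy–Weinberg proportions; genotype-likelihood
triples from sequencing data are integrated over.  The inbreeding
coefficient with respect to a base population ≈ *T*/2 generations back is

    F_G-T = genome-averaged posterior probability of any HBD class with R_k <= T

Fitting is per-individual expectation–maximization (forward–backward in
an O(NK) Rcpp core) with rates constrained to [1, 8192]; the number of
classes can be chosen by BIC.  Three parameterizations are provided: `1R`
(one HBD class, shared rate), `KR` (free rates) and `MixKR` (fixed dyadic
rates 2, 4, …, 8192; mixing free) — plus the classical estimators the
model is usually benchmarked against (F_HOM, F_ExHOM, two GRM-diagonal
variants, F_UNI, pedigree F), a PLINK-style sliding-window ROH caller
with per-panel presets, PLINK/VCF input with the standard QC filters, and
a mosaic-genome simulator (with pedigree gene dropping) that provides
exact ground truth.

Audience: population and quantitative geneticists quantifying recent
versus ancient inbreeding in livestock, wild or human populations from
SNP-array or sequence genotypes.

## Worked example

Simulate four genomes carrying recent (R = 10) and ancient (R = 1000)
autozygosity on five 1-Morgan chromosomes, then partition them with the
default 13-HBD-class model:

```r
library(hbdpart)
set.seed(42)

truth <- hbd_model("KR", K = 3, epsilon = 0.002)
truth$rates  <- c(10, 1000, 1000)              # recent, ancient, non-HBD
p <- c(0.10, 0.15, 0.75)                       # target genome fractions
truth$mixing <- p * truth$rates / sum(p * truth$rates)

map   <- simulate_map(n_chromosomes = 5, chrom_length = 1,
                      marker_spacing = 2e-4)
freqs <- simulate_frequencies(nrow(map), maf_floor = 0.01, seed = 7)
sim   <- simulate_mosaic(truth, map, freqs, n_individuals = 4, seed = 11)

fit <- hbd_fit(hbd_model("MixKR", epsilon = 0.002), sim$geno, map)
fit
#> MixKR model fitted to 4 individual(s); mean F_G = 0.2001 (range 0.1870-0.2208)
summary(fit)$table
#>       id       F_G    logLik      BIC n_iter
#> 1 ind001 0.1925718 -19768.00 39667.65    490
#> 2 ind002 0.1869958 -19888.71 39909.06    446
#> 3 ind003 0.2002519 -19683.07 39497.80    429
#> 4 ind004 0.2207517 -19545.85 39223.34    408
```

`F_G` is each genome's total HBD probability.  Restricting the base
population to recent ancestors (classes with R<sub>k</sub> ≤ 32, about 16
generations) recovers the simulated recent autozygosity:

```r
round(predict(fit, "inbreeding", T = 32), 4)
#> ind001 ind002 ind003 ind004
#> 0.0302 0.0289 0.0302 0.0657
round(sim$truth$fractions[, 1], 4)          # true recent fractions
#> ind001 ind002 ind003 ind004
#> 0.0290 0.0307 0.0335 0.0710
```

Viterbi HBD segments and their length distribution:

```r
segs <- predict(fit, "segments", ids = "ind001")
head(segs[, c("chrom", "start_bp", "end_bp", "class", "rate", "n_markers")], 3)
#>   chrom start_bp   end_bp class rate n_markers
#> 1     1  8260001  8660001    10 1024        21
#> 2     1 10420001 10940001    10 1024        27
#> 3     1 15840001 15940001    10 1024         6
segment_length_table(segs)[6:9, ]
#>             bin count
#> 6 100 kb-500 kb   107
#> 7   500 kb-1 Mb    17
#> 8     1 Mb-5 Mb     4
#> 9    5 Mb-10 Mb     1
```

The companion estimators work from the same containers, e.g.
`f_estimates(sim$geno, freqs)` for the marker-based coefficients and
`roh_scan(sim$geno, map, roh_preset("HD"))` for rule-based ROH and
F_ROH.  See the vignette in `vignettes/` for the model, defaults and
design decisions.

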