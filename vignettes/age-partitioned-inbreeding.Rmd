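---
title: "Age-based partitioning of genomic inbreeding: model and methods"
author: "hbdpart"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-based partitioning of genomic inbreeding: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbdpart)
```

## The mosaic model

An individual's diploid genome is modelled as a mosaic of
homozygous-by-descent (HBD) and non-HBD segments.  A segment of class $k$
has an exponentially distributed genetic length with rate $R_k$
(Morgans$^{-1}$), and a newly started segment belongs to class $k$ with
probability $m_k$ (the *mixing proportion*, $\sum_k m_k = 1$).  Because a
segment inherited through an inbreeding loop of $g$ generations has
expected length $1/g$ Morgans on each path, $R_k$ is roughly twice the
number of generations to the common ancestor: classes with small rates
describe recent inbreeding (long segments), classes with large rates
ancient inbreeding (short segments).  This is what makes the partition
*age-based*: the genome-wide probability of each class estimates the
fraction of the genome contributed by ancestors of the corresponding
epoch.

The model is a hidden Markov chain along each chromosome.  Over an
inter-marker distance $d$ the current class-$k$ segment survives with
probability $e^{-R_k d}$; if it ends, the next segment's class is drawn
from the mixing proportions (self re-entry allowed):

$$a(k,l) = e^{-R_k d}\,[k=l] + \left(1 - e^{-R_k d}\right) m_l .$$

This renewal form is the minimal transition kernel consistent with
exponential class-specific lengths and segment-frequency mixing; rows are
stochastic for every $d \ge 0$.  Chromosomes are independent chains, each
starting from the mixing proportions, and the same convention is used by
the simulator (the first segment's class is drawn from $m$, a stationary
start in segment frequency rather than length-biased).

Emissions compare the observed genotype to the segment state.  With
allele-A frequency $f_A$ and an error term $\varepsilon$ (the probability
of observing a heterozygote inside an HBD segment — genotyping error or
mutation):

* HBD class: $P(AA) = f_A (1-\varepsilon)$,
  $P(BB) = (1-f_A)(1-\varepsilon)$, $P(AB) = \varepsilon$;
* non-HBD class: Hardy–Weinberg proportions $f_A^2$, $2 f_A (1-f_A)$,
  $(1-f_A)^2$ (no error term, by construction);
* missing genotype: probability 1 in every state (and the marker does not
  count toward the BIC sample size);
* genotype probability triples (sequencing data): the emission is
  integrated, $\sum_g P(g \mid \text{state}) \, P(g \mid \text{data})$.

## Parameterizations

Three model families are exposed through `hbd_model()`:

* **1R** — one HBD and one non-HBD class sharing a single free rate; the
  shared rate has better statistical properties than two free rates when
  only one HBD class is fitted.
* **KR** — $K$ classes, each rate free; used with model comparison to
  choose $K$.
* **MixKR** — fixed dyadic rates $2^1, \dots, 2^{13}$ for 13 HBD classes
  and $2^{13}$ for the non-HBD class (default $K = 14$); only the mixing
  proportions are estimated.  The geometric grid gives a constant,
  limited overlap between successive length distributions, and fixed
  classes make individuals directly comparable.

Parameters that matter, with defaults:

| parameter | default | meaning |
|---|---|---|
| `epsilon` | 0.002 | heterozygote-in-HBD error probability; exposed everywhere, tests pass it explicitly |
| `rate_bounds` | (1, 8192) | clamp on free rates during EM |
| `n_iter` | 1000 | maximum EM iterations |
| `tol` | 1e-3 | stop when the log-likelihood gain per iteration falls below this; `0` disables early stopping |
| `T` (threshold) | largest HBD rate | classes with $R_k \le T$ count as autozygous; base population $\approx T/2$ generations back |

The inbreeding coefficient $F_{G\text{-}T}$ is the genome-averaged
posterior probability of belonging to any HBD class with $R_k \le T$;
marker averaging is unweighted by default (a distance-weighted option
exists) and $T$ at the largest HBD rate gives total $F_G$.

## Fitting

Parameters are estimated per individual by Baum–Welch EM with per-marker
scaling.  The E-step decomposes each interval's transition posterior into
*survival* and *termination + re-entry* events, which is exact under the
kernel above and keeps the recursions $O(NK)$ instead of $O(NK^2)$.
Mixing proportions are re-estimated from expected segment entries
(chromosome starts included).  Free rates have no closed-form update
under the shared-termination kernel, so each is re-estimated by bounded
one-dimensional maximization (`stats::optimize`, tolerance $10^{-4}$ in
the rate) of the expected complete-data log-likelihood, aggregated over
unique inter-marker distances; the old rate is kept whenever the
optimizer's candidate scores worse, so the log-likelihood never
decreases.  Rates are clamped to `rate_bounds`.

Initialization: mixing is uniform.  The shared 1R rate starts at the
geometric midpoint of the bounds.  For KR models with several free rates
the starting rates are *geometrically spaced interior points* of the
bounds rather than a common midpoint: HBD classes have identical
emissions, so an exactly symmetric start is a fixed point of EM and the
classes could never differentiate.  This was a deliberate design choice
after the midpoint initialization proved degenerate.

Model choice uses $\mathrm{BIC} = -2\log L + p \ln n$, with $p$ the
number of free parameters (free rates, counting the 1R shared rate once,
plus $K-1$ free mixing proportions) and $n$ the individual's non-missing
marker count.  Whether the reference implementation uses per-individual
or panel-wide $n$ is not documented; per-individual counts are the
assumption here, and ties go to the smaller $p$.

Viterbi decoding reports the jointly most probable class path; tie-breaks
go to the lowest class index (deterministic).  Segment physical bounds
are the first and last marker positions of the run.  Posterior (forward–
backward) probabilities are generally preferable at low marker density;
the Viterbi segments are what the length-distribution tables summarize.

## The simulator and what it does (not) emulate

`simulate_mosaic()` draws the renewal process directly — class from $m$,
length $\mathrm{Exp}(R_k)$ — until each chromosome is tiled, then emits
genotypes marker by marker under the emission model.  `gene_drop()`
complements it with pedigree-based truth: founder haplotypes are drawn
from allele frequencies, gametes recombine as a Poisson process on the
genetic map (Haldane, no interference — the model consistent with
exponential segment lengths), and founder-haplotype labels make realized
autozygosity exactly recoverable.

Study conditions encoded as defaults (chosen once):

* marker grids mimic three genotyping panels on a 25-Morgan genome —
  HD $4 \times 10^{-5}$ M spacing ($\approx$ 625K markers genome-wide),
  50K $8 \times 10^{-4}$ M ($\approx$ 31K), LD $3.4 \times 10^{-3}$ M
  ($\approx$ 7K); thinning the HD grid 20× gives the 50K grid and 85×
  the LD grid;
* allele frequencies $\mathrm{Beta}(1,1)$ with a minor-allele-frequency
  floor of 0.01, the usual QC threshold, applied by resampling so the
  Beta shape is preserved without an atom at the floor;
* $\varepsilon = 0.002$;
* physical positions follow a fixed 1 cM/Mb conversion
  ($10^{-8}$ Morgan/bp, 1-based).

The simulator does **not** emulate linkage disequilibrium beyond the
mosaic itself, coalescent ancestry, selection, mutation, allele-frequency
drift between reference and study populations, or genotype-calling error
outside $\varepsilon$.  Passing tests therefore demonstrate correctness
of the inference machinery under the model's own assumptions, not
robustness to the full complexity of real SNP-array data (map errors,
array ascertainment, misoriented alleles), which real analyses must
address through the QC layer.

Test and acceptance problem sizes — 20 individuals × 10 Morgans at the
HD-like grid (≈ 250K markers per genome), with one recovery cohort
(single HBD class, $R = 20$, stationary HBD fraction 0.25) and one
two-age-class cohort (rates 10 and 1000, stationary fractions 0.10 and
0.15) — were chosen as the smallest designs on which rate recovery,
age-partition fidelity and the density comparisons are all
well-conditioned.

## Numerical choices and conventions

* Scaling constants per marker (not log-space) in the forward–backward
  recursions; the log-likelihood accumulates the scaling logs.  Viterbi
  runs in log space.
* A marker whose emission vanishes in every state (possible only with
  $\varepsilon = 0$ and degenerate frequencies) aborts with the marker
  index; markers with $f_A \in \{0, 1\}$ are retained — QC normally
  removes them, and they simply carry no HBD/non-HBD contrast.
* QC order: individual call rate (< 0.90 dropped) before SNP filters
  (call rate < 0.95, MAF < 0.01, Hardy–Weinberg 1-df chi-square
  $p < 0.001$, opposite-homozygote conflicts in more than one
  parent–offspring pair).  The chi-square was chosen over an exact test
  because only the p-threshold is specified; the filters are idempotent.
* ROH windows follow the PLINK semantics: 50-SNP windows, no
  heterozygote, up to 5 missing; a SNP is eligible when at least 5% of
  covering windows are hits (that tool's default — rarely reported in
  published analyses, so it is exposed as a parameter here).  Panel presets: LD (≥ 1 SNP / 500 kb, ≥ 5 Mb, gap ≤ 1 Mb),
  50K (100 kb, 1 Mb, 500 kb), HD (10 kb, 100 kb, 200 kb); ROH length is
  inclusive ($end - start + 1$).
* Segment-length bins are half-open $[low, high)$ with the lowest bin
  closed at zero, from < 1 kb to 100 Mb.
* Pedigree inbreeding uses the tabular kinship recursion, exact for any
  pedigree (any exact kinship algorithm yields identical output to the
  method named for this step); unknown parents are unrelated, non-inbred
  founders.  Cycles are reported as errors; out-of-order pedigrees are
  topologically reordered with a warning.
* Estimator frequencies are always an explicit argument — typically a
  reference cohort such as the oldest genotyped animals — never computed
  silently in-sample.  Missing genotypes drop out of each estimator's
  numerator and denominator; markers with $2f(1-f) = 0$ are excluded from
  the per-SNP-weighted estimators with $N$ decremented.
* PLINK text input orients allele A as the alphabetically first observed
  allele unless allele labels are supplied; VCF input orients A as REF.

## Known limitations

* One non-HBD class only (multiple non-HBD states are not modelled).
* The renewal transition kernel is this package's own formulation: the
  minimal kernel consistent with exponential class-specific segment
  lengths and class entry by mixing proportion.  Other multi-HBD-class
  parameterizations (e.g. with distinct entry and survival algebra)
  exist and need not produce bitwise-identical decodings.
* X chromosome, haplotype-based IBD between individuals, phasing and
  imputation are out of scope; binary PLINK BED files are not read.
* Map-error screening (misplaced segments detected via linkage/LD/ROH
  breaks) is not implemented; only marker include/exclude lists through
  the QC layer.
* At low marker density HBD segment *boundaries* from Viterbi are
  unreliable even when genome-wide probabilities remain well calibrated;
  posterior probabilities should be preferred there.
* The simulator overstates what low-density panels can see of *ancient*
  autozygosity.  It emits genotypes with a genuine marginal homozygote
  excess inside every HBD segment, so even when ancient segments contain
  fewer than one marker the fitted model recovers their total mass from
  the per-marker excess (at wide spacing the chain is effectively
  memoryless and the HMM reduces to a marginal mixture — the correct
  maximum-likelihood answer for such data).  In real populations, ancient
  autozygosity relative to *contemporary* allele frequencies produces
  essentially no marginal Hardy–Weinberg deviation — excess-homozygosity
  estimators sit near zero while run-based measures are large — because
  the signal lives in the clustering of homozygosity along the genome,
  which sparse panels cannot resolve.  Consequently the total inbreeding
  coefficient on simulated data is nearly density-invariant, whereas on
  real data it drops substantially on sparser panels; emulating that
  would require shared haplotype/LD structure, which is outside this
  generator's scope.  Density comparisons on simulated data are therefore
  informative for ranking individuals and for recent classes, not for
  the absolute density dependence of total F_G.
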