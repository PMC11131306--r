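---
title: "Methods: joint analysis of archaic and modern variation at a locus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint analysis of archaic and modern variation at a locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleolocus)
```

## Overview

`paleolocus` analyses a single gene locus jointly across phased modern human
genomes (1000 Genomes-style VCFs with an `AA` ancestral-allele INFO tag) and
a small panel of unphased archaic genomes (Neanderthal and Denisovan
single-sample VCFs).  The pipeline merges the two kinds of data into one
complete site-by-sample matrix, and from that matrix derives four families of
results: identity-by-state (IBS) ordination, a lineage-specific derived-allele
conservation test, archaic-introgression summaries, and standardized
selection statistics.  A synthetic-data generator emulates every input
format, so the entire pipeline is exercisable and testable offline.

## Merging and polarization

Modern and archaic VCFs are reduced to biallelic SNVs inside the target
region.  Indels, spanning deletions (`*`) and multiallelic records are
excluded at read time.  The merged matrix is the intersection of sites on
(chrom, pos, ref, alt); any site uncalled in at least one input is dropped,
so the result has no missing entries.  Two deliberate choices:

* **Monomorphic sites are retained.**  Source files are filtered to variants
  polymorphic within themselves, but a site fixed across the merged dataset
  can still separate moderns from archaics and therefore carries IBS
  information.  The SFS statistics ignore such sites, so nothing downstream
  is biased by keeping them.
* **Strand flips are never auto-repaired.**  REF/ALT disagreement at a shared
  position aborts with a report; a silently "fixed" flip would corrupt
  polarization, which is the foundation of the conservation test.

The ancestral allele is parsed case-insensitively from the `AA` tag
(lowercase marks low-confidence calls in the 1000 Genomes convention).  Any
value outside `{REF, ALT}` — including `.`, `N`, `-` — leaves a site
unpolarized: it stays in the matrix for distance work but is excluded from
every derived-allele analysis.  Coordinates are 1-based inclusive throughout
(VCF convention); BED inputs are converted at the reader.

## IBS distances and the weighted MDS

Haplotypes are 0/1 vectors and archaic genotypes 0/1/2 dosages.  All three
pairwise kernels are per-site means of `|a - b|` after dosages are scaled by
one half, which puts every comparison on a common `[0, 1]` scale: a
heterozygous archaic site contributes 0.5 against either haplotype allele.
Using means rather than sums keeps pairs comparable under any site
subsetting; because ordination is invariant to a global positive rescaling
of the dissimilarities, this choice does not affect the recovered geometry.

With thousands of modern haplotypes and only four archaic genomes, an
unweighted MDS would place the archaics according to modern sampling depth
rather than genetic structure.  The weight scheme gives each archaic genome
weight `1/(A+1)` and divides one further `1/(A+1)` share equally among the
`H` modern haplotypes — with four archaics, five masses of one fifth.  The
weighted MDS double-centres `-D^2/2` with the weight vector as centering
mass and eigendecomposes the symmetrized matrix `W^{1/2} B W^{1/2}`, which
is numerically equivalent to weighted Gower centering but guarantees a real
symmetric eigenproblem.  Coordinates are scaled so the weighted sum of
squares per axis equals its eigenvalue; explained variance is reported over
positive eigenvalues only, and axis signs are fixed by forcing the
largest-magnitude coordinate on each axis positive, so plots are
reproducible across eigen-solver implementations.  With equal weights the
procedure reduces exactly to classical MDS, which the tests exploit as an
oracle (together with `vegan::wcmdscale` for unequal weights).  Zero-weight
objects are embedded afterwards by the standard out-of-sample formula and
cannot influence any other object's position.

## Ordinal SMACOF

Population structure in selection-statistic space is projected with ordinal
SMACOF: stress majorization with disparities fitted by monotone regression
on the rank order of the dissimilarities.  Settings, all open in the
literature and therefore fixed here as package defaults: primary approach to
ties (tied dissimilarities may receive unequal disparities, ordered by the
current configuration distances), Torgerson initialization with optional
seeded random restarts, convergence at a relative stress-1 change below
`1e-6`, and at most 300 iterations.  After each monotone fit the disparities
are rescaled by their least-squares optimal factor, which makes raw stress
non-increasing across both half-steps; the per-iteration stress-1 trace is
retained on the result object, and its monotonicity is asserted in the test
suite.  Exact orientation of any published configuration is not expected —
ordinal MDS is defined only up to rotation, reflection and monotone
transformation of the input.

## The conservation resampling test

For a panel of modern individuals, the test repeatedly draws subsets of four
individuals (matching the number of archaic genomes), splits polarized
polymorphic sites into those whose derived allele occurs only on the
subset's eight haplotypes (`D_EMH`) and those where it occurs only in the
archaic genomes (`D_ARC`), and records the difference in mean per-base
conservation between the two classes.  The reported probability is the
fraction of replicates with difference at or below zero, so small values
mean modern-lineage mutations sit at more conserved positions; ties at
exactly zero count against significance.  Derived presence is evaluated on
the eight subset haplotypes only, a literal reading of the subsampling
design.  Sites without a conservation score are dropped from the means (not
imputed) and counted; replicates with an empty class are skipped and
counted.  Reproducibility: a per-replicate seed table is drawn once from the
user seed, making replicates independent of evaluation order.

An important property, measured with the package's own generator and
asserted in the tests: the empirical probability is a *within-dataset*
quantity, not a dataset-calibrated p-value.  When the archaic panel is
replaced by four relabeled modern individuals (full exchangeability), its
distribution across generator replicates is uniform.  With genuinely
diverged archaic genomes, however, the replicate-to-replicate variance of
the difference (fresh lineage-specific site sets each replicate) exceeds the
within-replicate subsampling variance, and the distribution of the
probability under a zero conservation shift is U-shaped rather than
uniform.  Interpreting the statistic on real data should therefore treat it
as an empirical summary of the observed locus, not as a frequentist p-value
over hypothetical loci.

## Introgression summaries

Sprime-style records are matched to matrix sites by exact
(chrom, pos, ref, alt); unmatched records are counted and skipped, since
build-version drift between score tables and genotype files is common.
Counts are allele copies: a haplotype's count is the number of matched sites
carrying the putatively introgressed allele, and an individual sums its two
haplotypes.  Outlier haplotypes are flagged beyond the extreme-outlier fence
`Q3 + 3 IQR` (configurable), an automated stand-in for what is usually a
visual call on the ordination.  Depletion of introgression around the locus
is quantified as the length of the maximal marker-free interval containing
the locus, ranked one-sidedly among all inter-marker gap lengths on the
chromosome.  This chromosome-wide gap rank is a simplification — reference
maps publish genome-wide tests with unpublished details — and is documented
as such.

## Selection statistics

Per-gene values are overlap-weighted means of windowed statistics (weights
proportional to overlapping base pairs), standardized against the empirical
distribution of genes length-matched to the focal gene (inclusive tolerance
band, focal gene excluded; both a z-score and a strict empirical quantile
are returned, since published standardizations do not always state which
transform was used).  Genome-wide empirical window p-values count windows
strictly greater than the observed value.  Two SFS statistics are computed
in-house: nucleotide diversity per site with the unbiased `n/(n-1)`
estimator over a user-supplied accessible span, and Fay & Wu's
`H = theta_pi - theta_H` from the unfolded SFS.  Linkage-based (iHS) and
divergence-based (alpha) statistics are consumed as precomputed window
values only; computing them needs genome-scale data outside this package's
scope.

## The synthetic-data generator

The generator is first-class, tested code, not a fixture.  Its defaults are
the package's reference study conditions: a 1 Mb locus; 2 populations of 50
diploid individuals (200 haplotypes); 4 archaic genomes; Poisson site counts
around 300 shared, 150 modern-lineage and 150 archaic-lineage sites; derived
counts drawn from a neutral law (probability proportional to `1/i`) and
placed exactly on randomly chosen haplotypes, so the expected unfolded SFS
is exactly neutral and Fay & Wu's H is centred at zero; standard-normal
conservation scores with modern-lineage sites shifted by `delta = 1`; and an
introgressed tract spanning the central fifth of the locus copied from the
first archaic genome into 3 recipient haplotypes.  The donor is made
homozygous across the tract (with derived alleles fixed at archaic-lineage
tract sites), so recipients match it exactly and the tract is detectable by
construction.  Population differentiation comes from per-site log-normal
population weights (`drift` parameter) biasing carrier placement.

Deliberately absent realism: no coalescent genealogy, no recombination map,
no mutation-rate heterogeneity, no linkage outside the introgressed tract.
Sites are independent given their lineage labels and frequency law, which is
sufficient for the IBS-, SFS- and conservation-based statistics under test.
Passing tests therefore demonstrate correctness of the statistics under the
assumed sampling structure, not robustness to linkage disequilibrium or
demographic complexity in real panels.

All randomness flows from one seed through named child streams (sites,
frequencies, archaic genotypes, conservation, introgression, tables), and
emitted files contain no timestamps, so identical configurations give
byte-identical bundles.

## Problem sizes and numerical choices

The shipped tests run the generator at its default size (about 600 sites,
204 samples) for end-to-end checks, with 200 replicates for calibration
checks, 50 for power and 100 for SFS sign behavior — sizes at which the
Monte Carlo assertions are stable under their fixed seeds.  Numerical
tolerances: oracle equivalences at `1e-12` (identical arithmetic by two
routes), Procrustes comparisons at `1e-8` (eigendecompositions by two
routes), SMACOF stress monotonicity with `1e-12` slack for floating-point
accumulation.  Degenerate inputs are handled explicitly: all-equal
dissimilarities warn (degenerate ordinal problem), monomorphic matrices give
`pi = 0` and `H = 0`, empty conservation classes are skipped and counted,
and an all-missing score set signals the empty-class condition rather than
returning `NaN`.

## The packaged variant-screen example

The packaged annotation table transcribes the five archaic LRP5 missense
variants (with their published SIFT/PolyPhen scores, carriers and, where
available, FoldX stability changes).  Per-variant base quality, alignment
quality and conservation values are synthetic placeholders consistent with
the quality filters these variants are known to satisfy, and the decoy table
is fully synthetic, each decoy violating exactly one screening rule;
together they exercise the screen's pass logic and failure reporting.  The
default thresholds (SIFT at most 0.05, PolyPhen at least 0.85, phyloP at
least 2.0) are this package's configurable conventions for "damaging" and
"highly conserved", not values claimed from any external source; the quality
thresholds (base quality 23, alignment quality 150) follow the standard
archaic-genome read filters.  The stability threshold of 1.6 kcal/mol is
twice the FoldX standard deviation; comparisons are strict, so exactly 1.6
is "below threshold".

## Known limitations

* No genotype calling, phasing, imputation or liftover; inputs must be on a
  common assembly.
* The depletion p-value is a chromosome-wide gap rank, not a replication of
  any genome-wide published test.
* The conservation test's empirical probability is not calibrated across
  datasets under lineage divergence (see above); only the exchangeable null
  is uniform.
* Ordinal SMACOF can stall in local minima for large, noisy dissimilarity
  matrices; seeded random restarts (`n_init`) are available but not default.
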