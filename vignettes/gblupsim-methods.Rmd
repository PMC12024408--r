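---
title: "Simulating multi-breed cattle populations and evaluating genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating multi-breed cattle populations and evaluating genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gblupsim)
```

`gblupsim` is a forward-in-time simulator of beef-cattle breeding
populations coupled to three breeding-value estimators — pedigree BLUP
(PBLUP), genomic BLUP (GBLUP) and window-weighted genomic BLUP
(wGBLUP) — and a scenario-grid driver that measures prediction accuracy
as the correlation between true and estimated breeding values. This
vignette explains the models, the tunable parameters, the numerical
choices, and what the reduced-scale test suite does and does not
demonstrate.

## The simulated genome and trait

The genome holds 29 autosomes. Only two genome-length totals are
defensible for cattle — the assembly-derived 2715.85 cM and the older
2486 cM figure — and the package defaults to the assembly-derived
total, distributing it over chromosomes proportionally to the
ARS-UCD1.2 physical autosome sizes (`genome_spec(total_cm = 2486)`
selects the alternative). Markers are placed uniformly at random
within chromosomes, with per-chromosome counts apportioned to genetic
length by the largest-remainder rule so a configured panel size (58,990
for the 50k panel, 777,962 for the 770k panel) is hit exactly. The 25
QTL per chromosome sit at interval midpoints — "evenly distributed"
admits several readings; midpoints keep QTL off chromosome edges and
make spacing exactly uniform.

The trait is strictly additive. QTL effect magnitudes are gamma(0.4)
draws — a long-tailed architecture with many small and a few moderate
effects — with signs + or − at probability ½ each (the distribution
only constrains magnitudes; symmetric signs are the convention when no
direction is specified, and an all-positive mode is available). One
common constant rescales the vector so that
\[
\sum_j 2 p_j (1 - p_j)\, \beta_j^2 = h^2 \times 1.0,
\]
with \(p_j\) taken in the **last historical generation**, the common
base of all breeds: the breeds share one effect vector and differ only
in QTL frequencies, so their realized additive variances drift apart
naturally. Phenotypes are \(y = \mu + \mathrm{TBV} + e\),
\(e \sim N(0, 1-h^2)\), \(\mu = 0\): the overall mean is the only
fixed effect, so phenotypic variance is calibrated to 1.0 and
\(\mathrm{cor}(y, \mathrm{TBV})^2 = h^2\) in expectation. A per-QTL
variance report (`qtl_variance_report()`) flags any locus contributing
more than a configurable cap (0.02) to screen out accidental
major-gene architectures.

## Population simulation

**Historical phase.** Founders start with every allele Bernoulli(0.5)
("equal" frequencies), far from mutation–drift equilibrium;
equilibrium and LD are then approached through many generations of
random mating. Population size follows a breakpoint trajectory with
linear interpolation between breakpoints (the breeds contract to a
bottleneck at the midpoint and re-expand to a common final size of
7,120 at full scale). Gametes recombine with a Poisson(length/100)
crossover count per chromosome and uniform crossover positions —
Haldane's model, no interference; no map function is uniquely implied
by the design, and Haldane is the simulator convention. Mutation is
recurrent allele flipping at 2.5e-5 per locus per gamete: mutation
only switches between the two allelic states.

**Recent phase.** Each breed draws its founders at random from the
last historical generation. The founder counts (620/5,800 for A,
350/5,100 for B, 300/5,000 for C) exceed one sex's share of the 7,120
final historical animals, so the founding draw assigns sex at the draw
rather than honouring the (decorative, unselected) historical sexes; a
strict mode is available and errors informatively. Ten discrete
generations follow: every dam produces exactly one offspring by a
randomly assigned sire, offspring sex is Bernoulli(½), and each sex's
breeding pool is renewed by its replacement rate and grown along the
compound path \(\mathrm{round}(n_0 (1+g)^t)\) — the growth convention
is not uniquely determined by a "replacement and growth rate" pair, so
the package fixes closed-form compounding with half-up rounding,
culls at random (random culling is part of the design), recruits the
top-ranked young candidates of the right sex, and re-retains culled
animals only if a cohort cannot supply enough recruits of one sex
(a cohort holds only about half of each sex, so high dam growth can
momentarily outstrip the female young stock). The last cohort is
itself selected into the pools, completing the growth path.

Selection ranks candidates either by own phenotype or by PBLUP EBV
computed from all records accumulated so far; EBV mode costs a sparse
mixed-model solve per generation, so the fast desk-scale default is
phenotype ranking. Phenotypes are simulated for every recent animal
because selection needs them, but only generations 9–10 are exported —
they are the genotyped cohorts. Mutation is off in the 10 recent
generations (at 2.5e-5 it is negligible there, and founder-derived
genotypes make transmission exactly checkable); it can be re-enabled.

## Quality control and genotype I/O

QC follows the chip-data convention: animals with more than 10%
missing genotypes, then loci with more than 10% missingness, then
MAF < 0.05, then a Hardy–Weinberg exact test at p < 1e-5. The
"call rate < 0.10" phrasing is inverted relative to convention and is
implemented as "missing fraction > 0.10". The HWE test is the exact
conditional test (full enumeration of heterozygote counts given allele
counts, no mid-p). The filter order is fixed so removal counts are
deterministic; on simulated (complete) data the missingness filters
are provably no-ops, which the tests assert. PLINK text (.ped/.map)
and binary (.bed/.bim/.fam, SNP-major v1.9) readers and writers
round-trip dosages including missingness; the counted allele is A1.

## Relationship matrices and solvers

The pedigree matrix A uses the tabular recursion; its inverse is built
directly by Henderson's rules with Meuwissen–Luo computation of the
Mendelian-sampling variances, so inbreeding is exact, and the two
routes agree to 1e-8 on random pedigrees (a standing test). The
genomic matrix defaults to VanRaden method 1,
\(G = ZZ'/\sum_i 2p_i(1-p_i)\) with \(Z = M - 2p\): the uncentered
cross-product form \(MM'\) is retained behind `centered = FALSE` for
completeness, but an uncentered cross-product is not a relationship
matrix in the variance-component sense and is not used in fits.

One numerical fact shapes the solver interfaces: when genotypes are
centered on allele frequencies observed in any subset of the matrix's
own animals, the centered scores of that subset sum to zero and G is
*exactly* singular. G therefore enters the mixed-model equations
either after identity blending (`stabilize_grm()`, default
\(G^* = 0.99\,G + 0.01 I\), recorded in an attribute) or with
externally supplied frequencies. The exact-equivalence tests
(GBLUP vs SNP-BLUP backsolve, wGBLUP's two routes) supply frequencies
for this reason.

The mixed-model equations are solved by Jacobi-preconditioned
conjugate gradients to a relative residual of 1e-8 (configurable,
maximum 10n iterations, non-convergence always warns and is flagged in
the diagnostics), with a dense direct solver available and used as the
oracle in tests. SNP-BLUP solves the ridge system
\((Z'Z + \lambda W^{-1})\,\hat\alpha = Z'(y - X\hat b)\) jointly with
the fixed effects; when markers outnumber records it switches to the
algebraically identical dual (animal-dimension) form
\(\hat\alpha = W Z'(Z W Z' + \lambda I)^{-1}(y - X\hat b)\), which
also handles zero-weight markers naturally (\(\hat\alpha_j = 0\)).
Variance components are taken from simulation truth
(\(\sigma_a^2 = h^2\), \(\sigma_e^2 = 1 - h^2\)); estimating them
would add noise without changing the questions the grid asks.

## wGBLUP

wGBLUP is a two-pass procedure: SNP-BLUP with identity weights, then
per-SNP weights
\[
W_{jj} = C \cdot \frac{1}{2S+1} \sum_{k=j-S}^{j+S} \hat\alpha_k^2,
\]
then a refit with \(\mathrm{diag}(W)\) as the effect covariance. The
scaling constant C makes the mean weight exactly 1, preserving the
total genetic variance. Choices the formula leaves open, and how the
package fixes them:

* **Window half-width S** defaults to 10 (a 21-SNP window). Windows of
  tens of SNPs are the working range for this weighting style; S is a
  first-class argument and every result records it.
* **Edges.** Windows truncate at chromosome and panel boundaries, and
  the divisor is the *actual* window size, so edge markers are not
  systematically down-weighted.
* **Passes.** Exactly one reweighting by default (`n_passes = 2`);
  more are available but not part of the standard procedure.
* **λ between passes** is held fixed; re-estimation between passes is
  not part of the procedure.
* **All-zero effects** fall back to uniform weights rather than
  erroring: the refit then reproduces GBLUP, which is the sensible
  degenerate answer.

GEBVs are the standardized-genotype design times the final effects;
the same predictions are exposed through a weighted GRM
(\(G_w = Z_s \mathrm{diag}(W) Z_s' / \sum W\), `scaling =
"standardized"`) plus the GBLUP solver, and the two routes agree to
1e-6 on random instances (a standing test). The spec-level
VanRaden-scaled weighted GRM
(\(Z\,\mathrm{diag}(W)Z'/\sum 2p(1-p)W\)) is the `weighted_grm()`
default and reduces bitwise to `grm()` at unit weights.

## Scenario evaluation

Genotyped candidates are generations 9–10. The validation set is a
fixed-size random subset of generation 10; the reference set is drawn
from the remaining candidates by a common random ordering, so
reference sets of increasing size are nested and method contrasts
within a replicate are paired (same split for every method). The
reference/validation partition is a design choice of this package —
no canonical partition exists for this study type — and validation-only
accuracy, \(\mathrm{cor}(\mathrm{TBV}, \widehat{\mathrm{EBV}})\) over
validation animals, is the defensible reading of prediction accuracy.
Validation phenotypes are masked at the split and never enter any
training computation; a data-flow test corrupts them and asserts bit
identical predictions.

`run_grid()` executes the full factorial (breed × h² × density ×
reference size × method × replicate), simulating one dataset per
(breed, h², density, replicate) and reusing it across reference sizes
and methods; results stream to CSV and completed cells are skipped on
resume. The published full-scale accuracy grid for breed A and the
rounded example cells quoted for all three breeds ship as data
fixtures, and `density_gain()` / `method_gain()` compute the
percentage-point contrasts from either fixtures or fresh results.

## Desk-scale study conditions

The full study — 7,120 historical animals, up to 777,962 SNPs, 1,000
historical generations, reference sets to 15,000 — is not a
desk-scale computation, and the package's standing suite does not
attempt its absolute accuracies. The test suite instead fixes one
reduced configuration and asserts the *orderings*:

* scale 1/50 applied to population sizes, founder counts and the
  reference grid (reference sizes {100, 160, 240, 300}); historical
  generations are rescaled by the same factor because drift time
  scales with population size — shrinking N without shrinking t would
  overshoot the target drift/LD regime, not approximate it;
* the marker panel at 1/10 (58,990 → 5,899 markers), deliberately
  less shrunk than the populations: LD range in morgans stretches as
  the effective size falls, but tagging also needs several markers
  per QTL-bearing region, and thinning the panel 50-fold pushed
  marker density below that threshold — in calibration runs the
  GBLUP-PBLUP gap at h² = 0.5 collapsed to a statistical tie with a
  1/50 panel and was restored (positive in 8 of 8 paired replicates)
  on the same populations with the 1/10 panel. `panel_scale` exposes
  this choice; it defaults to `scale`;
* breed A, 50k-analog density, h² ∈ {0.3, 0.5, 0.7}, 8 replicates with
  paired splits and nested reference sets, 100 validation animals
  (10% of the generation-10 cohort with a floor of 100), EBV-criterion
  selection (the study's selection design; each recent generation runs
  a pedigree BLUP on the records accumulated so far),
  phenotype-criterion selection;
* assertions: GBLUP above PBLUP in every cell mean; cell means
  nondecreasing in h² for all three methods; nondecreasing in
  reference size for PBLUP/GBLUP at h² ≤ 0.5; and for the wGBLUP
  advantage, a sparse large-effect architecture (5 QTL among 500
  unlinked markers, 400 training / 100 validation, 20 paired
  replicates) where weighting must not lose more than 0.01 accuracy on
  average and must win in the majority of replicates.

What passing these tests shows: the estimators, matrices and solvers
interact correctly, and the simulation produces the drift, LD,
selection response and information orderings that quantitative-genetic
theory predicts at this scale. What it does not show: the full-scale
absolute accuracy values, the per-breed differences at full founder
counts, or 770k-density behaviour, all of which require the full-size
runs (`scale = 1`) on serious hardware.

One ordering is only partially recoverable at this scale and the
suite reports it as such rather than papering over it: between
h² = 0.3 and h² = 0.5 the cell-mean accuracies are compressed to
near-equality and their ordering flips in several cells (h² = 0.7
dominates both cleanly). Two desk-scale mechanisms contribute: with
only ~12 sires, EBV selection co-selects whole families and can
intermittently collapse the genetic structure of a mid-heritability
cohort; and the weaker selection at h² = 0.3 preserves between-family
variance that parent-average information predicts easily, propping up
low-heritability accuracy under validation-only scoring. The
compression is not purely an artifact of miniaturisation: the packaged
full-scale accuracy grid itself contains a cell where the h² = 0.3
accuracy exceeds the h² = 0.5 accuracy for the same method, density
and reference size — the increase of accuracy with heritability is a
trend, not a per-cell law.

Separately, stochastic recovery checks assert that simulated
phenotypic variance is 1.0 and \(\mathrm{cor}(y,\mathrm{TBV})^2 = h^2\)
within three Monte-Carlo standard errors in cohorts of 20,000, and that
heterozygosity under pure drift decays as \((1 - 1/(2N))^t\) (the
simulator's two-sex random-mating scheme has effective size within
half an animal of N, well inside the Monte-Carlo band at the test's
N = 50, t = 30).

## Known limitations

* Strictly additive, single-trait model: no dominance, epistasis,
  genotype-by-environment, maternal effects or multiple traits.
* No sex chromosomes, CNVs or multi-allelic loci; no migration between
  historical lines; no overlapping-generation age structure beyond
  pool carry-over.
* The synthetic populations have complete, error-free genotypes and
  pedigrees; the QC missingness filters are exercised only by
  constructed fixtures, and real-data pathologies (genotyping error,
  pedigree errors, population admixture) are out of scope.
* REML machinery for variance components is deliberately minimal:
  fits use the simulation-true ratio.
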