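---
title: "Multi-breed genomic prediction with simulated cattle populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-breed genomic prediction with simulated cattle populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question

Genomic selection needs a large phenotyped-and-genotyped reference
population, which small beef-cattle breeds do not have. One remedy is a
*mixed* reference: the large breed's animals plus a screened subset of a
small breed's animals, chosen by genetic distance. `mbgpsim` simulates
this design end to end: three cattle populations with distinct
linkage-disequilibrium (LD) histories, a quantitative trait at
heritability 0.42, marker quality control, multidimensional-scaling
(MDS) donor screening at 10/15/20% mixing ratios, and genomic
evaluation with GBLUP, single-step GBLUP (ssGBLUP) and window-weighted
GBLUP (wGBLUP), scored as the Pearson correlation between genomic
estimated breeding values (GEBV) and the simulated true breeding values
(TBV) of the small population's final generation.

# The simulator

## Genome and meiosis

A `genome_map` lays out biallelic markers and QTL on 29 autosomes (desk
and micro scales use fewer; see below). Marker counts per chromosome
are proportional to map length (largest-remainder rounding), positions
are uniform, and every locus starts at allele frequency one half.
Gametes recombine with a Poisson number of crossovers per chromosome
(mean 1 per Morgan, breakpoints uniform) and mutate recurrently —
allele flips at rate 2.5e-5 per locus per meiosis, no new allele
states. The meiosis kernel is compiled (Rcpp) and draws from R's RNG,
so every run is reproducible from `set.seed()`.

## Demographic histories

Each population runs through phases of constant or linearly
interpolated census ("gradual" changes are encoded as linear ramps, the
natural reading of endpoint-only descriptions):

* **PopA** — stable at 200 for 1000 generations, then expansion to
  1000 (100 males / 900 females): slow LD decay.
* **PopB** — 500 shrinking to 200 over 1000 generations, then the same
  expansion: intermediate.
* **PopC** — stable at 1000, then contraction to 200: fast LD decay
  (largest historical Ne).

Historical generations are non-overlapping with equal sex ratios,
random mating, no selection and no migration. Dams are used as evenly
as possible within a generation (without replacement until the pool is
exhausted); sires are drawn with replacement. A consequence worth
knowing: equalized female litter counts raise the effective population
size above the census (Crow–Denniston), and the package's drift tests
use that corrected Ne, which the simulation matches.

## Chip ascertainment

Equal-frequency loci drifted through a thousand generations are mostly
fixed or rare, so a fixed panel simulated directly would not look like
a 50k chip. The package therefore simulates a *pool* of candidate loci
(`pool_factor` times the panel size, default 8) and, at the end of the
historical phase, draws the marker panel uniformly from candidates
still segregating in **all** populations — the way a multi-breed chip
is designed. Conditional on surviving long drift, allele frequencies
are near-uniform, which is what lets most panel markers pass a
MAF > 0.05 filter later. QTL are ascertained on PopA (the main
population) only; their effects are shared across breeds, so QTL fixed
in PopB/PopC simply explain no variance there — breeds differ in the
variance each QTL explains, not in its effect.

## Recent generations

Each population then goes through two stages with litter size one:

1. **Expansion** (10 generations, no selection): 250 sires / 3000 dams
   (PopB: 250/2550) drawn from the final historical generation, with
   replacement when the pool is short (a duplicated founder is a
   separate pedigree entry sharing haplotypes — the full-scale counts
   exceed the historical census, so some reuse is unavoidable). The
   breeding set is refreshed each generation from new offspring, topped
   up with current breeders where a sex runs short.
2. **Selection** (10 generations): 200 sires / 2800 dams (PopB:
   220/2335). Every animal gets a TBV (sum of QTL effects, Q coded
   0/1/2) and, with probability 0.95, a phenotype
   `y = mu + TBV + N(0, 0.58)`. Each generation a pedigree-BLUP
   evaluation (the same conjugate-gradient solver as the final models,
   `A^{-1}` with inbreeding) re-estimates EBVs from all recorded
   phenotypes; the lowest-EBV 60%/30% (PopB 50%/30%, PopC 50%/20%) of
   sires/dams are culled — ties broken oldest first, then id — and
   replaced by the top-EBV young animals.

Genotypes and phenotype records are retained for the last two selected
generations only (generation 9 trains, generation 10 validates);
pedigree is retained for all recent generations so ssGBLUP can use it.

## Trait model

QTL effect magnitudes are gamma(shape 0.4) with random signs, rescaled
by one constant so the TBV variance in PopA's historical base equals
`sigma_a^2 = 0.42` exactly; `sigma_e^2 = 0.58` stays fixed thereafter
(phenotypic variance 1, h² = 0.42 at the base). Under selection the
realized genetic variance erodes (Bulmer effect), as in any breeding
program; the calibration statement applies to the base population.

# Evaluation models

All models solve Henderson's mixed-model equations with an overall mean
as the only fixed effect, by Jacobi-preconditioned conjugate gradients
(relative residual 1e-8, capped at 10,000 iterations; non-convergence
is flagged, not hidden):

* **PBLUP** — `K^{-1} = A^{-1}` from Henderson's sparse rules with
  inbreeding (Meuwissen–Luo-style exact F via indirect column
  evaluation).
* **GBLUP** — VanRaden's centered G,
  `G = ZZ' / sum(2 p (1-p))`, `Z = M - 2p`, with observed joint
  (reference + candidate) frequencies. Observed-frequency centering
  makes G exactly singular, so G is aligned and blended,
  `G* = 0.95 G + 0.05 I` (against `A22` in single-step). The blend
  weight is exposed; 0.95 is the classic single-step default.
* **ssGBLUP** — `H^{-1} = A^{-1} + [0, 0; 0, G*^{-1} - A22^{-1}]` on
  the genotyped block; `A22` is extracted exactly from the sparse
  Cholesky factor of `A^{-1}`, and the pedigree is pruned to ancestors
  of the animals in the system.
* **wGBLUP** — two passes, no iteration beyond them: (1) SNP-BLUP with
  identity weights on the training records only (candidates never leak
  into the weights), solved exactly in the dual n×n form with
  `sigma_alpha^2 = sigma_g^2 / sum(2pq)`; (2) per-marker weights
  `W_jj = C * mean(alpha_hat^2)` over the window `[j-S, j+S]` (clipped
  at the array ends, `C` restoring mean weight 1), then a weighted GRM
  `Z W Z' / (sum(2pq) mean(w))` and a refit. The half-width default is
  `S = 20` (a 41-SNP window); the qualitative behaviour is stable for
  S in 10–50. At matched variance scaling the weighted-GRM route and
  the SNP-space route are the same model; the package implements the
  GRM route and tests the equivalence.

Variance components are fixed at the simulated truth
(`lambda = 0.58/0.42`), not REML-estimated: the study compares models,
and fixing components isolates the model differences.

# Scenario construction

Marker QC per population (individual missingness > 0.10, locus
missingness > 0.10, MAF < 0.05, exact Hardy–Weinberg p < 1e-5, in that
order — PLINK-like; "call rate < 0.10" is read as the conventional
missing-rate > 0.10) is followed by the intersection of retained
markers for each population pair. Donor screening computes 1−IBS
distances (`D = 1 - shared alleles / 2m`) among generation-9 animals of
PopA and the donor population, embeds them with classical (Torgerson)
MDS in two dimensions, and ranks donors by Euclidean distance to the
PopA centroid — "top k%" is read as the k% *closest* donors, following
the stated screening goal of genetic similarity. Mixed references are
all phenotyped generation-9 PopA animals plus the selected donors;
single-breed references are the selected donors alone. Validation is
always the donor population's generation-10 animals; their phenotypes
are never used anywhere.

# Scales, test design and what passing shows

Three bundled configurations (`simulation_preset()`):

| scale | genome | histories | censuses | use |
|---|---|---|---|---|
| full | 29 chr / 2715.85 cM, 58,990 markers, 725 QTL | 1095 gens | full | the study itself (hours) |
| desk  | 3 chr / 280.95 cM, 3,000 markers, 75 QTL | 200 gens | ÷5 | tests, acceptance runs |
| micro | 2 chr / 100 cM, 400 markers, 30 QTL | 40 gens | ÷10 | smoke tests |

Chromosome lengths at full scale taper like the bovine karyotype and
sum to 2715.85 cM; the desk genome keeps per-chromosome lengths
realistic so crossover counts per chromosome stay comparable.

The test suite checks all linear-algebra paths against dense oracles
(direct inverses, recursive kinship, closed-form H, exhaustive HWE
enumeration), degenerate reductions (ssGBLUP→PBLUP, wGBLUP→GBLUP,
H⁻¹→A⁻¹), calibration of the simulator (h², var(y), crossover and
mutation rates, the LD-decay ordering PopA > PopB > PopC, PCA
separation of the populations), and structural orderings (wGBLUP ≥
GBLUP under a large-QTL architecture; accuracy increasing in reference
size). Problem sizes in tests are the desk and micro scales with 4–20
replicates per property; the acceptance script runs two desk
replicates of the full experiment plus a six-replicate calibration.

What the desk scale does *not* show: with 75 QTL on 3,000 markers and
small censuses, within-breed prediction from even a small same-breed
reference is relatively easy, and the three populations' independent
histories mean cross-breed information is weak. At this scale the
single-breed reference can match or beat the mixed reference, and the
15%-peak / model-ordering patterns of the full-scale study are not
expected to be resolvable from a handful of replicates. Reproducing
those patterns requires the full preset (five replicates, hours of
compute), which `run_experiment(simulation_preset("full"), 5, seed)`
is written to do.

# Numerical choices and degenerate inputs

* Conjugate gradients: Jacobi preconditioner, relative residual 1e-8,
  `max_iter = 10^4`; a non-converged solve returns partial results
  with `converged = FALSE` and a warning.
* Monomorphic markers: rejected by `genomic_relationship` (division
  degeneracy); the model wrappers drop markers monomorphic in the
  joint reference+candidate set with a warning.
* MDS: only non-negative eigenvalues are used; asking for more
  dimensions than exist warns and truncates.
* Ties in selection culling: older animals first, then id order — ids
  are assigned in birth order, so the rule is deterministic.
* HWE exact test: two-sided by summing all heterozygote counts whose
  conditional probability does not exceed the observed one (with a
  1e-10 relative slack against ties); monomorphic loci return p = 1.
* Largest-remainder allocation breaks remainder ties by bin order.

# Known limitations

* No sex chromosomes, migration, dominance or epistasis, multi-trait
  genetics, or REML variance estimation (components are fixed at
  truth).
* The three populations are fully independent lineages; any shared
  ancestry in the real multi-breed setting would increase the value of
  mixed references relative to what this simulator shows at small
  scale.
* Single-step blending and frequency choices (observed vs base) are
  exposed but fixed to conventional defaults; metafounders and sparse
  approximate inverses (APY) are out of scope.
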