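---
title: "Simulating genotyping strategies for a herdbook sheep breeding programme"
author: "herdsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating genotyping strategies for a herdbook sheep breeding programme}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the package answers

Many small-ruminant breeding programmes still run on pedigree BLUP: animals
are ranked on breeding values estimated from pedigree and phenotypes alone.
Genomic selection promises faster genetic gain, but genotyping an entire lamb
crop is expensive, so the practical question is not *whether* to genotype but
*whom*: all male lambs, only a preselected share of them, females too?
`herdsim` simulates a closed herdbook nucleus — modelled on the German Merino
population, with 469 breeding rams, 7185 breeding ewes and roughly 12,900
lambs per breeding cycle — and compares seven strategies that differ only in
the share of male and female lambs genotyped, from a pedigree-BLUP reference
(`Ped`) to single-step GBLUP with every lamb of both sexes genotyped
(`GS100+100`). Outputs are per-cycle genetic gain, EBV accuracy, pedigree
kinship and marker heterozygosity, with paired significance tests across
scenarios.

## Model components and assumptions

### Founder genomes

No real genotypes ship with the package, so founder genomes are synthetic by
construction and labelled as such. They are built in three steps:

1. **Ancestral panel.** Per-marker allele frequencies are drawn from a
   symmetric Beta(0.5, 0.5), giving the U-shaped frequency spectrum of
   unascertained SNPs; 100 ancestral haplotypes are drawn independently per
   marker (no LD), and monomorphic markers are redrawn so marker indexing
   stays stable for QTL assignment.
2. **Mosaic donors.** 1570 donor haplotypes (the diploid equivalent of 785
   genotyped animals) are produced by mosaic copying: along each chromosome
   the current ancestral template is replaced by a random one at Poisson
   points with rate 1 per Morgan. Shorter rates give longer shared segments;
   with the default rate, mean r² between markers 1 cM apart clearly exceeds
   that at 10 cM and decays monotonically with distance, which is the
   qualitative LD behaviour the downstream single-step evaluation needs. The
   real panel the study system rests on is not public, and its LD-decay and
   frequency spectra are not reported anywhere we could calibrate against, so
   these defaults are chosen once as field-typical values and not tuned.
3. **Founder herdbook.** Diploids are formed by sampling donor haplotypes
   (with replacement), randomly mated for five discrete generations to create
   pedigree structure and relatedness, and the final generation becomes the
   founder breeding cohorts. Founder ages are drawn from the stationary age
   distribution of the culling model so that demography is in steady state
   from the first cycle.

The genome is 26 autosomes of 1 Morgan each (the sheep karyotype), markers
evenly spaced, 50,000 markers at full scale. Meiosis follows the Haldane
model (no interference, sex-averaged map), implemented at marker resolution:
the parental origin along a chromosome is a two-state Markov chain whose
switch probability between adjacent markers is the Haldane recombination
fraction. This composes exactly — the recombination fraction between any two
markers d Morgan apart is (1 − e^{−2d})/2 — and is fast enough to simulate
tens of thousands of meioses per cycle in pure R.

### Traits

Two traits stand for a health complex (h² = 0.1) and a production complex
(h² = 0.3). Both are purely additive with one shared set of 1000 QTL drawn
uniformly from the markers. Per-QTL effect pairs are bivariate normal; the
effect-level correlation is calibrated (by root finding on the realised
founder TBV correlation) so the founder genetic correlation equals −0.1
exactly — high-yielding animals slightly more disease-prone. Each trait is
affinely rescaled so founder TBV mean and variance are exactly 100 and 10;
residual variances follow as 10(1 − h²)/h² (90 and 23.3). Phenotypes are
own-performance records, drawn once per animal when it enters a new-breeder
cohort (selection precedes phenotyping, so candidates never have own records
at the selection step), with residuals independent across traits and no sex
effect.

### The breeding cycle

Each cycle: every ewe is mated to one ram drawn uniformly at random (no AI,
ram reuse allowed); litter sizes 1/2/3 with probabilities 0.3/0.6/0.1 (mean
1.8 lambs born per ewe); 10% lamb loss; 50/50 sex ratio. Surviving lambs are
resampled/truncated to exactly 6450 males and 6465 females so that the
explicitly stated new-breeder counts (2% → 129 rams, 20% → 1293 ewes) are
exact — the stated demographic rates slightly under-produce that lamb crop,
and we treat the cohort counts as primary because they drive
reference-population growth. Selection is truncation on a total merit index;
selected animals are phenotyped and, under genotyping scenarios, join the
reference population. Exactly as many old breeders are culled per sex as new
ones enter, sampled with weight age², which yields a stable right-skewed age
pyramid (the survival data behind the original programme are not published;
the exponent is configurable). Ten pedigree-BLUP burn-in cycles precede
cycle 0; scenarios then run ten evaluated cycles from identical copies of
the cycle-0 state.

### Genetic evaluation

Both evaluation methods solve the same two-trait animal model: trait means
as the only fixed effects, animal effects with covariance K ⊗ G0, diagonal
residual covariance. The true simulation variance components are used (no
REML); this isolates the effect of the genotyping strategy from
variance-component estimation error, which is standard practice in
simulation studies. The relationship structure K is:

* **PBLUP** — the numerator relationship matrix A over the evaluation
  window, inverse built directly by Henderson's rules with inbreeding
  (Meuwissen–Luo coefficients).
* **ssGBLUP** — the single-step H matrix: H⁻¹ = A⁻¹ plus a correction
  Ĝ⁻¹ − A22⁻¹ on the genotyped block, with Ĝ = 0.95 G + 0.05 A22 and G the
  VanRaden method-1 genomic matrix centred at observed allele frequencies
  among the currently genotyped animals. Blending weight, and the choice of
  observed rather than base frequencies, are the literature defaults; no
  further compatibility scaling of G to A22 is applied. All three are
  configurable.

The evaluation window contains the selection candidates, all animals in
service, and phenotyped animals born within the last 10 cycles, with
pedigree extended a further 7 cycles back (older ancestors are treated as
unknown). Genotyped reference animals and their records are never dropped
("no sliding base"): the reference population only grows, by 129 rams per
cycle in male-genotyping scenarios plus 1293 ewes per cycle when females
are genotyped. Genotypes of preselected-but-unselected lambs are used only
in their own selection evaluation and then discarded — such animals leave
the programme and have no descendants or records.

The mixed-model equations are solved with a Jacobi-preconditioned conjugate
gradient (tolerance 1e−8 relative residual, at most 5000 iterations; failure
to converge is an error, not a warning). The single-step correction is kept
as a dense block applied inside the operator, so the sparse pedigree part
never fills in. Equivalence with dense GLS/BLUP is enforced by test oracles
on pedigrees up to a few hundred animals for PBLUP, ssGBLUP and the
zero-genotype limit (where ssGBLUP must collapse to PBLUP).

### The selection index

Candidates are ranked on a total merit index with equal weights for both
traits. "Equal weights" is ambiguous when the two traits' EBVs carry very
different amounts of variance: at the lamb stage, parent-average EBVs of the
h² = 0.1 trait have roughly a quarter of the variance of the h² = 0.3
trait's, so a raw sum is dominated by the production trait and the realised
health:production response ratio collapses to about one third. The reported
behaviour of the programme this package models — health gains of roughly
70% of production gains, and equal relative improvements from genotyping for
both traits — is only reproduced when both traits contribute equally to the
realised selection pressure. `run_cycle()` therefore standardizes each
trait's EBV to unit spread within the candidate cohort before summing
(`index_scaling = "sd_scaled"`, the default); the raw sum remains available
(`"raw"`). The exported `tmi()` helper is the plain weighted sum.

### Reported metrics

* **Genetic gain**: cohort mean TBV in genetic standard deviations
  (√10), zeroed per run and cohort at cycle 0. Gains refer to the breeding
  cohorts *after* each cycle's replacement (the cohort that exists at the
  end of the cycle).
* **EBV accuracy**: Pearson correlation of TBV and EBV within a cohort. For
  the breeding cohorts this is computed for the cohort *in service* at the
  cycle's evaluation — every member then has an own record and usually
  progeny records. Measuring instead the post-replacement cohort mixes in
  the just-selected animals, which cannot have own records yet (phenotyping
  follows selection), and depresses the correlation by construction; the
  in-service definition is the one that describes the quality of the
  information actually used for selection decisions.
* **Diversity**: mean pairwise pedigree kinship (A_ij/2, self-pairs
  excluded, founder cohort as unrelated base) and mean observed marker
  heterozygosity, both for the breeding ram cohort.

### Common random numbers and paired tests

Within a replicate run, every scenario continues from a bit-identical copy
of the cycle-0 state and consumes the random stream in the same order
(matings, litters, survival, sexes, culling draws, phenotype residuals), so
scenario differences are driven by selection decisions, not by independent
demographic noise. Scenario comparisons therefore use paired two-sample
t-tests across runs (p < 0.05, no multiplicity correction), and significance
letters are assigned by a greedy clique cover of the non-significance graph
— two scenarios share a letter exactly when they do not differ
significantly.

## Desk-scale runs and what they can show

Full-scale study conditions (scale 1, 50,000 markers, 100 runs) are the
package defaults but take CPU-days. A single global scale factor s
multiplies every cohort size while selection proportions stay fixed, so
selection intensities are preserved. The acceptance script runs the four
scenarios it needs at s = 0.08 (38 rams, 575 ewes, ~1032 lambs per cycle)
with 1000 markers on 26 chromosomes, 250 QTL and 12 paired replicates; the
test suite exercises all seven scenarios at s = 0.05 (23 rams, 359 ewes,
~646 lambs) with the same genome and 12 paired replicates. These sizes were
chosen once, as the largest that keep the full suite and the acceptance
script within comfortable desk-scale runtimes on a single CPU.

Scaling down has known costs. Genetic drift scales with 1/N, so across-run
SDs of cycle-10 gain are several times the full-scale values, and
ratio-type summaries (relative gain over the reference) inherit that noise
in both numerator and denominator. The genomic reference population is also
~20× smaller, which caps the accuracy advantage single-step evaluation can
express. Qualitative contrasts (scenario ordering, diversity direction,
accuracy ordering between traits) are stable at this scale; exact
percentage-point reproduction of relative gains is not, and the acceptance
checks treat those targets with correspondingly wide stochastic bands.

What passing desk-scale tests does *not* show about real data: the founder
LD is a two-parameter caricature of real haplotype structure; there is no
genotyping error, no missing pedigree, no flock substructure, no trait
recording model beyond a single own record; variance components are known,
not estimated; and economic weighting of the two traits is out of scope.

## Numerical choices and degenerate inputs

* Ties in truncation selection are broken by id order — selections are fully
  deterministic given the index values.
* Monomorphic markers are redrawn at panel creation only; markers that drift
  to fixation later contribute zero to G (centred dosage 0) and are never
  filtered, so QTL/marker indexing is stable over a run.
* `build_G` errors when *all* markers are monomorphic among genotyped
  animals; the blended Ĝ is always invertible for blend < 1 since A22 is
  positive definite.
* An evaluation without a single phenotype for some trait is an error (the
  fixed trait means would be undefined), as is phenotyping an animal twice,
  a singleton cohort in kinship, or a preselection proportion outside (0, 1].
* The conjugate-gradient solver reports non-convergence as an error with the
  achieved residual rather than returning unconverged values.
* With `n_random_mating_generations = 0` the founders are direct panel
  diploids with unknown parents; the kinship base is always the founder
  breeding cohort.

## Reproducibility

Every run is fully determined by `(config, base_seed)`: per-run seeds are
derived arithmetically from the base seed, and all randomness flows through
R's global RNG seeded at defined points (founding, and once per scenario at
the shared cycle-0 fork). `scripts/acceptance.R --seed S --out F` re-runs
the scaled four-scenario experiment from scratch and writes the headline
quantities as JSON; `scripts/run_experiment.R` exposes the full experiment
(any scenario subset, any scale) and writes trajectory and summary CSVs
plus a manifest.
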