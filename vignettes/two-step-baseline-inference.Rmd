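---
title: "Two-step baseline inference for coding-sparse genomes"
author: "popbaseline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step baseline inference for coding-sparse genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Patterns of genetic variation are shaped simultaneously by demographic history
(size changes, bottlenecks, splits, migration), by purifying selection and the
background selection (BGS) it induces at linked sites, and — episodically — by
selective sweeps. Inference that ignores any of these forces tends to absorb
its signal into the others: BGS masquerades as population growth, bottlenecks
masquerade as sweeps. In a coding-sparse genome, however, there exist large
noncoding regions far enough from functional sites that they are essentially
free of BGS, and those regions can support *neutral* demographic inference.

`popbaseline` implements this two-step programme:

1. **Step 1 — demography.** Curate nonfunctional regions at least 10 kb from
   any annotated functional interval, at least 15 kb long, with accessibility
   and conserved-element masking and region-mean mutation/recombination rates
   (regions without rate information are dropped). Simulate each region under
   a 5-population Out-of-Africa (OOA) model with a coalescent engine, and fit
   the model to an 18-statistic summary vector by a coarse-then-fine grid
   search.
2. **Step 2 — DFE.** Conditional on the fitted demography, simulate functional
   (exonic) regions with a native forward Wright–Fisher engine in which exonic
   mutations draw fitness effects from a discrete distribution of fitness
   effects (DFE), so that BGS is generated mechanistically rather than
   corrected for. Divergence over a long window (nominally the 12 My to the
   human–chimpanzee split, 446,100 generations at 26.9 years per generation)
   constrains the deleterious and beneficial input.
3. **Power evaluation.** Within the fitted baseline, simulate single hard
   sweeps, scan with a composite likelihood ratio (CLR) and windowed H12, and
   summarise detectability as ROC curves.

A synthetic-data module emulates every empirical input (GFF3 annotation, BED
accessibility and conservation masks, piecewise-constant rate maps, ancestral
states, multi-population VCFs) under a *known* truth model, so the entire
chain is testable without downloads and supports parameter-recovery
experiments.

# The demographic model

Five populations: the ancestral African lineage (AFR, sampled), an unsampled
ancestral Eurasian population (EURASI), and EUR, EAS, SAS founded from
EURASI. The 25 free parameters are the ancestral African size
`N_AFR_anc`; the Bantu-expansion onset `tau_BANTU` and growth rate `r_AFR`;
the OOA split `tau_OOA` with bottleneck severity `B_EURASI` and size
`N_EURASI`; for each of EUR/EAS/SAS a dispersal time `tau_*`, bottleneck
severity `B_*`, post-founding size `N_*` and growth rate `r_*`; and seven
symmetric pairwise migration rates. Times are generations before present,
sizes diploid, rates per generation; `years_to_generations()` converts at the
fixed generation time of 26.9 years.

**Bottleneck semantics.** A population founded at time `tau` has size
`B * N_source` during a founding epoch of `founding_epoch_gens` generations
(default 100) and then recovers to its own size parameter `N`, growing at `r`
to the present. We deliberately give the founding epoch a finite default
duration rather than a single generation: a one-generation founding epoch has
a per-pair coalescent probability of only `1/(2 B N)` and would leave every
`B` parameter statistically invisible, defeating the purpose of estimating
bottleneck severities. The duration is a model constant, not a free
parameter.

**Growth.** Growth is exponential (including the Bantu expansion; an
instantaneous change can be emulated by `r = 0` plus a size parameter).

The same compiled event list drives both simulators: `compile_demography()`
feeds the coalescent backend (msprime, via a bundled Python bridge — the
engine is commodity infrastructure; all model semantics, seeding and masking
parity live in R), and `forward_trajectory()` expands it into per-generation
population sizes, founder events and migration epochs for the native forward
engine. The two routes are cross-validated against each other in the test
suite (neutral diversity and segregating sites agree within 10%).

**Parameter ranges** ship in `inst/extdata/ooa_parameter_ranges.yaml`, drawn
from the human demographic-inference literature of the Gutenkunst/Gravel era;
the registry is config-driven so another enumeration can be swapped in.
Midpoints are the documented starting point of every grid search.

# The fitting vector and the distance

For each sampled population: segregating sites per accessible site, Tajima's
D and mean r² in sliding windows (default 10 kb windows, 5 kb step); for each
of the six population pairs: Hudson's F_ST combined across variants as a
ratio of sums — 3 × 4 + 6 = 18 statistics. Windows without data are
undefined and skipped, never zero-filled. Masked bases are removed from both
numerators and denominators, and the *same* mask is applied to simulated
replicates of a region (the parity rule), so empirical and simulated
statistics are computed by the same code on the same site sets.

Choices worth stating:

* **Hudson rather than Weir–Cockerham** for F_ST (the latter is available via
  `fst(..., method = "wc")`): the ratio-of-sums Hudson estimator is robust to
  unequal sample sizes. With identical allele counts in both samples it
  equals exactly `-1/(n-1)` — slightly negative, 0 only in expectation — and
  the tests assert that analytic value rather than a spurious zero.
* **r² without a frequency cutoff**, computed as the squared Pearson
  correlation of derived-allele indicators.
* **Replicate aggregation**: per-region means and SDs across replicates; for
  display and fitting, the mean of region means is the point and the mean of
  region SDs the error bar.

The fit distance is the sum over the 18 statistics of squared residuals
scaled by the empirical across-region standard deviation of each statistic
(floored at 1e-12). It is zero iff the vectors coincide, symmetric, and
monotone in each absolute residual.

# Grid search

A full factorial grid over 25 parameters is unthinkable (3^25 points), and
the optimization strategy is therefore iterative **coordinate sweeps**: cycle
through the parameters, evaluating each parameter's grid values while holding
the others at the current best, until a full cycle brings no improvement or
the evaluation budget is exhausted. The fine stage rebuilds, for each free
parameter, a grid spanning one coarse step either side of the coarse optimum
at `refinement_factor` times the resolution (default 4; at least 2), clipped
to the declared ranges, and sweeps again starting from the coarse best — so
the final distance can never exceed the coarse one. Every evaluated point
derives its simulation seed deterministically from its coordinates and the
master seed: re-runs reproduce the trace exactly and revisited points hit a
cache.

# The forward Wright–Fisher engine

A discrete-generation diploid Wright–Fisher simulator with multiplicative
fitness across sites (genotype fitnesses `1`, `1 + h s`, `1 + s`, with `s`
signed: negative deleterious, positive beneficial; `h = 0.5` by default since
the DFE is defined on homozygotes and genic selection is the neutral choice),
Poisson recombination and mutation driven by piecewise-constant maps,
migration as per-offspring parent-source choice, founder events, and
per-generation size trajectories compiled from the demographic model.

* **DFE.** Four fixed classes on the `2 N_ref s` scale with boundaries 1, 10
  and 100 (effectively neutral, weakly, moderately, strongly deleterious; the
  top class is capped at `s = 1`, a lethal), uniform within each class, plus
  an optional beneficial class. Only exonic bases draw from the DFE; intronic
  and intergenic mutations are neutral. The shipped default mixture
  (f0 = 0.25, f1 = 0.50, f2 = 0.15, f3 = 0.10) is a package default meant to
  be representative of a human-like exonic DFE, not an estimate.
* **Burn-in and divergence.** Runs start with `10 N_ref` generations of
  burn-in at the ancestral size, followed by a divergence window (nominally
  446,100 generations; configurable) containing all demographic events.
  Post-burn-in fixations are logged with position, selection coefficient and
  element class; simulated divergence is fixations per exonic bp. Where the
  ordering of the ancient divergence window relative to the burn-in is
  ambiguous, we run burn-in first and then the full window — one consistent
  reading.
* **Rescaling.** Desk-scale runs use the standard rescaling by a factor
  `kappa`: sizes and times divided, rates and selection coefficients
  multiplied (`scale_model()` handles the model side). A scaling-consistency
  test checks that diversity is preserved across `kappa` ∈ {1, 2, 5}.
* **Mutation model.** Biallelic with continuous positions, so recurrent hits
  at a site have probability zero (the infinite-sites idealization).
* **Conditioned sweeps.** Models 1–3 introduce one beneficial mutation into
  AFR at the end of burn-in, EURASI at the OOA split, or EUR at its split,
  and require fixation (population frequency 1 at sampling) in all four
  sampled populations, in EUR/EAS/SAS, or in EUR respectively. Failed runs
  restart from a saved state at the introduction generation with fresh
  randomness — not from a fresh burn-in — and the restart count is reported;
  a configurable cap (default 10,000) turns pathological conditioning into an
  error rather than an endless loop. Note one desk-scale interaction: with
  migration rescaled by `kappa`, migrant influx into a recently founded
  population makes *literal* fixation there unreachable, so our scaled-down
  sweep experiments use the migration-free reduction of the model; at full
  scale, migration is rare enough per generation for the strict condition to
  be attainable.

# Sweep scans and power

* **CLR.** A SweepFinder-style composite likelihood ratio: the background
  site-frequency spectrum (polymorphic classes 1..n plus the fixed-derived
  substitution class, built from sweep-free simulations) is distorted by a
  sweep centered at the test position via a per-lineage escape probability
  `1 - exp(-alpha d)`, where `d` is the recombination distance from the rate
  map. Lineages that fail to escape coalesce into one; the effective sample
  of `k` escapees plus one representative is filled in by hypergeometric
  downsampling of the background spectrum. `Lambda = 2 (ln CL_sweep - ln
  CL_bg)` is maximized over `alpha` on a log grid with golden-section
  refinement; because `alpha` large recovers the background exactly,
  `Lambda >= 0` by construction. Sweep spectra are cached over the scaled
  distance `x = alpha d` on a log grid (400 points over `1e-8..1e4`), which
  keeps resolution where the likelihood is most sensitive; the test suite
  checks the scan against a brute-force dense-grid oracle.
* **H12.** Haplotype homozygosity with the two most frequent classes pooled,
  evaluated at each SNP with the SNP at the window center, over widths 1, 2,
  5, 10, 20 and 40 kb. Haplotype identity is exact match over the window's
  unmasked SNPs.
* **ROC.** Replicate-level power: a sweep replicate is summarised by its
  maximum score within `tp_radius` (default 1 kb) of the true sweep site, a
  null replicate by its genome-wide maximum; thresholds sweep the pooled
  scores. The trapezoid AUC equals the Mann–Whitney statistic on the
  replicate maxima (asserted to 1e-9). Site-level bookkeeping is available
  behind `level = "site"` since the replicate-level definition, though
  standard, is one of two readings.

# The synthetic-data generator

`generate_genome()` draws gene intervals (uniform lengths; either scattered
uniformly, which yields exponential-like intergenic gaps, or regularly
spaced), inaccessible blocks of geometric length (mimicking the clumping of
real accessibility masks), conserved blocks restricted to noncoding sequence
(whose only role is to be masked by curation), piecewise-constant rate maps,
and a random ancestral sequence; `generate_polymorphism()` simulates the
chromosomes under a truth model (honouring the rate maps), drops inaccessible
sites, and writes per-chromosome VCFs with ancestral-allele annotation, a
sample panel, and a truth record that inference code never reads. With a
fixed seed every emitted byte is reproducible.

What the generator does *not* emulate: sequencing error, missing genotypes,
multiallelic sites, gene conversion, realistic gene-length and rate
distributions, and correlation between functional density and recombination.
Passing tests on synthetic data therefore demonstrate the correctness and
statistical behaviour of the machinery under the stated model, not robustness
to real-data artefacts.

# Desk-scale study conditions

The test suite and the acceptance script run everything at sizes a laptop
core handles in minutes; the vignette states them once as the package's
choices:

* Neutral calibration: a single-population reduction (N = 500,
  mu = r = 1e-8, 100 kb, 200 replicates) against E[pi] = 4 N mu; the same
  scenario through the forward engine at `kappa = 5`, with 600 replicates on
  each side of the forward/coalescent comparison so Monte Carlo error does
  not dominate the 10% agreement bound.
* Parameter recovery: a 3-parameter reduction (`N_AFR_anc`, `tau_OOA`,
  `B_EURASI`; all other parameters clamped to truth), truth at
  (5000, 1500, 0.05) — a grid point of the 3-point coarse grid — with 20
  regularly spaced ~17 kb curated regions x 20 replicates, 8 diploid samples
  per population, coarse 3-point grids, fine refinement 2. The severe-
  bottleneck truth point is deliberately in the informative part of the
  range: bottleneck severity and split time partially compensate for one
  another (a likelihood ridge), and at desk-scale sample sizes a
  near-boundary mild bottleneck is not resolvable at fine-grid resolution.
* BGS: one functional region, deleterious mass concentrated in the
  moderately deleterious class (where the linked footprint of a compact
  region is largest), N = 200, mu = 5e-6, r = 2e-7, deleterious fractions
  {0, 0.25, 0.5}, 50 replicates each; intergenic pi must fall monotonically.
* Beneficial input: fractions {0, 0.1, 1, 10}% of new exonic mutations with
  `2 N s_b` in [100, 1000), N = 100, 300-generation window, 50 replicates;
  exonic divergence must rise monotonically — the mechanism behind rejecting
  a 10% beneficial rate as incompatible with observed divergence.
* Sweep power: the `kappa = 25`, migration- and growth-free reduction of the
  OOA model, a 2-functional-region chromosome, a conditioned recent hard
  sweep in EUR at the strongest scaled selection, 30 sweep + 60 sweep-free
  replicates (20 + 40 in the acceptance script), 25 diploid EUR samples,
  per-replicate rate maps drawn uniformly around the mean. Because the
  selection coefficient saturates at `s = 1` under the rescaling, the
  hitchhiking footprint `~ s / (r ln 2Ns)` spans tens of kb — comparable to
  the whole simulated region — so true positives are scored within a
  footprint-scale radius (20 kb) of the introduction site rather than the
  1 kb default that suits localized sweeps. CLR and H12 should each separate
  sweep from null (AUC > 0.8) while a null-vs-null placebo (averaged over
  seeded half-splits of the null set) sits near 0.5.

# Known limitations

* The coalescent engine is external commodity software reached through a
  text bridge; errors there surface with the offending parameter set, but
  performance depends on a working `python` with msprime on the PATH.
* The CLR implementation follows the published sweep-spectrum construction
  but is not a byte-for-byte reimplementation of any particular external
  binary; its scores are validated against a brute-force oracle and against
  detectability properties, not against another program's output files.
* Coordinate-sweep grid search is a local strategy: with strongly confounded
  parameters it can settle on a ridge point. The search trace is returned so
  users can inspect the surface; multi-start search is a straightforward
  extension via the `start` argument.
* Strict-fixation conditioning interacts with rescaled migration as
  described above.
* The Weir–Cockerham F_ST flag uses haploid allele-count variance
  components; it is provided for comparison, not as the primary estimator.
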