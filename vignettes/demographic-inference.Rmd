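---
title: "Composite-likelihood demographic inference from joint SNP spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite-likelihood demographic inference from joint SNP spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

sfsdemo fits event-based three-population demographic models to the joint
site frequency spectrum (SFS) of unlinked biallelic SNPs, ranks candidate
models by AIC, attaches parametric-bootstrap uncertainty to the winner, and
asks whether co-distributed taxa share the timing of a divergence. It was
built for comparative phylogeography of structured bird populations — the
motivating system is a set of antbird species complexes split into an
Andean cluster (A), a northern Atlantic Forest cluster (B), and a
central–southern Atlantic Forest cluster (C) — but nothing in the machinery
is taxon specific.

## The model family

A `demographic_model` is a rooted three-leaf population tree, by default
`((A,B),C)`, decorated with events:

* **splits** at `tdiv_AB` and `tdiv_ABC` (years), each written as the pair
  of child populations merging into their ancestor;
* **admixture pulses**: at time `tmig`, a fraction `p` of the destination
  population derives from the source population (forward in time). Looking
  backward, every destination lineage independently jumps to the source
  with probability `p`;
* **size changes**, **bottlenecks** (an instantaneous multiplier in (0, 1)
  applied to all older times), and **exponential growth** at a
  per-generation rate up to a stated time.

Candidate sets are data: one YAML document per model, shipped in versioned
per-taxon catalogs (`model_catalog_dir()`), with free parameters declared
as bounds and fixed parameters as values. The two best-supported published
scenarios are pinned exactly — a four-pulse divergence-with-migration model
with 13 free parameters (three sizes, two split times, four pulse times,
four pulse fractions) and the same model plus one growth rate (14) — and
are flagged `status: transcribed`; the remaining members are composed from
the published category descriptions (`status: inferred`) with their free-
parameter counts matched to the published tables wherever those are
internally consistent. Catalogs are editable without touching code.

Ancestral population sizes are not estimated separately by default: each
ancestor's size is tied to the size of the lineage it continues (the
outer-leaf lineage), with per-model overrides (`ne:` map) where a catalog
member frees them. Two published pulses are reported between the joint
"A–B" cluster and C at times more recent than the A/B split, when no joint
ancestor exists yet; the simulator interprets such a pulse as acting on the
pair, splitting its intensity evenly across A and B (two sequential
backward pulses with combined probability `p`). Pulse times equal to the
relevant split time are allowed; pulses sort before splits at equal times.

## Simulation and the expected spectrum

The engine is a structured coalescent in continuous time (exponential
waiting times; sample sizes are far below the effective sizes, where the
Moran/Wright–Fisher and coalescent descriptions agree). Within a
population of current diploid size `Ne(t)` each lineage pair coalesces at
rate `1/(2 Ne(t))` per generation; growth makes the rate integrable in
closed form. Times are stored in years and converted with the generation
time at simulation time; defaults are a mutation rate of 2.5e-9 per site
per generation and 2.33 years per generation, the values standard for
thamnophilid antbirds.

The expected joint SFS is Monte Carlo: each replicate genealogy's branches
deposit their lengths into the cell of the configuration they subtend, and
cells are normalized over the configurations polymorphic in the total
sample (the package's conditioning convention; the alternative of
conditioning per population is not offered). A dataset simulator draws one
segregating site per locus — a branch chosen proportionally to length —
matching the one-random-SNP-per-locus reduction used upstream of SFS
methods, pairs allele copies into diploids, and masks genotypes
independently at the requested missing rate. An infinite-sites mode
(Poisson mutations on branches) backs the sequence-level diversity
statistics. All randomness comes from a locally seeded generator in the
compiled code, so identical inputs are bit-reproducible and independent of
R's global RNG.

## Likelihood, optimization, numerics

The objective is the multinomial composite log-likelihood
`sum_c n_c log pi_c` over polymorphic cells, with observed counts possibly
fractional: sites with missing genotypes are projected to fixed per-
population sizes by expected hypergeometric downsampling (default sizes:
80% of the per-population maximum called copies, rounded down to an even
count). Projection mass falling on configurations monomorphic after
projection is dropped and accounted; retained mass plus drops always
equals the input site count. Folding (joint, on the total minor allele,
lexicographic tie at exactly half) is available for data without reliable
ancestral states.

Numerical choices that matter:

* **Probability floor.** An observed cell with zero Monte-Carlo mass would
  have `log 0`; it receives a floor instead (1e-30 when reporting, 1e-8
  inside the optimizer, where a harsher floor would let rare tail cells
  dominate the search).
* **Common random numbers.** Within one optimization start every
  likelihood call reuses one simulator seed, making the Monte-Carlo
  objective a deterministic function that Nelder–Mead can descend; each
  start gets a fresh seed and a fresh log-uniform initial point. The first
  start is always the geometric midpoint of the bounds, and callers can
  inject warm starts (e.g. a nested model's solution extended with pulse
  fractions at their lower bound); bootstrap refits warm-start at the
  generating parameters.
* **Restart polish.** Each Nelder–Mead run is restarted once from its own
  optimum; re-inflating the collapsed simplex routinely escapes premature
  convergence and measurably improves nested-model comparisons.
* **Re-scoring before ranking.** Optimized models are re-evaluated at
  their fitted parameters under one shared seed and more replicates before
  AIC ranking (`rescore_fits()`), removing between-fit seed noise from
  model comparisons.
* **Bounds and penalties.** Parameters are searched on the log scale
  inside declared boxes; structurally invalid points (a pulse older than
  the split merging its populations, inverted split times) receive a
  smooth penalty that slopes back toward the valid region. Ties in the
  maximized likelihood break toward the smaller log-parameter norm.
* **Ranking conventions.** Weights are reported as the relative likelihood
  `exp(-dAIC/2)` — the convention of the published tables, where the best
  model has weight 1 — with `normalize = TRUE` giving textbook Akaike
  weights; ranks are strict (1, 2, 3, ...) with ties broken by model name.

## The shared-divergence comparison

`test_shared_divergence()` decides between one shared divergence time and
free per-taxon times by profile likelihood on a common grid: for every
taxon the composite log-likelihood is profiled at each of 21 log-spaced
candidate times (the remaining parameters re-optimized with the split
pinned, warm-started along the grid) under taxon-specific common random
numbers. Both hypotheses then read the same deterministic curves — the
free hypothesis takes each curve's own maximum, the shared one maximizes
the summed curves — so their likelihood difference is non-negative by
construction and free of Monte-Carlo seed noise, and the decision reduces
to AIC with the shared model saving one parameter per additional taxon.
This design emerged after joint full-parameter fits proved too noisy for
the one-unit AIC margin that separates the hypotheses when times truly
coincide; at that margin the comparison sits at its statistical limit
(the shared model is preferred with probability P(chi-square_1 < 2),
about 0.84, when the truth is shared).

## What SNP-only spectra cannot tell you

The package's central caveat: with one SNP per locus and a likelihood
conditioned on polymorphism, the composite likelihood is **exactly
invariant** to multiplying every effective size and every time by a common
factor (the normalized SFS depends only on relative branch lengths). The
data identify shapes — time/size ratios, pulse fractions — but not the
absolute scale. This is not an implementation artifact: a fixed per-site
mutation rate cancels from the conditioned likelihood, and the study
system's own analyses acknowledge the strong dependence of time estimates
on the assumed sizes. Consequences inside this package:

* Absolute divergence-time recovery with all sizes free is a lottery along
  the flat ridge; the validation experiment `validate_recovery()` measures
  it honestly and, with free sizes, fails the within-factor-two target.
  `anchor_sizes()` fixes the size parameters at a declared reference
  (presets use 2e5 diploids), after which times are identified and the
  same experiment recovers the deep divergence within a factor of two in
  essentially every replicate.
* The shared-divergence comparison anchors the template's sizes for the
  same reason: with sizes free, a shared-time model can fit taxa whose
  true times differ four-fold by rescaling each taxon's sizes, and the
  comparison would be vacuous.
* Percentile bootstrap intervals for absolute times inherit both the ridge
  and the Monte-Carlo floor bias and under-cover at desk scale; the
  coverage experiment reports this rather than hiding it.

## The synthetic-data generator

`table5_presets()` reproduces the four published best-fit scenarios as
generating truths: the published point estimates for split times, pulse
times and fractions (a dash in the published table — a pulse not estimated
— becomes the parameter's lower bound, effectively absent), the published
SNP-matrix sizes (1845–2036 loci) and missing-data rates (1.5–10.41%), the
expansion model for the antvireo and the four-pulse model for the other
three taxa. Effective sizes were not published; presets declare 2e5
diploids — a typical order of magnitude for these antbirds — and record
that choice in the truth file. Sampling defaults to 8 diploids per
population.

What the generator deliberately does not emulate: sequencing error,
genotype-call uncertainty, linkage within loci (irrelevant at one SNP per
locus), Z-linked loci, selection, and non-random missingness. Passing
tests therefore demonstrate correctness of the inferential machinery under
the model's own assumptions, not robustness to real-data artifacts.

## Validation experiments and problem sizes

The `validate_*()` functions are the package's simulation studies, run by
the test suite and by `scripts/acceptance.R` at these sizes (chosen as
desk-scale versions of the full analysis, which would use 100 optimizer
starts and 100 bootstrap replicates):

* expected-SFS oracle: one population, 10 haploids, 1e5 replicates against
  the analytic `1/i` spectrum;
* recovery: 10 datasets of 2000 SNPs, 8 diploids per population, fits with
  20 starts (free sizes) or 6 (anchored);
* bootstrap coverage: 20 outer replicates of 300 SNPs with 8 bootstrap
  refits each;
* barrier-model discrimination: 20 datasets of 1000 SNPs, three candidate
  models, warm-started and re-scored under common random numbers;
* shared divergence: 20 replicate taxon pairs per scenario, 800 SNPs per
  taxon;
* neutrality: 500 infinite-sites loci, 20 sequences, for the constant-size
  and recent-expansion regimes.

## Known limitations

* No exact (matrix-exponentiation) expected SFS; the Monte-Carlo engine
  plus analytic oracles covers desk scale, and an exact backend would slot
  behind `expected_sfs_mc()` without interface changes.
* No continuous migration — the model vocabulary is discrete pulses only,
  matching the study design.
* Total haploid sample size is capped at 60 allele copies (the leaf-set
  bitmask of the engine).
* The composite likelihood treats SNPs as independent; confidence
  statements lean on the parametric bootstrap rather than on curvature.
* AMOVA, haplotype networks, Bayesian species trees and migration-surface
  estimation are out of scope; established packages cover them.
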