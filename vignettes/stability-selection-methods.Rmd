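---
title: "Methods: mutational stability effects and selection on folding and binding"
author: "mutstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutational stability effects and selection on folding and binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutstab)
```

## The scientific problem

A viral coat protein must fold, and folded copies must bind each other to
assemble a capsid. Every amino-acid substitution perturbs both free
energies: the folding stability of the monomer
($\Delta\Delta G_{fold}$, kcal/mol, positive = destabilizing) and the
binding stability of the oligomer it assembles into
($\Delta\Delta G_{bind}$). For an $n$-copy complex (here a pentamer,
$n = 5$) the binding free energy follows the thermodynamic cycle

$$\Delta G_{bind} = \Delta G_{interaction} - n\,\Delta G_{fold},$$

and substitution effects are differences between the substituted and
reference proteins, computed by `ddgBindFromCycle()`.

Not every amino-acid change is evolutionarily available in one step: a
codon reaches at most nine neighbor codons by a single nucleotide
mutation, and after discarding synonymous and nonsense changes, typically
five to seven amino-acid targets per site remain out of nineteen. The
package calls this one-DNA-change set the *accessible* pool
(`enumerateAccessible()`), and contrasts it with *observed* substitutions
— changes actually fixed in wild relatives of the reference phage
(inferred by consensus comparison, `consensusSubstitutions()`) or in
laboratory adaptation experiments (an `Experiment` registry).

The package asks three questions of such data:

1. Do observed substitutions cluster inside a *stability zone* around
   zero more than random draws from the accessible pool would
   (`randomizationTest()`)?
2. What *selection surface* over
   $(\Delta\Delta G_{fold}, \Delta\Delta G_{bind})$ best explains the
   observed set given the accessible density
   (`fitSelectionSurface()`)?
3. How far do *cumulative* stability changes travel over the course of
   an adaptation relative to the range of single-substitution effects
   (`cumulativeTrajectory()`, `individualEffectRadius()`)?

## The randomization test

For an observed set of size $m$ and a closed zone $[lo, hi]$ (defaults
$[-2, 2]$ and $[-3.5, 3.5]$ kcal/mol), each of `reps` replicates draws
$m$ substitutions without replacement from the accessible pool and
counts how many fall in the zone by folding, by binding, and by both
jointly. The two-sided p-value for each criterion is twice the
proportion of replicates whose count is greater than or equal to the
real count (ties included), capped at 1. We report a zero tail count as
"p < 2/reps" rather than 0 in the show method; an optional add-one
estimator ($2(k+1)/(\text{reps}+1)$) is available behind a flag and off
by default. Closed-interval zone membership is deliberate: boundary
values count as inside. All replicates flow from a single seed, so
results are exactly reproducible.

## The selection-surface model

The observation model assumes the probability of seeing a substitution
with a given stability pair is proportional to the product of

* the accessible-substitution density at that point, estimated by
  gridding $[-3, 3]^2$ into $0.25$-kcal/mol cells and taking cell
  proportions (`gridAccessibleDensity()`), and
* a selection function: a bivariate normal
  $(\mu_{fold}, \mu_{bind}, \sigma_{fold}, \sigma_{bind}, \rho)$
  truncated to the same square, evaluated at cell centers and
  renormalized over the square (`truncatedBvnCellDensities()`).

Because that product defines a probability distribution over cells, the
fitted score is the weighted log-likelihood

$$\sum_i w_i \log \frac{A(c_i)\, s_\theta(c_i)}
  {\sum_c A(c)\, s_\theta(c)},$$

where $c_i$ is the cell of observation $i$ and $w_i$ its experiment
multiplicity. The denominator matters: without it the accessible terms
are constant in $\theta$ and the fit would simply match the observed
cell distribution, ignoring the shape of the accessible pool — the
model would then be unable to separate "selection prefers small
effects" from "small effects are common among mutations". With the
normalizer the estimator is the maximum-likelihood fit of the stated
generative model, and simulation (the parameter-recovery tests) shows
it recovers known surface means from data generated under that model.

Fitting is an exhaustive scan over a parameter lattice, defaults
$\mu \in [-1, 1]$ step $0.1$, $\sigma \in [0.25, 1.5]$ step $0.0625$,
$\rho \in [-0.9, 0.9]$ step $0.1$ (about 3.7 million combinations; the
$\rho = \pm 1$ endpoints are excluded because the covariance is
singular there). The scan is vectorized so that for each
$(\sigma_{fold}, \sigma_{bind}, \rho)$ triple the normalizer and the
observation terms for *all* mean pairs come from a few matrix
operations; the full scan runs in minutes on one core, and a documented
coarse lattice (`coarseSurfaceLattice()`: $\mu$ step $0.25$,
$\sigma \in \{0.5, 0.75, 1, 1.25\}$, $\rho \in \{-0.5, 0, 0.5\}$) runs
in under a second and is what the tests use.

Numerical edge policies, all surfaced in results and the run manifest:

* **Out-of-bounds observations** (the grid stops at $\pm 3$ but real
  observed effects can exceed it) are clamped to the nearest boundary
  cell; the count is reported as `nClamped`.
* **Zero-mass accessible cells** containing an observation would score
  $-\infty$; their mass is floored at $1/(2\,|\text{pool}|)$ — half the
  smallest observable mass — with a warning, and counted in `nFloored`.
* **Ties** in the scan are broken by the first maximum in lexicographic
  $(\mu_{fold}, \mu_{bind}, \sigma_{fold}, \sigma_{bind}, \rho)$ order,
  making the argmax deterministic.

## Trajectories

Laboratory adaptations may branch; segments form a rooted tree and each
carries the substitutions fixed along it. `cumulativeTrajectory()`
starts the root at $(0, 0)$ and adds each segment's summed
$\Delta\Delta G$ pair to its parent's point, so endpoints are invariant
to substitution order within a segment. `individualEffectRadius()` is
the largest Euclidean norm among single-substitution effects — the
radius of the circle cumulative endpoints are compared against. When
the within-experiment order of substitutions is unknown only
segment-level sums are produced.

## The synthetic-data generator

`synthDdgTable()` builds a complete $19 L$ table whose defaults encode
the study conditions the package targets: $L = 426$ residues, and
accessible pools that are $72.9\%$ (folding) and $70.0\%$ (binding)
destabilizing. Two design points deserve emphasis:

* **Accessibility is genetically coherent.** A random coding sequence
  consistent with the protein is simulated (random synonymous codon per
  residue) and accessibility flags come from `enumerateAccessible()` on
  it — so per-site target counts, their $\le 9$ bound, and the overall
  accessible fraction (about $6/19$ of all substitutions) follow from
  the genetic code rather than from a tunable rate.
* **Calibration by shift.** Each axis is drawn from a two-component
  normal mixture (narrow core, broader right-shifted tail — chosen to
  resemble empirical accessible-effect histograms; illustrative, not
  fitted) and rigidly shifted so the realized destabilizing fraction
  among accessible substitutions equals the target to within $1/n$.
  Targets of exactly 0 or 1 are rejected as infeasible.

`synthObservedUnderSelection()` then samples accessible substitutions
without replacement with probability proportional to a known truncated
selection surface — the exact generative model the fit assumes — and
`synthExperiments()` wraps draws into linear or binary-branching
registries with the 12:13:4 high/normal/variable temperature mix of the
compiled adaptation data.

What the generator does *not* emulate: spatial correlation of effects
along the structure (interface versus core residues), any fold–bind
correlation (axes are independent by construction), FoldX's energy
function, or real mutational biases (no transition/transversion or
codon-usage weighting). Passing tests therefore demonstrate the
statistical machinery is correct under the assumed model, not that the
model describes any particular protein.

## Problem sizes and test design

The test suite exercises enumeration at full protein scale
($L = 426$, 8094 substitutions), table calibration at the same scale,
randomization calibration with 200 simulations of 2000 replicates, and
surface recovery with 20 independent observation sets of $n = 200$
fitted on the coarse lattice — sizes chosen so the whole suite runs in
a few minutes while keeping Monte-Carlo error well inside the asserted
tolerances. The randomization oracle on pools of $\le 8$ is exact
subset enumeration; the enumeration oracle is brute-force point
mutation plus independent translation; the surface-score oracle is a
naive per-observation loop.

## Known limitations

* Consensus ancestral inference is majority-rule only; ties error
  unless a first-in-alphabet policy is requested, and no phylogenetic
  weighting is applied.
* The selection-surface scan offers no confidence intervals; the
  lattice bounds the precision of $\hat\mu$ at one step.
* The p-value accompanying the fold–bind correlation uses the standard
  t approximation for a Pearson correlation.
* GenBank parsing covers simple, complement and join CDS locations
  only; anything more exotic should be converted to FASTA first.
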