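---
title: "Ensembling residue-residue contact predictions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensembling residue-residue contact predictions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contactens)
```

## The problem

A residue-residue *contact* is a pair of amino acids whose representative
atoms — the C-beta atom, or C-alpha for glycine — lie within 8 Angstrom of
each other in the folded protein. Predicted contact maps are among the most
informative one-dimensional-sequence-to-structure annotations: a
sufficiently accurate contact set essentially determines the fold. Modern
deep networks predict, for every residue pair, a full probability
distribution over *binned* distances (a "distogram") rather than a binary
contact call, and different networks use different discretizations of the
distance axis.

`contactens` implements the complete evaluation and ensembling pipeline for
such predictions:

1. convert distograms to contact probabilities at the 8 A threshold,
2. average contact probabilities across heterogeneous methods into an
   ensemble prediction,
3. select the top-L most probable contacts per sequence-separation class,
4. derive ground-truth labels from experimental structures, and
5. score predictions with ceiling-normalized top-L precision and compare
   methods with Jaccard distances.

A synthetic-benchmark module generates folded toy chains and families of
noisy predictors with controllable accuracy and inter-predictor error
correlation, so the central claim — that averaging diverse,
comparably-accurate predictors beats each individual predictor — can be
demonstrated and regression-tested entirely in code.

## From distograms to contact probabilities

A bin scheme is the ordered set of distance edges a network uses, optionally
preceded by a "no contact / beyond range" bin that absorbs the mass of pairs
farther than the last edge. The contact probability of a pair is the total
probability mass at distances up to 8 A. Within a bin we model mass as
uniformly distributed over the bin's span, so the bin straddling the
threshold contributes the fraction `(threshold - lower_edge) / bin_width`
of its mass. That integration model is what makes the straddling-bin share
well-defined; for a 64-bin scheme spanning 2-22 A the 8 A threshold falls
20% of the way into bin 19 (0-based), so bins 0-18 count in full plus 20%
of bin 19:

```{r}
contact_bin_summary(scheme_alphafold(), 8)[c("full", "fractional_bin", "fraction")]
```

For a scheme of 0.5 A bins starting at 2 A with a leading no-contact bin,
the threshold coincides with a bin edge and bins 1-12 are included exactly,
with no fractional share:

```{r}
contact_bin_summary(scheme_trrosetta(), 8)[c("full", "fraction")]
```

Two boundary conventions are fixed deliberately. First, probability mass
below the first edge (physically impossible distances, e.g. < 2 A) counts
as contact: such mass means the network is confident the pair is very
close, and excluding it would understate contact probability. Second, the
no-contact bin always gets weight zero regardless of threshold. If the
threshold does not exceed the smallest edge, no mass can qualify: the
weight vector is all zeros and a warning is raised rather than an error,
since the operation is well-defined, just vacuous.

The 10-bin preset (`scheme_prospr()`) is a documented *reconstruction*: the
network's public description fixes that bins 0-2 count as contact but not
the edge positions, so the preset uses 10 equal-width bins with the first
three spanning exactly 0-8 A. Analyses that depend on that network's exact
edges should supply them explicitly via `bin_scheme()`.

Asymmetric tensors are symmetrized on construction by averaging the (i,j)
and (j,i) distributions, with a warning: networks are near- but not exactly
symmetric, and the contact relation itself is symmetric.

## Contact classes, top-L selection and labels

Pairs are classed by sequence separation `s = |i - j|`: short (6-11), mid
(12-23), long (24+); pairs with `s < 6` are excluded from evaluation. In
each class the `L` most probable pairs are declared contacts, where `L` is
the *full target sequence length*, not the resolved-structure length —
predictions are made for the whole sequence, and using the structure length
would silently change the selection size per target. Ties are broken
deterministically (probability descending, then `i`, then `j` ascending) so
outputs are bit-stable; with zero-probability ties this means the
lexicographically smallest pairs fill out the selection.

Labels come from structures: representative-atom (C-beta / glycine
C-alpha) distances between every residue pair, with residues that disagree
with the prediction sequence at their position removed (positional
comparison, no realignment — structures are assumed already mapped to
target numbering). For NMR-style multi-model files the per-pair distances
are averaged across models, a pair being unresolved only if unresolved in
every model. Pairs at `<= 8` A ("8 A or less", so the boundary counts) and
`s >= 6` are true contacts.

Predicted pairs touching structurally unresolved residues cannot be
verified and are dropped before precision is computed: an unverifiable
prediction must count neither for nor against a method.

## Scoring: precision with a ceiling

Contact predictors make no negative predictions, so accuracy reduces to
precision, `TP / (TP + FP)`. A target-class with fewer than `L` true
contacts cannot reach precision 1 under top-L selection: its best
achievable precision is the *ceiling* `min(1, n_true / L)`. Normalizing by
the ceiling — equivalently scoring `TP / min(L, n_true)` — puts every
target-class on a 0-1 scale. A class with no true contacts at all is
*skipped* (not scored 0 or 1): a vacuous class carries no information about
the predictor and either constant would bias the averages.

Aggregation is macro: per class, the mean over targets where the class is
defined; overall, the mean of the three class means. A pooled micro average
(summed TP over summed `min(L, n_true)`) is available behind
`aggregate_evaluations(..., micro = TRUE)` for comparison.

Method similarity uses the Jaccard distance
`d_j = (|A ∪ B| - |A ∩ B|) / |A ∪ B|` between top-L contact sets, reported
per class plus the unweighted mean of the three class distances; two empty
sets are at distance 0 by convention.

## Ensembling

An ensemble is the per-pair arithmetic mean of its members' contact
probabilities — no weighting, no stacking. For RR-file members the default
`zero_fill` policy treats unlisted pairs as probability 0, the literal
reading of averaging fixed-size probability objects when groups submit only
confident pairs; `average_available` (mean over reporting members only) is
offered for distogram-derived maps where every pair is genuinely defined.
Ranked sub-ensembles ("top 20% of methods") take the first
`ceiling(fraction * n)` methods — the only rounding consistent with a 20%
cut of 33 methods selecting 7.

## The synthetic benchmark

`gen_chain()` grows a coarse-grained chain (one representative point per
residue) as a self-avoiding random walk: fixed 3.8 A steps (the C-alpha
virtual bond length), a 3.5 A excluded-volume radius between non-adjacent
residues, and a step-direction bias toward the centroid of the partial
chain. The compaction strength (default 0.4) was chosen once so that chains
of L >= 60 reliably form a globule with contacts in all three separation
classes, including long-range; sequences are drawn from approximately
natural amino-acid frequencies (about 7% glycine, so the glycine C-alpha
rule is exercised). The generator emulates contact *density and class
structure*, not protein geometry: there is no secondary structure, no
side-chain packing, and no sequence-structure relationship, so passing
tests demonstrate correctness of the pipeline and of the ensembling
mechanism, not predictive performance on real proteins.

A simulated predictor perceives each true distance `d` with additive
Gaussian error decomposed into a family-shared and a private component:

    d' = d + rho * shared + sqrt(1 - rho^2) * own,   own ~ N(0, sigma)

with the shared field drawn once per target at the same scale, so the
marginal error is `N(0, sigma)` for every `rho`. `rho = 0` gives
independent (maximally diverse) predictors, `rho = 1` identical ones. The
predictor then emits a distogram by discretizing `Normal(d', dist_sd)` over
its bin scheme (`dist_sd = max(sigma, 0.5)` A by default; the floor keeps
the emitted distribution proper in the noiseless limit). Mass below the
first edge joins the first bin, mass beyond the last edge goes to the
no-contact bin when present, otherwise to the last bin, so rows sum to 1
exactly. Because the integrated contact probability is strictly decreasing
in `d'` near the threshold, `sigma = 0` makes top-L selection recover the
true contacts exactly — the end-to-end identity used in the tests.

This is the simplest mechanism that reproduces the ensembling argument:
averaging cancels the private error components but not the shared one, so
the ensemble's gain over its best member is largest at `rho = 0`, shrinks
as `rho` grows, and vanishes at `rho = 1`. `ensemble_experiment()` runs the
full comparison (k predictors plus their mean ensemble, scored per class
and aggregated over targets, with pairwise Jaccard distances):

```{r, eval = FALSE}
exp <- ensemble_experiment(n_targets = 100, L = 100, k = 3,
                           noise_sd = 2, rho = 0, seed = 1)
exp$summary
```

The regression suite asserts this at 100 targets of L = 100 with three
predictors at sigma = 2 A under three seeds (ensemble long-range accuracy
strictly above every individual) and checks the gain is non-increasing over
rho in {0, 0.5, 1}; the unit suites use smaller sizes (3-50 targets,
L = 25-80) to keep runs fast. All randomness descends deterministically
from explicit integer seeds through a fixed derivation, so every stochastic
check reruns bit-stably.

## Numerical and design notes

* Distogram validation tolerances: per-pair sums within 1e-6 of 1,
  symmetry within 1e-6 (then symmetrized by averaging).
* Contact probabilities are clamped to [0, 1] after integration to absorb
  float round-off; the diagonal is zeroed.
* RR probabilities are written with 6 decimals; round-tripping is exact at
  that precision.
* `rank_methods()` breaks accuracy ties by method id so rankings, and
  hence top-fraction ensembles, are reproducible.
* Unresolved pairs propagate as `NA` distances; they are excluded from
  labels and from scoring denominators.
* Multi-chain structure files: only the requested (or first) chain is
  read; the choice is logged.

## Limitations

* The synthetic error model is Gaussian on perceived distance; real
  network errors are heteroscedastic, distance-dependent and structured
  along the sequence. Conclusions about *how much* ensembling helps on
  real predictors cannot be read off the simulation.
* Reconciliation is positional; structures whose numbering does not match
  the target sequence need realignment upstream.
* The extended RR "distance" format and multi-model RR files are out of
  scope, as are CASP Z-scores and precision at L/2 or L/5.
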