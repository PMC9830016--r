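---
title: "Methods: comparative analysis of behavioral niche and morphology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analysis of behavioral niche and morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mygacomp)
```

This vignette documents the models, algorithms and design decisions
behind `mygacomp`. The package implements a complete comparative
pipeline for discrete behavioral and morphological characters on
genus-level phylogenies — the kind of data produced by scoring spider
retreat-construction behavior (opportunist / obligate burrower /
nest-builder; web / open / turret / collar / trapdoor / purse entrance)
and ~55 somatic characters across ~110 genera — together with a
synthetic-data generator so that every stage can be validated without
access to any particular empirical matrix.

## Data model

A `charMatrix` stores one *state set* per cell: a singleton for an
ordinary score, two or more states for a polymorphic genus, the empty
set for missing data. This is the native currency of all downstream
code — parsimony treats a polymorphic tip as free to take any of its
observed states, likelihood gives it partial likelihood 1 on each
observed state, Gower treats intersecting state sets as potential
agreement, and the pairwise-comparison stage excludes taxa whose
binarized value is ambiguous. NEXUS I/O preserves polymorphism (`{01}`)
and records ordered characters in an `ASSUMPTIONS`/`TYPESET` block;
no installed parser round-trips state-set cells, which is why the
character-matrix reader is implemented here while all tree I/O goes
through `ape`.

Five binary behaviors are derived from the two multistate behavioral
characters: web building, opportunism, burrowing, entrance
modification (purse, collar, turret or trapdoor), and trapdoor
construction. A polymorphic source cell that spans both sides of a
binarization yields `ambiguous`, which likelihood methods treat as
`{0,1}` uncertainty and pair-based methods treat as unusable — a
conservative, consistent convention.

## Supertree by matrix representation with parsimony

Overlapping rooted input trees are encoded by Baum–Ragan coding: each
informative clade becomes a binary pseudo-character (members 1, other
taxa of that source tree 0, absent taxa missing), and an all-zero
pseudo-outgroup row provides the rooting convention. Columns are
weighted equally across source trees. The parsimony search uses
random-addition starting trees followed by NNI and then SPR
hill-climbing (via `phangorn`'s Fitch engine); all equally
most-parsimonious topologies found are returned, rooted on the
pseudo-outgroup and with it removed. The strict consensus summarizes
conflict among optima, and the pipeline uses the first optimal tree as
its working resolution — a config-level choice mirroring the common
practice of selecting one resolution and reporting the alternatives.
The package's own exact unit-cost dynamic program serves as an
independent oracle for the Fitch scores in the test suite.

## Ancestral state reconstruction

**Maximum parsimony.** The supertree is polytomous and topology-only,
so MP reconstruction must be exact on multifurcations. Set-based Fitch
passes are exact only on binary trees; `mpReconstruct()` therefore
implements the unit-cost (Fitch-cost) Sankoff dynamic program, which
handles polytomies and state-set tips exactly and reduces to Fitch on
binary trees. A second, preorder pass computes for every node the full
set of states attainable in at least one most-parsimonious
reconstruction — not merely the downpass sets, which can both over- and
under-state ancestral ambiguity.

**Maximum likelihood.** `fitMkModel()` fits Mk models with ER, SYM or
ARD rate constraints by Felsenstein pruning with `P(t) = exp(Qt)`
(one eigendecomposition of `Q` shared across edges, with a
scaling-and-squaring fallback near defective matrices; partial
likelihoods are rescaled against underflow). Optimization is
multi-start bounded quasi-Newton on log rates; the first start is
parsimony-informed (changes per unit branch length) and the rest are
seeded lognormal perturbations. `selectAsrModel()` fits all constraints
on both branch-length sets (chronogram and phylogram) and selects the
minimum-AICc combination, reporting the full table rather than
hard-coding either branch-length set, since either can be the better
clock for morphology. Ties (exact for binary characters, where SYM
coincides with ER) are broken deterministically: earlier tree, then
ER < SYM < ARD, with the tie recorded. Marginal ancestral probabilities
come from the standard two-pass (re-rooting) algorithm.

Numerical conventions, chosen once and used everywhere: the root prior
is equal frequencies (stationary optional); AICc uses
`-2 logL + 2k + 2k(k+1)/(n-k-1)` with `k` the free-rate count and `n`
the number of tips; optimizer tolerance is tight (`factr 1e4` for
single characters, `1e7` for the 20-model screen where speed matters);
rates live on the log scale with generous bounds around the
parsimony-informed center.

## Morphospace: Gower dissimilarity and NMDS

`gowerDissimilarity()` averages per-character distances over the
characters scored in both taxa of a pair: an unordered character
contributes 0 when the state sets intersect and 1 otherwise; an ordered
character contributes the gap between the sets' ranges scaled by
`n_states - 1`. Pairs with no comparable characters are flagged
undefined and *refused* by the ordination rather than imputed — silent
imputation would distort the configuration. The distance input defaults
to the morphological characters only, excluding the two behavioral
characters, so that the ordination describes somatic morphology and
can then be interpreted against behavior.

`nmds()` minimizes Kruskal stress-1 by alternating an isotonic
regression step (monotone fit of configuration distances on input
dissimilarities, ties averaged — Kruskal's primary approach) with a
Guttman majorization update. Stress is recorded each iteration and an
update that would increase it is rejected, so the within-run stress
sequence is non-increasing by construction. The best of `nStarts`
initializations is kept (classical metric MDS first, random restarts
after); the final configuration is centered, rotated to principal axes
and sign-fixed so the orientation is reproducible, since NMDS solutions
are otherwise rotation- and reflection-invariant. `vegan::monoMDS`
optimizes the same objective and is used as an independent cross-check
in the test suite; it is not the implementation because the module
exposes the per-iteration stress sequence as part of its contract.

## Correlation tests

**Pairwise comparisons.** `findPairingScheme()` builds one maximal set
of phylogenetically independent taxon pairs: candidate pairs that
qualify for the mode (PC1: both the behavior and the feature contrast;
PC2: at least one contrasts) are visited in seed-shuffled order of
increasing path length and accepted when their connecting path shares
no node with previously accepted pairs (Maddison-style non-overlapping
pairs). Short paths are preferred because they waste fewer nodes,
which empirically yields near-maximum pair counts; random restarts
explore alternative maximal matchings. A pair contrasting in both
traits is positive when states co-occur concordantly, negative
otherwise; single-contrast pairs are neutral and appear only in PC2
counts. The p-value is the one-tailed binomial sign test
`P(X <= min(pos, neg))`, `X ~ Bin(pos + neg, 1/2)`; neutral pairs never
enter it. `pairwiseTest()` repeats this over many schemes (study
default 1000) and reports the *largest* p — deliberately conservative,
trading power for robustness to the arbitrariness of any one pairing.
A feature/behavior cell is significant when either the PC1 or the PC2
max-p falls at or below `alpha`; this combined rule is what gates the
likelihood stage, and its operating characteristics (type-I error and
power under strong simulated dependence) are measured directly in the
test suite.

**Likelihood model screen.** `enumerateModels()` builds 20 Markov
models of paired binary evolution on the state space
{00, 01, 10, 11}: four dependence structures (independent,
x-dependent, y-dependent, interdependent) crossed with ER/ARD
constraints per character (16 "standard" models), plus hidden-rate
counterparts of the four independent models. Dual transitions (both
characters changing in one step) have rate zero structurally. The
hidden models duplicate the four observed states into two rate classes,
each with its own full set of character rates, joined by one symmetric
class-switch rate that never changes the observed state — the minimal
parameterization of "two rate categories for each state", included
because rate heterogeneity in a single character can masquerade as
correlation. (Published descriptions of this model set count it once
as 22 and once as 20 models; only the 20 are fully specified, and
those are what the package implements.) `compareDependence()` fits all
20, takes the AICc-best model within each dependence category (hidden
models compete inside the independent category), and reports the four
category bests' delta-AICc, zero-anchored at the overall best.

## Synthetic data

`makeStudyBundle()` generates everything the pipeline consumes. The
defaults emulate the empirical study conditions: a 110-tip birth–death
chronogram (birth 1, death 0.2, conditioned on the tip count, rescaled
to unit root depth so rates read "per tree depth"), a phylogram copy
with independent lognormal branch-rate perturbations (sigma 0.5), three
overlapping input trees covering 70% of taxa each for supertree
construction, a 3-state retreat character and 6-state entrance
character under Mk/ER (per-state leaving rate 1.5 — enough changes for
reconstruction to be nontrivial without saturating), and 55 binary
morphological characters. Ten of them track burrowing with a 10-fold
rate ratio (gain rate 2 while the lineage is a burrower, 0.2
otherwise), simulated by Gillespie sampling *conditional on the
realized behavior history* along each edge, so the dependence is
mechanistic rather than a static association. Five percent of cells
are blanked and five percent widened to polymorphic sets, matching the
"some missing, many polymorphic" character of literature-scored
matrices; polymorphism is injected post hoc because the empirical
phenomenon is scoring-level, not a process being modeled.

What the generator does **not** emulate: correlated evolution among
morphological characters beyond their shared behavioral driver,
ordered/multistate morphology (all synthetic morphology is binary),
state-dependent diversification, and taxon-sampling biases. Passing
tests on these data therefore demonstrate correctness of the
algorithms and calibration of the statistics under the stated model,
not robustness to every violation real matrices can present.

## Problem sizes and seeds

All stochastic behavior is seed-controlled and bit-reproducible. The
test suite validates exact operations against brute-force oracles on
small instances (likelihood enumeration at up to 5 tips and 8 states to
1e-8; exhaustive MP at 6 tips; exhaustive tree search at 6 taxa) and
statistical behavior at deliberately desk-scale sizes: ER rate recovery
on 300-tip trees (20 replicates), dependence-category recovery on
150-tip trees (20 replicates per condition), and pairwise-comparison
operating characteristics on a 100-tip tree (200 replicates, 25
pairing schemes per test — the max-p rule is conservative for any
scheme count, so the reduced count does not inflate the type-I bound).
The acceptance script runs the full pipeline once at the default
110-taxon study scale.

## Known limitations

* The MRP search is heuristic; optimality is only guaranteed where the
  test suite compares against exhaustive enumeration (small instances),
  as with any parsimony heuristic.
* With 70%-overlap input trees the supertree is generally not uniquely
  determined; the search then returns several optima whose strict
  consensus shows the unresolved regions, and downstream analyses use
  the first optimum as the working resolution.
* The hidden-rate models use one global symmetric class-switch rate;
  richer class-switch structures are out of scope.
* `ambiguous` binarized values are excluded from pairing rather than
  fractionally weighted; with heavily polymorphic traits this discards
  information but never fabricates contrasts.
* AICc uses tip count as the sample size — the convention of the tools
  this pipeline emulates, though the effective information content of
  a discrete character on a tree is smaller.
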