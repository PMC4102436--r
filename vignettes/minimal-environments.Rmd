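---
title: "Predicting unique minimal growth environments from genome-scale metabolic models"
author: "minenv package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting unique minimal growth environments}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minenv)
```

## The question

Many environmental microbes are oligotrophs: they grow in nutrient-poor
conditions and often fail on rich media. For such organisms the *minimal*
set of nutrients that still supports growth is a more informative
nutritional signature than any rich-medium phenotype. Given a genome-scale
metabolic model — a stoichiometric matrix $S$, flux bounds, a designated
biomass reaction, and a set of exchange reactions each moving a single
metabolite across the cell boundary — `minenv` computes:

* the smallest number of exchange metabolites whose uptake lets the model
  reach a nominal biomass flux (the organism's *nutritional
  fastidiousness*);
* a *unique* minimal environment (MINENV) of exactly that size,
  disambiguated among the usually many alternative minimal media;
* the subset of *critical* metabolites that appear in every
  growth-supporting medium whatsoever;
* comparative ecological statistics built on these sets.

## The two-stage optimization

Flux balance analysis treats the cell at steady state: fluxes $V$ satisfy
$S V = 0$ within bounds, and growth is the flux $f_{BM}$ through the
biomass reaction. Uptake of exchange metabolite $i$ is negative flux
through its exchange reaction ($f_i \le 0$ when the metabolite is
consumed, for the conventional $-1$ stoichiometric orientation).

**Stage 1 (minimal cardinality).** For each exchange metabolite a binary
indicator $\vartheta_i$ is coupled to its flux by

$$ f_i \ge f_{min}\,(1 - \vartheta_i), \qquad f_{min} = -\text{uptakeMagnitude}, $$

so $\vartheta_i = 1$ forbids uptake and $\vartheta_i = 0$ permits it.
Subject to $S V = 0$, the flux bounds, and $f_{BM} \ge$ `cutoff`, the MILP
maximizes $\sum_i \vartheta_i$. The optimum gives the provably minimal
number of consumed metabolites; the consumed set of one optimal solution
is a *non-unique* minimal environment — many equally small sets usually
exist.

**Stage 2 (unique selection).** All exchange metabolites are ranked by
ascending molar mass (explicit annotation if present, otherwise the mass
computed from the chemical formula with standard atomic weights), ties
broken by lexicographic metabolite id so the ordering is machine-
independent. With the cardinality constrained to the stage-1 optimum
($\sum_i (1-\vartheta_i) \le K$), stage 2 minimizes the summed rank of the
consumed metabolites. This prefers media of light, simple compounds and
pins down a single answer in almost every case.

**Residual ties.** Distinct rank sets can share a sum (ranks $\{1,4\}$ and
$\{2,3\}$). The reported set is made fully deterministic by a
fix-and-resolve sweep: metabolites are visited in ascending rank and kept
exactly when some optimum of the stage-2 objective contains them, which
selects the lexicographically smallest sorted rank vector among the
optima. The brute-force oracle (below) applies the identical rule, so the
two routes are comparable by exact set equality.

**Verification.** Every reported set is re-checked by plain FBA: the set
must reach the cutoff, and removing any single member must not. Members
that fail the necessity check would be pruned; with an exact solver this
is a guard against integrality-tolerance leakage, and the test suite
asserts it never fires on the validation sweep.

**Degeneracy audit.** `swapDegeneracyCheck()` asks, for each member,
whether any non-member of *identical* molar mass could replace it while
growth persists. A nonempty answer flags media whose uniqueness rests
only on the id tie-break.

**Critical metabolites.** A member is critical when closing its exchange
alone — with every other exchange open — drops the optimal biomass below
the cutoff. By monotonicity of FBA in the medium this is equivalent to
membership in every growth-supporting uptake set.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `cutoff` | 0.1 | flux units | nominal "nonzero biomass" threshold; may also be given as a fraction of the rich-medium optimum (`cutoffType = "fraction"` in `grows()`) |
| `uptakeMagnitude` | 1000 | flux units | uptake bound opened by a medium *and* the big-M constant $-f_{min}$; the two must coincide or MILP witnesses would not verify by FBA |
| `timeLimit` | 300 | s | per-MILP wall clock; exceeding it raises a timeout error carrying the incumbent and bound |
| `exempt` | none | — | metabolites (e.g. water, protons) whose uptake is always free and never counted; off by default so that freely available inorganics count like any nutrient |

A medium never widens the model's own bounds: uptake is opened to
$\max(\text{model lower bound}, -\text{uptakeMagnitude})$, and secretion
stays open for every exchange regardless of the medium — a medium
restricts only what may enter.

## Numerical choices

The linear programs are solved by a dense bounded-variable two-phase
primal simplex (compiled code) with reduced-cost tolerance $10^{-7}$ and
pivot tolerance $10^{-9}$; Bland's rule takes over after a burn-in to
exclude cycling. The test suite cross-checks it against an independent LP
implementation on random problems. Growth comparisons use a $10^{-6}$
slack below the cutoff so LP round-off at the boundary never flips a
verdict; the boundary itself counts as growth. The branch-and-bound is
exact: both stage objectives have integer coefficients, so nodes are
pruned with `floor(LP bound)`; branching picks the most fractional
indicator (lowest index on ties) and explores the "closed" branch first,
making the search deterministic. Integrality is accepted at $10^{-6}$ and
indicators are rounded before set extraction, with the FBA re-check
guarding the result. Infinite model bounds are kept for unboundedness
detection in plain FBA (a diagnostic for broken mass-creating loops) but
are capped at $10^7$ inside the MILP, which requires finite big-M
coupling.

With big-M coupling the LP relaxation is weak ($\vartheta_i \approx
1 - |f_i|/M$), so branch-and-bound scales poorly in the number of
exchanges. That is acceptable here: the package's validation operates on
networks with at most 12 exchanges (where the exhaustive oracle is also
available), and a greedy FBA warm start keeps node counts low. Genome-
scale networks with hundreds of exchanges would need a commercial-grade
MILP solver behind the same interface.

## The oracle

`bruteForceMinimalMedia()` enumerates uptake subsets in ascending
cardinality, FBA-testing only subsets with no known-feasible proper
subset (growth is monotone in the medium, so feasibility propagates
upward and minimal feasible sets characterize the whole feasible
up-set). It returns the exact minimum cardinality, all minimum-cardinality
feasible sets, all minimal feasible sets, and their intersection — the
ground-truth critical set. The guard at 12 exchanges keeps the lattice
below 4096 subsets. `bruteForceUniqueMinenv()` applies the stage-2
selection rule by direct enumeration. These oracles share no code with the
MILP path beyond the FBA feasibility test itself.

## What the synthetic data emulate

`generateToyModel()` builds networks with a layered ground truth: each
biomass precursor is fed by one or more alternative external nutrients,
and optional *hub* compounds convert into several precursors at once —
the way a single complex compound (a nucleotide, say) can simultaneously
satisfy carbon, nitrogen and phosphorus needs, which is exactly the
"packing" behavior that makes minimal media non-obvious. Masses default
to distinct random values; planted equal-mass pairs exercise the tie and
swap machinery. GPR rules (single genes, complexes, isozymes) are
attached to conversion reactions at a configurable density.

`generateCommunity()` emulates the structure behind the hypothesis that
co-occurring organisms share nutritional needs: 10 environments own
disjoint 6-nutrient cores from a 60-nutrient pool; each of 50 organisms
lives in 1–2 environments and draws the source of each of its 5 biomass
precursors from its own environments' cores with probability `coupling`,
otherwise uniformly from the pool. At `coupling = 1` nutritional
similarity is maximally informative about co-occurrence; at `coupling = 0`
the two are independent by construction. These sizes were chosen once, by
a design sweep over candidate generator settings, as the smallest
configuration at which a coupled community is reliably detected (pair-
level Spearman and split-half separation) while an uncoupled one is
reliably null across seeds; they are the package's validation conditions,
not tuned per test.

What the toys do **not** emulate: genome-scale network statistics
(thousands of reactions, shared currency metabolites, redundant
pathways), annotation noise, or gap-filled reactions of uncertain
confidence. Passing the recovery tests therefore demonstrates that the
algorithms and statistics are implemented correctly, not that any
particular biological claim holds for real draft models.

## The ecology layer

Similarity is Jaccard throughout, $|A \cap B| / |A \cup B|$, with
$J(\emptyset, \emptyset) := 1$ (identical sets; the case never arises in
the analyses). Ecological distance between organisms is one minus the
Jaccard similarity of their environment-membership sets.

`binnedSimilarityCurve()` bins organism pairs by ecological distance
(equal-width bins over $[0,1]$; the bin count and the minimum pairs per
bin — default 1000, the exclusion rule appropriate for million-pair
surveys — are configurable and should be lowered for small communities).
Each threshold's curve is summarized twice: a bin-level Spearman of the
above-threshold ratio against the bin midpoint (negative when
co-distributed organisms share nutrition, since the x-axis is a
distance), and a pair-level Spearman of ecological *similarity* against
the thresholded nutritional-similarity indicator across all pairs, which
keeps the full sample size and is the statistic of choice for small
communities. The two differ by orientation: sharing shows up as a
negative bin-level and a positive pair-level coefficient.

`splitHalfEnvironmentDistance()` (100 trials by default) splits an
environment's members into two disjoint groups, compares the Jaccard
distance of their aggregate (union) minimal environments, and contrasts
with groups drawn from strict non-members. `growthOnAggregate()` builds
an aggregate from half of an environment's members and FBA-tests the
held-out members against an equal-size random sample of outsiders;
builders are never tested. `containmentTest()` is its model-free
analogue for curated media, with set containment as the growth criterion.
All resampling is funneled through a caller-supplied seed and restores
the global RNG state, so every report is bit-reproducible.

`fastidiousnessCorrelates()` is a thin wrapper over Spearman rank
correlation (average ranks on ties) for relating minimal-environment
size to lifestyle covariates; `meanPairScore()` averages pairwise
cooperation/competition scores per organism.

## Design choices made where the design was open

* **Exchange detection**: a reaction touching exactly one metabolite is
  an exchange, as is anything with an `EX_` id prefix; an explicit flag
  overrides detection, and the designated biomass reaction is never
  auto-flagged. This matches the conventions of community model
  repositories.
* **Mass source**: explicit molar-mass annotation wins over the formula;
  generic residue formulas (`R` groups) raise an error rather than being
  assigned a guessed mass, because a wrong mass silently corrupts the
  uniqueness ordering.
* **Stage-2 cardinality as $\le K$** rather than $= K$: equality is
  implied at the optimum (fewer is impossible), and the inequality is
  numerically safer.
* **Rank sum over consumed metabolites only**: summing over all exchanges
  differs by a constant, so the optimum is unchanged; consumed-only keeps
  the objective small.
* **Lethal genes** in the deletion-stability analysis are reported
  separately and excluded from the alteration ratios.
* **Outside-organism controls** sample uniformly without replacement,
  matched in number to the inside test set, from strict non-members of
  the focal environment.

## Problem sizes used in validation

The shipped validation sweep uses 200 seeded toy models with 3–10
exchange reactions (every model checked against the exhaustive oracle for
size, unique set, and critical core, plus feasibility, irreducibility and
cutoff monotonicity), 20 planted-swap and 20 distinct-mass fixtures, and
synthetic communities of 50 organisms in 10 environments (one coupled
community plus 20 uncoupled null seeds). `scripts/acceptance.R` recomputes
all of it from scratch at any seed.

## Known limitations

* Big-M branch-and-bound does not scale to genome-scale exchange counts;
  see above.
* SBML support covers Level 3 with the FBC package (bounds via
  parameters, objective, nested gene associations) — the subset written
  by the mainstream constraint-based tools — not the full SBML
  specification; molar masses ride along in a private annotation
  attribute that other tools will ignore.
* The alternative fractional biomass cutoff defines "optimal medium" as
  the all-exchanges-open rich medium of the model at hand.
* Aggregate media are unions of sets; concentrations, uptake kinetics and
  compound stability are out of scope.
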