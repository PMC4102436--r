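# minenv: minimal growth environments for genome-scale metabolic models

Many microbes — and most that resist cultivation — are oligotrophs whose
natural habitat is nutrient-poor. For them the informative nutritional
signature is not what they can grow on, but the *smallest* set of
nutrients that still supports growth. `minenv` computes that signature
from a genome-scale metabolic model and provides the comparative ecology
built on it, for microbiologists designing defined media and for
computational ecologists relating nutrition to co-occurrence.

## The method

A metabolic model is a stoichiometric matrix **S** (metabolites ×
reactions) with flux bounds, a biomass reaction, and exchange reactions
that each move one metabolite across the cell boundary (negative flux =
uptake). Flux balance analysis (FBA) maximizes the biomass flux
*f*<sub>BM</sub> subject to **S·V** = 0 and the bounds.

The core is a two-stage mixed-integer linear program. Stage 1 attaches a
binary *ϑ<sub>i</sub>* to each exchange flux via

&nbsp;&nbsp;&nbsp;&nbsp;*f<sub>i</sub>* ≥ *f*<sub>min</sub> (1 − *ϑ<sub>i</sub>*),&nbsp;&nbsp;*f*<sub>min</sub> = −1000,

and maximizes Σ *ϑ<sub>i</sub>* subject to *f*<sub>BM</sub> ≥ 0.1 (the
nominal biomass cutoff), giving the provably minimal number of consumed
nutrients — the organism's **fastidiousness**. Stage 2 holds that
cardinality fixed and minimizes the summed molar-mass rank of the
consumed metabolites (ranks ascending in mass, ties by id), yielding a
**unique minimal environment (MINENV)** of light, simple compounds.
Residual rank-sum ties resolve to the lexicographically smallest sorted
rank vector, so the output is a deterministic function of the model. The
**critical metabolites** are the MINENV members whose single closure
abolishes growth even with every other exchange open — equivalently, the
compounds present in every growth-supporting medium.

Because no MILP solver ships with this R stack, the package includes its
own exact solver: a dense bounded-variable two-phase simplex in compiled
code under an integer-bound branch-and-bound, cross-checked in the test
suite against an independent LP implementation and against exhaustive
enumeration of all uptake subsets on networks small enough to enumerate.

## Worked example

```r
library(minenv)

model <- generateToyModel(toyModelSpec(nPrecursors = 3, sourcesPerPrecursor = 2,
                                       nHubs = 1, seed = 42))
model
#> MetabolicModel 'toy_s42_p3_a2_h1': 10 metabolites, 15 reactions (7 exchanges), 0 genes
#>   biomass reaction: BIOMASS

res <- uniqueMinenv(model, critical = TRUE)
res
#> MinenvResult for 'toy_s42_p3_a2_h1': 2 metabolites (cutoff 0.1, status optimal)
#>   minenv: H1, N1_1
#>   critical: (none)

bf <- bruteForceMinimalMedia(model)
bf$min_size                       # 2
sapply(bf$minimal_media, paste, collapse = "+")
#> "H1+N1_1" "H1+N1_2"
```

The toy has three biomass precursors, each with two alternative nutrient
sources, plus one "hub" compound `H1` convertible into precursors 2 and
3. Two nutrients therefore suffice: the hub plus any source of precursor
1 — the exhaustive oracle confirms exactly two such media. Stage 2 picks
`N1_1` over `N1_2` because it ranks lighter in the molar ordering
(`molarOrdering(model)` puts `N1_1` at rank 1, `N1_2` at rank 7). No
member is critical: every nutritional need here has an alternative
route, and indeed `grows(model, medium("H1"))` is `FALSE` while the full
pair grows. Equal-mass degeneracy can be audited with
`swapDegeneracyCheck(model, res)` (empty here).

Reading a real model works the same way:

```r
model <- readMetabolicModel("organism.xml")   # SBML/FBC or COBRA-style JSON
res   <- uniqueMinenv(model, critical = TRUE)
writeMinenvTable(list(res), "minenv.tsv")     # organism, size, members, criticals
```

Ecology: given MINENVs for many organisms and an organism × environment
presence table, `binnedSimilarityCurve()` relates nutritional to
ecological similarity, `splitHalfEnvironmentDistance()` and
`growthOnAggregate()` test nutrient sharing within environments, and
`fastidiousnessCorrelates()` rank-correlates MINENV size with lifestyle
covariates. `generateCommunity()` builds seeded synthetic communities
with tunable nutrition–co-occurrence coupling for validating all of it;
see the methods vignette (`vignettes/minimal-environments.Rmd`).

A thin command-line wrapper for the single-model, batch and ecology
workflows is installed at `inst/scripts/minenv-cli.R`.

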