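# Hand-built miniature models used across the test files. All are built in
# code; masses are chosen so that molar orderings are unambiguous unless a
# tie is planted on purpose.

# Biomass consumes A at yield 1; uptake of A capped at 10.
threeReactionToy <- function() {
  metabolicModel(
    id = "three_rxn",
    metabolites = data.frame(id = "A", molar_mass = 100),
    reactions = data.frame(
      id = c("EX_A", "BIOMASS"),
      lower_bound = c(-10, 0), upper_bound = c(1000, 1000),
      is_exchange = c(TRUE, FALSE)),
    stoich = list(c(A = -1), c(A = -1)),
    biomass = "BIOMASS")
}

# Grows with no uptake: an internal generator reaction supplies the
# precursor. The generator's single-metabolite column is explicitly marked
# non-exchange.
autotrophToy <- function() {
  metabolicModel(
    id = "autotroph",
    metabolites = data.frame(id = c("A"), molar_mass = 50),
    reactions = data.frame(
      id = c("EX_A", "GEN_A", "BIOMASS"),
      lower_bound = c(-1000, 0, 0), upper_bound = c(1000, 1000, 1000),
      is_exchange = c(TRUE, FALSE, FALSE)),
    stoich = list(c(A = -1), c(A = 1), c(A = -1)),
    biomass = "BIOMASS")
}

# Exchanges {A, B, C}; C converts into both A and B; biomass needs A and B.
# Minimal medium is {C} (size 1); deleting the conversions makes it {A, B}.
hubToy <- function(withConversions = TRUE) {
  rid <- c("EX_A", "EX_B", "EX_C", "CONV_CA", "CONV_CB", "BIOMASS")
  st <- list(c(A = -1), c(B = -1), c(C = -1),
             c(C = -1, A = 1), c(C = -1, B = 1),
             c(A = -1, B = -1))
  ub <- rep(1000, 6)
  if (!withConversions) ub[4:5] <- 0
  metabolicModel(
    id = "hub_toy",
    metabolites = data.frame(id = c("A", "B", "C"),
                             molar_mass = c(18, 20, 60)),
    reactions = data.frame(id = rid, lower_bound = c(-1000, -1000, -1000,
                                                     0, 0, 0),
                           upper_bound = ub,
                           is_exchange = c(TRUE, TRUE, TRUE, FALSE, FALSE,
                                           FALSE)),
    stoich = st, biomass = "BIOMASS")
}

# Pathological fixture: an internal reaction creates P from nothing (its
# column nets to +P only, deliberately marked non-exchange) and biomass has
# no upper bound, so the FBA objective is unbounded.
unboundedLoopToy <- function() {
  metabolicModel(
    id = "unbounded_loop",
    metabolites = data.frame(id = "P", molar_mass = 10),
    reactions = data.frame(
      id = c("MAKE_P", "BIOMASS"),
      lower_bound = c(0, 0), upper_bound = c(Inf, Inf),
      is_exchange = c(FALSE, FALSE)),
    stoich = list(c(P = 1), c(P = -1)),
    biomass = "BIOMASS")
}

# Deterministic parameters for the seeded toy-model sweep: 3 to 10
# exchange reactions, mixing replaceable sources and hub compounds.
sweepCombos <- local({
  g <- expand.grid(k = 1:4, s = 1:3, h = 0:2)
  g <- g[g$k >= 2 | g$h == 0, ]
  g <- g[g$k * g$s + g$h >= 3 & g$k * g$s + g$h <= 10, ]
  g[order(g$k, g$s, g$h), ]
})

sweepSpec <- function(i, seed = i) {
  row <- sweepCombos[(i - 1L) %% nrow(sweepCombos) + 1L, ]
  toyModelSpec(nPrecursors = row$k, sourcesPerPrecursor = row$s,
               nHubs = row$h, seed = seed)
}

# Fixture with one planted equal-mass interchangeable nutrient pair
# (N1_1/N1_2 both feed precursor 1 and share a molar mass); all other
# sources have distinct masses.
plantedSwapSpec <- function(seed) {
  toyModelSpec(nPrecursors = 2, sourcesPerPrecursor = 2,
               massAssignment = c(N1_1 = 89, N1_2 = 89,
                                  N2_1 = 150, N2_2 = 333),
               seed = seed)
}

# Community minenvs computed through the full two-stage pipeline.
communityMinenvs <- function(community, cutoff = 0.1) {
  lapply(community$models, function(m) minenv(uniqueMinenv(m, cutoff)))
}
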