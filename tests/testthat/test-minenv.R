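# The two-stage optimization, verified against exhaustive enumeration and
# on hand-solvable fixtures.

test_that("stage 1 finds the provably minimal cardinality on hand cases", {
  # hub compound covers both precursors: one nutrient suffices
  st <- minimalMediumSize(hubToy())
  expect_identical(st$size, 1L)
  expect_identical(st$witness, "C")
  # without the conversions both elementary nutrients are needed
  st2 <- minimalMediumSize(hubToy(withConversions = FALSE))
  expect_identical(st2$size, 2L)
  expect_identical(st2$witness, c("A", "B"))
  # autotroph grows on the empty medium
  expect_identical(minimalMediumSize(autotrophToy())$size, 0L)
  # unattainable cutoff is a structured error
  expect_error(minimalMediumSize(hubToy(), cutoff = 1e6),
               class = "minenvInfeasibleError")
})

test_that("MILP and unique selection match brute force on seeded toys", {
  for (i in 1:30) {
    m <- generateToyModel(sweepSpec(i))
    bf <- bruteForceMinimalMedia(m)
    st <- minimalMediumSize(m)
    expect_identical(st$size, bf$min_size)
    res <- uniqueMinenv(m)
    expect_identical(minenv(res), bruteForceUniqueMinenv(m, oracle = bf))
    expect_identical(sort(criticalMetabolites(m, res)), bf$critical)
  }
})

test_that("stage 2 prefers light compounds and breaks mass ties by id", {
  # two alternative sole sources: the 60 g/mol one wins over 180 g/mol
  m <- generateToyModel(toyModelSpec(
    nPrecursors = 1, sourcesPerPrecursor = 2,
    massAssignment = c(N1_1 = 180, N1_2 = 60), seed = 2))
  expect_identical(minenv(uniqueMinenv(m)), "N1_2")
  # identical masses: lexicographically smaller id is chosen
  tie <- generateToyModel(toyModelSpec(
    nPrecursors = 1, sourcesPerPrecursor = 2,
    massAssignment = c(N1_1 = 89, N1_2 = 89), seed = 2))
  expect_identical(minenv(uniqueMinenv(tie)), "N1_1")
  # a unique minimal medium equals the stage-1 witness
  st <- minimalMediumSize(hubToy())
  expect_identical(minenv(uniqueMinenv(hubToy())), st$witness)
})

test_that("every reported minimal environment is feasible and irreducible", {
  for (i in seq(1, 25, by = 3)) {
    m <- generateToyModel(sweepSpec(i, seed = 400 + i))
    res <- uniqueMinenv(m)
    expect_true(grows(m, medium(minenv(res)), res@cutoff))
    for (mm in minenv(res)) {
      expect_false(grows(m, medium(setdiff(minenv(res), mm)), res@cutoff))
    }
    # theta encodes the same set
    expect_setequal(names(thetaValues(res))[thetaValues(res) == 0],
                    minenv(res))
  }
})

test_that("repeated runs return the identical minimal environment", {
  for (i in c(4, 9, 14)) {
    m <- generateToyModel(sweepSpec(i, seed = 777 + i))
    r1 <- uniqueMinenv(m)
    r2 <- uniqueMinenv(m)
    expect_identical(minenv(r1), minenv(r2))
    expect_identical(r1@molarRankSum, r2@molarRankSum)
  }
})

test_that("minimal size is nondecreasing in the biomass cutoff", {
  grid <- c(0.01, 0.1, 1, 10, 100)
  for (i in c(2, 7, 12, 19)) {
    m <- generateToyModel(sweepSpec(i, seed = 900 + i))
    sizes <- vapply(grid, function(ct) minimalMediumSize(m, ct)$size,
                    integer(1))
    expect_true(all(diff(sizes) >= 0))
  }
})

test_that("swap check reports planted equal-mass pairs and nothing else", {
  m <- generateToyModel(plantedSwapSpec(21))
  res <- uniqueMinenv(m)
  sw <- swapDegeneracyCheck(m, res)
  expect_identical(nrow(sw), 1L)
  expect_identical(sw$out_compound, "N1_1")
  expect_identical(sw$in_compound, "N1_2")
  # all-distinct masses admit no swap candidates
  m2 <- generateToyModel(toyModelSpec(nPrecursors = 2,
                                      sourcesPerPrecursor = 2, seed = 22))
  expect_identical(nrow(swapDegeneracyCheck(m2, uniqueMinenv(m2))), 0L)
  # empty minimal environment: nothing to swap
  auto <- autotrophToy()
  expect_identical(nrow(swapDegeneracyCheck(auto, uniqueMinenv(auto))), 0L)
})

test_that("critical metabolites are the irreplaceable core", {
  # sole source for each precursor: everything is critical
  m <- generateToyModel(toyModelSpec(nPrecursors = 2, seed = 3))
  res <- uniqueMinenv(m, critical = TRUE)
  expect_setequal(criticalSet(res), minenv(res))
  # two alternative carbon sources: neither is critical
  m2 <- generateToyModel(toyModelSpec(nPrecursors = 1,
                                      sourcesPerPrecursor = 2, seed = 3))
  expect_identical(criticalMetabolites(m2, uniqueMinenv(m2)), character())
  # empty minimal environment has an empty core
  expect_identical(criticalMetabolites(autotrophToy(),
                                       uniqueMinenv(autotrophToy())),
                   character())
})

test_that("preferred selection overrides mass but not cardinality", {
  m <- generateToyModel(toyModelSpec(
    nPrecursors = 1, sourcesPerPrecursor = 2,
    massAssignment = c(N1_1 = 60, N1_2 = 180), seed = 5))
  plain <- uniqueMinenv(m)
  expect_identical(minenv(plain), "N1_1")
  pref <- preferredMinenv(m, preferred = "N1_2")
  expect_identical(minenv(pref), "N1_2")
  expect_identical(minimalSize(pref), minimalSize(plain))
  # preferring everything or nothing reduces to the plain selection
  expect_identical(minenv(preferredMinenv(m, exchangeMetabolites(m))),
                   minenv(plain))
  expect_identical(minenv(preferredMinenv(m, character())), minenv(plain))
})

test_that("gene-deletion stability separates lethal and altering genes", {
  m <- generateToyModel(toyModelSpec(nPrecursors = 2, sourcesPerPrecursor = 2,
                                     gprDensity = 1, seed = 9))
  st <- minenvStabilityUnderDeletions(m)
  expect_true(st$fraction_composition_changed >= 0 &&
                st$fraction_composition_changed <= 1)
  expect_identical(nrow(st$per_gene), length(genes(m)))
  # a gene guarding the sole route to a precursor changes the composition
  single <- metabolicModel(
    id = "route",
    metabolites = data.frame(id = c("A", "B", "C", "P1", "P2"),
                             molar_mass = c(10, 20, 30, NA, NA)),
    reactions = data.frame(
      id = c("EX_A", "EX_B", "EX_C", "CONV_CA", "CONV_CB", "T_A", "T_B",
             "BIOMASS"),
      lower_bound = c(-1000, -1000, -1000, 0, 0, 0, 0, 0),
      upper_bound = rep(1000, 8),
      gpr = c("", "", "", "gHub", "gHub", "", "", ""),
      is_exchange = c(TRUE, TRUE, TRUE, rep(FALSE, 5))),
    stoich = list(c(A = -1), c(B = -1), c(C = -1),
                  c(C = -1, P1 = 1), c(C = -1, P2 = 1),
                  c(A = -1, P1 = 1), c(B = -1, P2 = 1),
                  c(P1 = -1, P2 = -1)),
    biomass = "BIOMASS")
  expect_identical(minenv(uniqueMinenv(single)), "C")
  stg <- minenvStabilityUnderDeletions(single)
  expect_identical(stg$fraction_composition_changed, 1) # {C} -> {A,B}
  expect_identical(stg$fraction_size_changed, 1)
  # no GPRs at all violates the precondition
  expect_error(minenvStabilityUnderDeletions(hubToy()),
               class = "minenvPreconditionError")
})

test_that("result tables round-trip through the TSV format", {
  m <- generateToyModel(toyModelSpec(nPrecursors = 2, seed = 13))
  res <- uniqueMinenv(m, critical = TRUE)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeMinenvTable(list(res), f)
  back <- readMinenvTable(f)
  expect_identical(back[[modelId(m)]], minenv(res))
  expect_identical(unname(attr(back, "sizes")[modelId(m)]),
                   minimalSize(res))
  expect_identical(attr(back, "critical")[[modelId(m)]], criticalSet(res))
})
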