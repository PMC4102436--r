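# Model construction, formula masses, molar ordering, and the two dialects.

test_that("compoundMass matches standard atomic weights", {
  expect_equal(compoundMass("H2O"), 18.015, tolerance = 1e-6)
  expect_equal(compoundMass("C6H12O6"), 180.156, tolerance = 1e-6)
  expect_equal(compoundMass("(NH4)2SO4"),
               2 * (14.007 + 4 * 1.008) + 32.06 + 4 * 15.999,
               tolerance = 1e-6)
  expect_error(compoundMass(""), class = "minenvMassError")
  expect_error(compoundMass("C6R"), class = "minenvMassError")
  expect_error(compoundMass("C6H12("), class = "minenvMassError")
})

test_that("molarOrdering sorts by mass with lexicographic tie-break", {
  m <- metabolicModel(
    id = "ord",
    metabolites = data.frame(id = c("B", "A", "C", "P"),
                             molar_mass = c(18, 18, 60, NA)),
    reactions = data.frame(
      id = c("EX_B", "EX_A", "EX_C", "CONV", "BIOMASS"),
      lower_bound = c(-1000, -1000, -1000, 0, 0),
      upper_bound = rep(1000, 5),
      is_exchange = c(TRUE, TRUE, TRUE, FALSE, FALSE)),
    stoich = list(c(B = -1), c(A = -1), c(C = -1),
                  c(A = -1, P = 1), c(P = -1)),
    biomass = "BIOMASS")
  ord <- molarOrdering(m)
  expect_identical(names(ord), c("A", "B", "C"))
  expect_identical(unname(ord), 1:3)
  # idempotent and invariant to metabolite-table permutation
  expect_identical(molarOrdering(m), ord)
  m2 <- m
  perm <- c(3, 1, 4, 2)
  m2@metabolites <- m@metabolites[perm, ]
  m2@stoichiometry <- m@stoichiometry[perm, ]
  expect_identical(molarOrdering(m2), ord)
  # single exchange gets rank 1; reversed masses reverse the order
  expect_identical(unname(molarOrdering(threeReactionToy())["A"]), 1L)
})

test_that("mass resolution prefers annotation and falls back to formula", {
  m <- threeReactionToy()
  m@metabolites$formula <- "H2O"
  expect_equal(resolveMasses(m, "A"), 100) # annotation wins
  m@metabolites$molar_mass <- NA_real_
  expect_equal(resolveMasses(m, "A"), 18.015, tolerance = 1e-6)
  m@metabolites$formula <- "R"
  expect_error(molarOrdering(m), class = "minenvMassError")
})

test_that("model invariants are enforced at construction", {
  # exchange touching two metabolites
  expect_error(metabolicModel(
    id = "bad",
    metabolites = data.frame(id = c("A", "B"), molar_mass = c(1, 2)),
    reactions = data.frame(id = c("EX_A", "BIOMASS"),
                           lower_bound = c(-10, 0),
                           upper_bound = c(10, 10),
                           is_exchange = c(TRUE, FALSE)),
    stoich = list(c(A = -1, B = 1), c(A = -1)),
    biomass = "BIOMASS"), "exchange")
  # missing biomass reaction
  expect_error(metabolicModel(
    id = "bad2",
    metabolites = data.frame(id = "A", molar_mass = 1),
    reactions = data.frame(id = "EX_A", lower_bound = -10,
                           upper_bound = 10, is_exchange = TRUE),
    stoich = list(c(A = -1)),
    biomass = "GROWTH"), "biomass")
  # bounds crossed
  expect_error(metabolicModel(
    id = "bad3",
    metabolites = data.frame(id = "A", molar_mass = 1),
    reactions = data.frame(id = c("EX_A", "BIOMASS"),
                           lower_bound = c(5, 0), upper_bound = c(-5, 10),
                           is_exchange = c(TRUE, FALSE)),
    stoich = list(c(A = -1), c(A = -1)),
    biomass = "BIOMASS"), "lower_bound")
})

test_that("JSON round trip preserves the model field by field", {
  m <- generateToyModel(toyModelSpec(nPrecursors = 3, sourcesPerPrecursor = 2,
                                     nHubs = 1, gprDensity = 0.5, seed = 31))
  f <- withr::local_tempfile(fileext = ".json")
  writeMetabolicModel(m, f)
  rt <- readMetabolicModel(f)
  expect_identical(rt@reactions$id, m@reactions$id)
  expect_identical(rt@reactions$lower_bound, m@reactions$lower_bound)
  expect_identical(rt@reactions$upper_bound, m@reactions$upper_bound)
  expect_identical(rt@reactions$gpr, m@reactions$gpr)
  expect_identical(rt@reactions$is_exchange, m@reactions$is_exchange)
  expect_identical(rt@metabolites$molar_mass, m@metabolites$molar_mass)
  expect_identical(as.matrix(rt@stoichiometry), as.matrix(m@stoichiometry))
  expect_identical(rt@biomassReaction, m@biomassReaction)
  expect_identical(sort(rt@genes), sort(m@genes))
})

test_that("SBML round trip preserves stoichiometry, bounds, GPRs, masses", {
  m <- generateToyModel(toyModelSpec(nPrecursors = 2, sourcesPerPrecursor = 2,
                                     gprDensity = 1, seed = 32))
  f <- withr::local_tempfile(fileext = ".xml")
  writeMetabolicModel(m, f)
  rt <- readMetabolicModel(f)
  expect_identical(as.matrix(rt@stoichiometry), as.matrix(m@stoichiometry))
  expect_identical(rt@reactions$lower_bound, m@reactions$lower_bound)
  expect_identical(rt@reactions$upper_bound, m@reactions$upper_bound)
  expect_identical(rt@metabolites$molar_mass, m@metabolites$molar_mass)
  expect_identical(rt@reactions$is_exchange, m@reactions$is_exchange)
  # GPR strings may gain explicit parentheses but must be logically equal
  expect_identical(gsub("[() ]", "", rt@reactions$gpr),
                   gsub("[() ]", "", m@reactions$gpr))
})

test_that("the JSON fixture and its cobrapy-written SBML twin agree", {
  # toy_model_synthetic_cobrapy.xml was produced by an external SBML writer
  # from toy_model_synthetic.json; both must parse to the same network and
  # the same unique minimal environment.
  js <- readMetabolicModel(
    system.file("extdata", "toy_model_synthetic.json", package = "minenv"))
  sb <- readMetabolicModel(
    system.file("extdata", "toy_model_synthetic_cobrapy.xml",
                package = "minenv"))
  expect_setequal(sb@metabolites$id, js@metabolites$id)
  expect_setequal(sb@reactions$id, js@reactions$id)
  expect_equal(maximizeBiomass(sb)@objective, maximizeBiomass(js)@objective)
  expect_identical(minenv(uniqueMinenv(sb)), minenv(uniqueMinenv(js)))
})

test_that("reader errors carry the parse/model error classes", {
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("{ not json", bad)
  expect_error(readMetabolicModel(bad), class = "minenvParseError")
  expect_error(readMetabolicModel("/nonexistent/x.json"),
               class = "minenvParseError")
  # model without any objective reaction
  noObj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    id = "noobj",
    metabolites = list(list(id = "A", molar_mass = 10, compartment = "c")),
    reactions = list(list(id = "EX_A", metabolites = list(A = -1),
                          lower_bound = -10, upper_bound = 10)),
    genes = list()), noObj, auto_unbox = TRUE)
  expect_error(readMetabolicModel(noObj), class = "minenvModelError")
})
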