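# Generators and the exhaustive oracle.

test_that("toy models are deterministic in the seed and always viable", {
  sp <- toyModelSpec(nPrecursors = 3, sourcesPerPrecursor = 2, nHubs = 1,
                     gprDensity = 0.5, seed = 77)
  a <- generateToyModel(sp)
  b <- generateToyModel(sp)
  expect_identical(a@reactions, b@reactions)
  expect_identical(a@metabolites, b@metabolites)
  expect_identical(as.matrix(a@stoichiometry), as.matrix(b@stoichiometry))
  expect_true(grows(a, richMedium(a), 0.1))
})

test_that("generated models are valid, viable, and within the exchange budget", {
  for (i in 1:50) {
    m <- generateToyModel(sweepSpec(i, seed = 5000 + i))
    expect_true(isTRUE(validObject(m, test = TRUE)))
    E <- length(exchangeMetabolites(m))
    expect_true(E >= 3 && E <= 12)
    expect_true(grows(m, richMedium(m), 0.1))
  }
})

test_that("spec limits are enforced at construction", {
  expect_error(toyModelSpec(nPrecursors = 5, sourcesPerPrecursor = 3),
               class = "minenvPreconditionError") # 15 exchanges
  expect_error(toyModelSpec(nPrecursors = 1, nHubs = 1),
               class = "minenvPreconditionError")
  expect_error(communitySpec(coupling = 2),
               class = "minenvPreconditionError")
  expect_error(communitySpec(poolSize = 10),
               class = "minenvPreconditionError")
})

test_that("the oracle refuses combinatorially large models", {
  # 13 exchanges would need 8192 subsets
  m <- generateToyModel(toyModelSpec(nPrecursors = 4, sourcesPerPrecursor = 3,
                                     seed = 1))
  fake <- m
  extra <- data.frame(id = "Z", name = "Z", formula = NA, molar_mass = 1,
                      compartment = "c")
  fake@metabolites <- rbind(fake@metabolites, extra)
  fake@stoichiometry <- rbind(fake@stoichiometry,
                              Matrix::sparseMatrix(i = integer(),
                                                   j = integer(), x = numeric(),
                                                   dims = c(1, ncol(fake@stoichiometry))))
  newRxn <- fake@reactions[1, ]
  newRxn$id <- "EX_Z"; newRxn$name <- "EX_Z"; newRxn$is_exchange <- TRUE
  fake@reactions <- rbind(fake@reactions, newRxn)
  fake@stoichiometry <- cbind(fake@stoichiometry,
                              Matrix::sparseMatrix(i = nrow(fake@stoichiometry),
                                                   j = 1, x = -1,
                                                   dims = c(nrow(fake@stoichiometry), 1)))
  dimnames(fake@stoichiometry) <- list(fake@metabolites$id, fake@reactions$id)
  expect_error(bruteForceMinimalMedia(fake),
               class = "minenvPreconditionError")
})

test_that("oracle results are self-consistent minimal sets", {
  for (i in c(3, 8, 13)) {
    m <- generateToyModel(sweepSpec(i, seed = 600 + i))
    bf <- bruteForceMinimalMedia(m)
    for (s in bf$minimal_sets) {
      expect_true(grows(m, medium(s), 0.1))
      for (drop in s) {
        expect_false(grows(m, medium(setdiff(s, drop)), 0.1))
      }
    }
    expect_true(all(lengths(bf$minimal_media) == bf$min_size))
    # criticals lie in every minimal set
    for (s in bf$minimal_sets) expect_true(all(bf$critical %in% s))
  }
  # oracle worked examples: the hub toy and the autotroph
  bf <- bruteForceMinimalMedia(hubToy())
  expect_identical(bf$min_size, 1L)
  expect_identical(bf$minimal_media, list("C"))
  auto <- bruteForceMinimalMedia(autotrophToy())
  expect_identical(auto$min_size, 0L)
  expect_identical(auto$critical, character())
})

test_that("communities are deterministic and structured as specified", {
  sp <- communitySpec(nOrganisms = 12, nEnvironments = 4,
                      coreNutrientsPerEnvironment = 4, poolSize = 16,
                      coupling = 1, seed = 11)
  a <- generateCommunity(sp)
  b <- generateCommunity(sp)
  expect_identical(presence(a$profile), presence(b$profile))
  expect_identical(lapply(a$models, function(m) m@metadata$nutrients),
                   lapply(b$models, function(m) m@metadata$nutrients))
  # every organism lives somewhere and every model is valid and viable
  expect_true(all(rowSums(presence(a$profile)) >= 1))
  for (m in a$models) {
    expect_true(isTRUE(validObject(m, test = TRUE)))
    expect_true(grows(m, richMedium(m), 0.1))
  }
  # at full coupling every nutrient comes from the organism's own cores
  p <- presence(a$profile)
  for (o in organisms(a$profile)) {
    myCores <- unlist(a$groundTruth$cores[p[o, ] == 1])
    expect_true(all(a$groundTruth$nutrients[[o]] %in% myCores))
  }
})

test_that("the full pipeline recovers each organism's planted nutrients", {
  cm <- generateCommunity(communitySpec(nOrganisms = 8, nEnvironments = 3,
                                        coreNutrientsPerEnvironment = 5,
                                        poolSize = 15, coupling = 0.5,
                                        seed = 19))
  for (o in names(cm$models)) {
    res <- uniqueMinenv(cm$models[[o]])
    expect_identical(minenv(res), cm$groundTruth$nutrients[[o]])
  }
})
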