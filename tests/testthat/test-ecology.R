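# Ecology layer: similarity metrics, resampling analyses, correlations.

test_that("jaccard handles the textbook cases", {
  expect_equal(jaccard(c("a", "b"), c("b", "c")), 1 / 3)
  expect_equal(jaccard(c("x", "y"), c("x", "y")), 1)
  expect_equal(jaccard("a", "b"), 0)
  expect_equal(jaccard(character(), character()), 1)
  expect_equal(jaccard(character(), "a"), 0)
})

test_that("jaccard distance is a metric on random sets", {
  set.seed(42)
  universe <- letters
  rset <- function() sample(universe, sample(0:10, 1))
  for (i in 1:200) {
    a <- rset(); b <- rset(); cc <- rset()
    sab <- jaccard(a, b)
    expect_identical(sab, jaccard(b, a))
    expect_true(sab >= 0 && sab <= 1)
    # triangle inequality for d = 1 - jaccard
    dab <- 1 - sab; dbc <- 1 - jaccard(b, cc); dac <- 1 - jaccard(a, cc)
    expect_lte(dac, dab + dbc + 1e-12)
  }
})

test_that("aggregateMinenv is the plain union", {
  expect_identical(aggregateMinenv(list(c("a", "b"), c("b", "c"))),
                   c("a", "b", "c"))
  expect_identical(aggregateMinenv(list(c("s", "t"))), c("s", "t"))
  expect_identical(aggregateMinenv(list(character(), character())),
                   character())
  expect_error(aggregateMinenv(list()), class = "minenvPreconditionError")
})

test_that("binned curve separates co-distributed from disjoint pairs", {
  profile <- ecologicalProfile(matrix(
    c(1, 1, 0, 0,
      0, 0, 1, 1), 4, 2,
    dimnames = list(c("o1", "o2", "o3", "o4"), c("e1", "e2"))))
  mins <- list(o1 = c("a", "b"), o2 = c("a", "b"),
               o3 = c("c", "d"), o4 = c("c", "d"))
  cv <- binnedSimilarityCurve(mins, profile, nBins = 2, thresholds = 50,
                              minPairsPerBin = 1)
  # 2 same-environment pairs at distance 0 share everything; the 4 cross
  # pairs at distance 1 share nothing
  expect_equal(unname(cv@ratio[1, 1]), 1)
  expect_equal(unname(cv@ratio[2, 1]), 0)
  expect_identical(cv@pairCounts, c(2L, 4L))
  expect_equal(cv@pairSpearman$rho, 1)
  # all-identical organisms: one occupied bin, ratio 1 at any threshold
  same <- ecologicalProfile(matrix(1, 3, 1,
    dimnames = list(c("o1", "o2", "o3"), "e1")))
  cv2 <- binnedSimilarityCurve(lapply(mins[1:3], function(x) c("a", "b")),
                               same, nBins = 4, thresholds = c(30, 100),
                               minPairsPerBin = 1)
  expect_equal(unname(cv2@ratio[1, ]), c(1, 1))
  expect_true(all(is.na(cv2@ratio[-1, ])))
  # correlation is reported as absent when every bin is flagged
  cv3 <- binnedSimilarityCurve(mins, profile, nBins = 2, thresholds = 50,
                               minPairsPerBin = 100)
  expect_true(all(cv3@flagged))
  expect_true(is.na(cv3@spearman$rho))
  expect_error(binnedSimilarityCurve(mins["o1"], profile),
               class = "minenvPreconditionError")
})

test_that("split-half distances are reproducible and detect shared cores", {
  cm <- generateCommunity(communitySpec(coupling = 1, seed = 23))
  mins <- lapply(cm$models, function(m) m@metadata$nutrients)
  sh <- splitHalfEnvironmentDistance(mins, cm$profile, "env01",
                                     nTrials = 50, seed = 4)
  sh2 <- splitHalfEnvironmentDistance(mins, cm$profile, "env01",
                                      nTrials = 50, seed = 4)
  expect_identical(sh$per_trial, sh2$per_trial)
  expect_lt(sh$within_mean, sh$random_mean)
  # identical member minenvs collapse the within-distance to zero
  p <- presence(cm$profile)
  members <- rownames(p)[p[, "env01"] == 1]
  minsSame <- mins
  for (o in members) minsSame[[o]] <- c("n1", "n2")
  shSame <- splitHalfEnvironmentDistance(minsSame, cm$profile, "env01",
                                         nTrials = 5, seed = 1)
  expect_equal(shSame$within_mean, 0)
  # single-trial record with a fixed seed is stable
  one <- splitHalfEnvironmentDistance(mins, cm$profile, "env02",
                                      nTrials = 1, seed = 9)
  expect_identical(nrow(one$per_trial), 1L)
  expect_error(
    splitHalfEnvironmentDistance(mins, cm$profile, "env01",
                                 groupSize = 1000),
    class = "minenvPreconditionError")
  expect_error(
    splitHalfEnvironmentDistance(mins, cm$profile, "no_such_env"),
    class = "minenvLookupError")
})

test_that("growth on aggregates honors the builder/tested separation", {
  # m1 needs {a}; m2 needs {a,b} (one precursor per nutrient); m3 needs {c}
  mkModel <- function(id, nutrients) {
    n <- length(nutrients)
    pre <- paste0("P_", nutrients)
    mets <- data.frame(id = c(nutrients, pre),
                       molar_mass = c(seq(10, by = 10, length.out = n),
                                      rep(NA, n)))
    rid <- c(paste0("EX_", nutrients), paste0("T_", nutrients), "BIOMASS")
    st <- c(lapply(nutrients, function(x) setNames(-1, x)),
            lapply(nutrients, function(x)
              setNames(c(-1, 1), c(x, paste0("P_", x)))),
            list(setNames(rep(-1, n), pre)))
    metabolicModel(id = id, metabolites = mets,
                   reactions = data.frame(
                     id = rid, lower_bound = c(rep(-1000, n), rep(0, n + 1)),
                     upper_bound = rep(1000, 2 * n + 1),
                     is_exchange = c(rep(TRUE, n), rep(FALSE, n + 1))),
                   stoich = st, biomass = "BIOMASS")
  }
  models <- list(m1 = mkModel("m1", "a"), m2 = mkModel("m2", c("a", "b")),
                 m3 = mkModel("m3", "c"))
  # m2 needs BOTH a and b: tie the two transporters stoichiometrically
  mins <- list(m1 = "a", m2 = c("a", "b"), m3 = "c")
  profile <- ecologicalProfile(matrix(c(1, 1, 0, 0, 0, 1), 3, 2,
    dimnames = list(c("m1", "m2", "m3"), c("e1", "e2"))))
  g <- growthOnAggregate(models, mins, profile, "e1", nTrials = 4, seed = 2)
  # builder m2 -> aggregate {a,b} lets m1 grow; builder m1 -> {a} starves
  # m2; outsider m3 never grows (c is absent from any aggregate)
  expect_identical(g$outside_growth_fraction, 0)
  expect_identical(nrow(g$per_trial), 4L)
  for (tr in seq_len(4)) {
    expect_true(g$per_trial$inside[tr] %in% c(0, 1))
  }
  # superset monotonicity: an organism whose minenv is inside the
  # aggregate always grows
  expect_true(grows(models$m1, medium("a")))
  expect_true(grows(models$m2, medium(c("a", "b"))))
  g2 <- growthOnAggregate(models, mins, profile, "e1", nTrials = 4, seed = 2)
  expect_identical(g$per_trial, g2$per_trial) # bit-reproducible
})

test_that("containment test mirrors the resampling scheme without models", {
  media <- list(m1 = c("x"), m2 = c("x", "y"), m3 = c("z"))
  profile <- ecologicalProfile(matrix(c(1, 1, 0, 0, 0, 1), 3, 2,
    dimnames = list(c("m1", "m2", "m3"), c("e1", "e2"))))
  ct <- containmentTest(media, profile, "e1", nTrials = 10, seed = 3)
  expect_identical(ct$outside_fraction, 0) # z is never in the aggregate
  # an organism whose medium equals every other medium is always contained
  same <- list(m1 = "x", m2 = "x", m3 = "x")
  profAll <- ecologicalProfile(matrix(c(1, 1, 1, 1, 0, 0), 3, 2,
    dimnames = list(c("m1", "m2", "m3"), c("e1", "e2"))))
  ct2 <- containmentTest(same, profAll, "e1", nTrials = 5, seed = 3)
  expect_identical(ct2$inside_fraction, 1)
})

test_that("fastidiousness correlations behave at the extremes and null", {
  sizes <- setNames(as.numeric(1:20), paste0("o", 1:20))
  expect_equal(fastidiousnessCorrelates(sizes, sizes)$rho, 1)
  expect_equal(fastidiousnessCorrelates(sizes, -sizes)$rho, -1)
  expect_error(fastidiousnessCorrelates(sizes[1:2], sizes[1:2]),
               class = "minenvPreconditionError")
  # independent covariate at n = 1000: weak, nonsignificant association
  set.seed(8)
  big <- setNames(rnorm(1000), paste0("b", 1:1000))
  noise <- setNames(rnorm(1000), names(big))
  nullRes <- fastidiousnessCorrelates(big, noise)
  expect_lt(abs(nullRes$rho), 0.1)
  expect_gt(nullRes$p, 0.05)
  expect_identical(nullRes$n, 1000L)
})

test_that("meanPairScore averages over the pairs containing the organism", {
  ps <- data.frame(orgA = c("a", "a"), orgB = c("b", "c"), score = c(1, 3))
  expect_equal(meanPairScore("a", ps), 2)
  expect_equal(meanPairScore("b", ps), 1)
  expect_error(meanPairScore("zz", ps), class = "minenvLookupError")
})

test_that("profiles round-trip through the TSV format and reject bad input", {
  cm <- generateCommunity(communitySpec(nOrganisms = 6, nEnvironments = 3,
                                        coreNutrientsPerEnvironment = 3,
                                        poolSize = 9, seed = 2))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeEcologicalProfile(cm$profile, f)
  back <- readEcologicalProfile(f)
  expect_identical(presence(back), presence(cm$profile))
  noHeader <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("o1\t1\t0", "o2\t0\t1"), noHeader)
  expect_error(readEcologicalProfile(noHeader), class = "minenvParseError")
  allZero <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("organism\te1", "o1\t0"), allZero)
  expect_error(readEcologicalProfile(allZero), class = "minenvParseError")
})
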