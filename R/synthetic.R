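## Seedable synthetic fixtures: toy metabolic models whose minimal media are
## exactly enumerable, an exhaustive brute-force oracle, and synthetic
## communities with a tunable coupling between shared nutrition and
## ecological co-occurrence.

#' Specification of a synthetic toy metabolic model
#'
#' The generated network has a layered structure mirroring how real models
#' satisfy nutritional needs: each biomass precursor can be fed by one or
#' more alternative external nutrients (replaceable sources), and optional
#' "hub" compounds are convertible into several precursors at once,
#' emulating complex nutrients that pack multiple needs into one compound
#' (the way a nucleotide can serve simultaneously as carbon, nitrogen and
#' phosphorus source).
#'
#' @param nPrecursors number of biomass precursors.
#' @param sourcesPerPrecursor alternative external nutrients per precursor.
#' @param nHubs number of hub compounds, each convertible into a random
#'   subset (>= 2) of precursors.
#' @param massAssignment optional named numeric vector of molar masses
#'   (g/mol) for exchange metabolites; unnamed nutrients get distinct
#'   random masses.
#' @param gprDensity fraction of conversion reactions carrying a GPR rule.
#' @param seed integer seed; the model is a deterministic function of the
#'   spec.
#' @return an object of class \code{ToyModelSpec} (validated list).
#' @export
toyModelSpec <- function(nPrecursors = 3, sourcesPerPrecursor = 1,
                         nHubs = 0, massAssignment = NULL,
                         gprDensity = 0, seed = 1) {
  nEx <- nPrecursors * sourcesPerPrecursor + nHubs
  if (nEx > 12) {
    preconditionError(sprintf(
      "spec implies %d exchange reactions; at most 12 are allowed so the brute-force oracle stays enumerable",
      nEx))
  }
  if (nPrecursors < 1 || sourcesPerPrecursor < 1 || nHubs < 0) {
    preconditionError("nPrecursors and sourcesPerPrecursor must be >= 1, nHubs >= 0")
  }
  if (nHubs > 0 && nPrecursors < 2) {
    preconditionError("hub compounds need at least 2 precursors to convert into")
  }
  structure(list(nPrecursors = as.integer(nPrecursors),
                 sourcesPerPrecursor = as.integer(sourcesPerPrecursor),
                 nHubs = as.integer(nHubs),
                 massAssignment = massAssignment,
                 gprDensity = gprDensity, seed = as.integer(seed)),
            class = "ToyModelSpec")
}

#' Generate a toy metabolic model
#'
#' Builds the network described by a [toyModelSpec()]: one exchange plus one
#' conversion reaction per nutrient source, one multi-output conversion per
#' hub, and a biomass reaction consuming one unit of every precursor. The
#' ground-truth structure (which nutrients feed which precursor, hub
#' coverage) is stored in the model's \code{metadata} slot for recovery
#' tests. The generated model always grows on the all-open medium.
#'
#' @param spec a \code{ToyModelSpec}.
#' @return a [MetabolicModel-class].
#' @export
generateToyModel <- function(spec) {
  stopifnot(inherits(spec, "ToyModelSpec"))
  withSeed(spec$seed, buildToyModel(spec))
}

buildToyModel <- function(spec) {
  k <- spec$nPrecursors; s <- spec$sourcesPerPrecursor; h <- spec$nHubs
  nut <- sprintf("N%d_%d", rep(seq_len(k), each = s), rep(seq_len(s), k))
  hub <- if (h > 0) sprintf("H%d", seq_len(h)) else character()
  pre <- sprintf("P%d", seq_len(k))
  exMet <- c(nut, hub)

  mass <- stats::setNames(sample(seq(20, 980, by = 2), length(exMet)), exMet)
  if (!is.null(spec$massAssignment)) {
    given <- intersect(names(spec$massAssignment), exMet)
    mass[given] <- spec$massAssignment[given]
  }
  hubCover <- lapply(seq_len(h), function(i) {
    sort(sample(seq_len(k), sample(2:k, 1)))
  })

  mets <- data.frame(id = c(exMet, pre), molar_mass = c(mass[exMet],
                     rep(NA_real_, k)), compartment = "c",
                     stringsAsFactors = FALSE)
  rid <- character(); lbv <- numeric(); ubv <- numeric(); gpr <- character()
  stoich <- list()
  addRxn <- function(id, s, lb, ub, rule = "") {
    rid <<- c(rid, id); lbv <<- c(lbv, lb); ubv <<- c(ubv, ub)
    gpr <<- c(gpr, rule); stoich[[length(stoich) + 1L]] <<- s
  }
  for (mid in exMet) {
    addRxn(paste0("EX_", mid), stats::setNames(-1, mid), -1000, 1000)
  }
  gcount <- 0L
  convRule <- function() {
    if (spec$gprDensity <= 0 || stats::runif(1) > spec$gprDensity) return("")
    gcount <<- gcount + 1L
    g1 <- sprintf("g%d", gcount)
    style <- sample(3, 1)
    if (style == 1L) return(g1)
    gcount <<- gcount + 1L
    g2 <- sprintf("g%d", gcount)
    if (style == 2L) paste(g1, "and", g2) else paste(g1, "or", g2)
  }
  for (i in seq_len(k)) {
    for (j in seq_len(s)) {
      mid <- sprintf("N%d_%d", i, j)
      addRxn(sprintf("CONV_%s", mid),
             stats::setNames(c(-1, 1), c(mid, pre[i])), 0, 1000, convRule())
    }
  }
  for (i in seq_len(h)) {
    cov <- hubCover[[i]]
    addRxn(sprintf("CONV_H%d", i),
           stats::setNames(c(-1, rep(1, length(cov))),
                           c(hub[i], pre[cov])), 0, 1000, convRule())
  }
  addRxn("BIOMASS", stats::setNames(rep(-1, k), pre), 0, 1000)
  rxns <- data.frame(id = rid, lower_bound = lbv, upper_bound = ubv,
                     gpr = gpr, is_exchange = startsWith(rid, "EX_"),
                     stringsAsFactors = FALSE)
  model <- metabolicModel(
    id = sprintf("toy_s%d_p%d_a%d_h%d", spec$seed, k, s, h),
    metabolites = mets, reactions = rxns, stoich = stoich,
    biomass = "BIOMASS",
    metadata = list(groundTruth = list(
      precursors = pre,
      sources = split(nut, rep(seq_len(k), each = s)),
      hubs = stats::setNames(hubCover, hub),
      masses = mass)))
  if (!grows(model, richMedium(model), 0.1)) {
    solverError("generated toy model fails to grow on the rich medium")
  }
  model
}

#' Brute-force enumeration of minimal media (the oracle)
#'
#' Exhaustively tests uptake subsets of the exchangeable metabolites by
#' plain FBA, in ascending cardinality, exploiting that growth is monotone
#' in the medium (a superset of a feasible set is feasible and is never
#' solved again). Returns the exact minimum cardinality, every feasible set
#' at that cardinality, every minimal feasible set (feasible sets with no
#' feasible proper subset), and the intersection of all feasible sets of
#' any cardinality -- the ground-truth critical metabolites. Refuses models
#' with more than 12 exchanges.
#'
#' @param model a [MetabolicModel-class] with at most 12 exchange reactions.
#' @param cutoff biomass cutoff.
#' @param uptakeMagnitude uptake bound magnitude.
#' @return list with \code{min_size}, \code{minimal_media} (list of
#'   character vectors at the minimum cardinality), \code{minimal_sets}
#'   (all minimal feasible sets), \code{critical} (character vector), and
#'   \code{n_solves}.
#' @export
bruteForceMinimalMedia <- function(model, cutoff = 0.1,
                                   uptakeMagnitude = 1000) {
  ids <- exchangeMetabolites(model)
  E <- length(ids)
  if (E > 12) {
    preconditionError(sprintf(
      "brute force refused: %d exchange reactions (limit 12)", E))
  }
  nMask <- bitwShiftL(1L, E)
  feasible <- logical(nMask)
  nSolves <- 0L
  masks <- order(vapply(0:(nMask - 1L), popcount, integer(1)))
  minimalSets <- list()
  for (mask in (0:(nMask - 1L))[masks]) {
    idx <- mask + 1L
    # a superset of a known feasible set is feasible and never minimal
    dominated <- FALSE
    if (mask > 0L) {
      for (bit in 0:(E - 1L)) {
        if (bitwAnd(mask, bitwShiftL(1L, bit)) != 0L) {
          sub <- bitwAnd(mask, bitwNot(bitwShiftL(1L, bit)))
          if (feasible[sub + 1L]) { dominated <- TRUE; break }
        }
      }
    }
    if (dominated) { feasible[idx] <- TRUE; next }
    members <- ids[bitwAnd(mask, bitwShiftL(1L, 0:(E - 1L))) != 0L]
    ok <- grows(model, medium(members, uptakeMagnitude), cutoff)
    nSolves <- nSolves + 1L
    feasible[idx] <- ok
    if (ok) minimalSets[[length(minimalSets) + 1L]] <- members
  }
  if (!length(minimalSets)) {
    infeasibleError(sprintf(
      "model '%s' cannot reach biomass %g on any uptake subset",
      model@id, cutoff))
  }
  sizes <- lengths(minimalSets)
  minSize <- min(sizes)
  critical <- Reduce(intersect, minimalSets)
  list(min_size = as.integer(minSize),
       minimal_media = lapply(minimalSets[sizes == minSize], sort),
       minimal_sets = lapply(minimalSets, sort),
       critical = sort(critical),
       n_solves = nSolves)
}

popcount <- function(x) {
  n <- 0L
  while (x > 0L) { n <- n + bitwAnd(x, 1L); x <- bitwShiftR(x, 1L) }
  n
}

#' Brute-force counterpart of the unique minimal environment
#'
#' Among the minimum-cardinality feasible uptake sets enumerated by
#' [bruteForceMinimalMedia()], selects the one minimizing the molar-rank
#' sum, breaking residual ties toward the lexicographically smallest sorted
#' rank vector -- the same disambiguation rule as [uniqueMinenv()], derived
#' here by direct enumeration instead of optimization.
#'
#' @inheritParams bruteForceMinimalMedia
#' @param oracle optional precomputed result of [bruteForceMinimalMedia()].
#' @return character vector of member metabolite ids.
#' @export
bruteForceUniqueMinenv <- function(model, cutoff = 0.1,
                                   uptakeMagnitude = 1000, oracle = NULL) {
  if (is.null(oracle)) {
    oracle <- bruteForceMinimalMedia(model, cutoff, uptakeMagnitude)
  }
  ranks <- molarOrdering(model)
  keyOf <- function(s) sort(unname(ranks[s]))
  cands <- oracle$minimal_media
  keys <- lapply(cands, keyOf)
  sums <- vapply(keys, sum, numeric(1))
  cands <- cands[sums == min(sums)]
  keys <- keys[sums == min(sums)]
  best <- 1L
  if (length(cands) > 1L) {
    for (i in seq_along(cands)[-1L]) {
      a <- keys[[i]]; b <- keys[[best]]
      cmp <- which(a != b)
      if (length(cmp) && a[cmp[1L]] < b[cmp[1L]]) best <- i
    }
  }
  sort(cands[[best]])
}

#' Specification of a synthetic microbial community
#'
#' Describes a community in which each ecological environment carries a
#' core set of nutrients and each member organism draws the nutrient
#' sources of its biomass precursors from the cores of its environments
#' with probability \code{coupling}, or uniformly from the global nutrient
#' pool otherwise. At \code{coupling = 1} co-occurring organisms share
#' nutritional requirements maximally; at \code{coupling = 0} requirements
#' are statistically independent of co-occurrence.
#'
#' @param nOrganisms number of organisms (default 50).
#' @param nEnvironments number of environments (default 10).
#' @param coreNutrientsPerEnvironment size of each environment's nutrient
#'   core (default 6).
#' @param coupling probability in \[0, 1\] of drawing from the environment
#'   cores.
#' @param nPrecursors biomass precursors per organism (default 5).
#' @param poolSize size of the global nutrient pool (default 60; must be
#'   large enough to give every environment a disjoint core).
#' @param environmentsPerOrganism organisms are assigned to 1 to this many
#'   environments, uniformly (default 2).
#' @param seed integer seed.
#' @return an object of class \code{CommunitySpec}.
#' @export
communitySpec <- function(nOrganisms = 50, nEnvironments = 10,
                          coreNutrientsPerEnvironment = 6, coupling = 1,
                          nPrecursors = 5, poolSize = 60,
                          environmentsPerOrganism = 2, seed = 1) {
  if (coupling < 0 || coupling > 1) {
    preconditionError("coupling must be in [0, 1]")
  }
  if (poolSize < coreNutrientsPerEnvironment * nEnvironments) {
    preconditionError(
      "poolSize must be >= coreNutrientsPerEnvironment * nEnvironments (cores are disjoint)")
  }
  structure(list(nOrganisms = as.integer(nOrganisms),
                 nEnvironments = as.integer(nEnvironments),
                 coreNutrientsPerEnvironment =
                   as.integer(coreNutrientsPerEnvironment),
                 coupling = coupling,
                 nPrecursors = as.integer(nPrecursors),
                 poolSize = as.integer(poolSize),
                 environmentsPerOrganism = as.integer(environmentsPerOrganism),
                 seed = as.integer(seed)),
            class = "CommunitySpec")
}

#' Generate a synthetic community
#'
#' Builds the community described by a [communitySpec()]: a global nutrient
#' pool with fixed distinct molar masses, per-environment nutrient cores,
#' organism-environment assignments, and one toy metabolic model per
#' organism whose precursor sources follow the coupling rule. Everything is
#' a deterministic function of the seed.
#'
#' @param spec a \code{CommunitySpec}.
#' @return list with \code{models} (named list of [MetabolicModel-class]),
#'   \code{profile} (an [EcologicalProfile-class]), and \code{groundTruth}
#'   (pool, cores, assignments, per-organism nutrient sets).
#' @export
generateCommunity <- function(spec) {
  stopifnot(inherits(spec, "CommunitySpec"))
  withSeed(spec$seed, buildCommunity(spec))
}

buildCommunity <- function(spec) {
  pool <- sprintf("nut%02d", seq_len(spec$poolSize))
  poolMass <- stats::setNames(
    sample(seq(20, 978, by = 2), spec$poolSize), pool)
  envs <- sprintf("env%02d", seq_len(spec$nEnvironments))
  # disjoint cores: each environment owns its own slice of the pool
  shuffled <- sample(pool)
  cores <- stats::setNames(lapply(seq_along(envs), function(i) {
    sort(shuffled[(i - 1L) * spec$coreNutrientsPerEnvironment +
                    seq_len(spec$coreNutrientsPerEnvironment)])
  }), envs)
  orgs <- sprintf("org%03d", seq_len(spec$nOrganisms))
  presence <- matrix(0, spec$nOrganisms, spec$nEnvironments,
                     dimnames = list(orgs, envs))
  models <- vector("list", spec$nOrganisms)
  names(models) <- orgs
  orgNutrients <- vector("list", spec$nOrganisms)
  names(orgNutrients) <- orgs
  for (o in seq_len(spec$nOrganisms)) {
    nEnv <- sample(seq_len(spec$environmentsPerOrganism), 1)
    mine <- sample(envs, min(nEnv, length(envs)))
    presence[o, mine] <- 1
    coreUnion <- sort(unique(unlist(cores[mine])))
    nutrients <- vapply(seq_len(spec$nPrecursors), function(p) {
      if (stats::runif(1) < spec$coupling) sample(coreUnion, 1)
      else sample(pool, 1)
    }, character(1))
    uniq <- unique(nutrients)
    mets <- data.frame(
      id = c(uniq, sprintf("P%d", seq_len(spec$nPrecursors))),
      molar_mass = c(poolMass[uniq], rep(NA_real_, spec$nPrecursors)),
      compartment = "c", stringsAsFactors = FALSE)
    rid <- character(); lbv <- numeric(); ubv <- numeric(); st <- list()
    for (mid in uniq) {
      rid <- c(rid, paste0("EX_", mid)); lbv <- c(lbv, -1000)
      ubv <- c(ubv, 1000); st[[length(st) + 1L]] <- stats::setNames(-1, mid)
    }
    for (p in seq_len(spec$nPrecursors)) {
      rid <- c(rid, sprintf("CONV_%d", p)); lbv <- c(lbv, 0)
      ubv <- c(ubv, 1000)
      st[[length(st) + 1L]] <-
        stats::setNames(c(-1, 1), c(nutrients[p], sprintf("P%d", p)))
    }
    rid <- c(rid, "BIOMASS"); lbv <- c(lbv, 0); ubv <- c(ubv, 1000)
    st[[length(st) + 1L]] <-
      stats::setNames(rep(-1, spec$nPrecursors),
                      sprintf("P%d", seq_len(spec$nPrecursors)))
    models[[o]] <- metabolicModel(
      id = orgs[o], metabolites = mets,
      reactions = data.frame(id = rid, lower_bound = lbv, upper_bound = ubv,
                             is_exchange = startsWith(rid, "EX_"),
                             stringsAsFactors = FALSE),
      stoich = st, biomass = "BIOMASS",
      metadata = list(nutrients = sort(uniq)))
    orgNutrients[[o]] <- sort(uniq)
  }
  list(models = models,
       profile = ecologicalProfile(presence),
       groundTruth = list(pool = pool, poolMass = poolMass, cores = cores,
                          nutrients = orgNutrients))
}
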