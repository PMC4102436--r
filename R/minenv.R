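## Minimal-environment operations: stage-1 size, stage-2 unique set,
## critical core, degeneracy swap check, preferred variant, gene-deletion
## stability, and the tab-separated result tables.

#' Minimal number of consumed exchange metabolites
#'
#' Stage 1: solves the MILP that maximizes the number of exchange
#' metabolites forced shut for uptake while biomass still reaches the
#' cutoff, yielding the provably minimal cardinality of a growth-supporting
#' uptake set. The witness set is one optimal support (a "non-unique
#' minimal environment"); stage 2 ([uniqueMinenv()]) disambiguates it.
#'
#' @param model a [MetabolicModel-class].
#' @param cutoff biomass cutoff in flux units (default 0.1).
#' @param uptakeMagnitude uptake bound magnitude and MILP big-M constant.
#' @param exempt exchange-metabolite ids whose uptake is always free and
#'   never counted (empty by default: freely available inorganics are
#'   counted like any other nutrient unless the caller opts out).
#' @param timeLimit MILP wall-clock limit in seconds.
#' @param verbose log one line per MILP solve.
#' @return list with \code{size} (integer) and \code{witness}
#'   (character vector of metabolite ids).
#' @export
minimalMediumSize <- function(model, cutoff = 0.1, uptakeMagnitude = 1000,
                              exempt = character(), timeLimit = 300,
                              verbose = FALSE) {
  stopifnot(is(model, "MetabolicModel"), cutoff >= 0)
  if (!grows(model, richMedium(model, uptakeMagnitude), cutoff)) {
    infeasibleError(sprintf(
      "model '%s' cannot reach biomass %g even with all exchanges open",
      model@id, cutoff))
  }
  milp <- buildMinenvMILP(model, cutoff, uptakeMagnitude, exempt)
  E <- length(milp$thetaIdx)
  if (E == 0L) return(list(size = 0L, witness = character()))
  witness <- greedyWitness(model, cutoff, uptakeMagnitude, exempt, milp)
  sol <- milpSolve(milp, rep(1, E), timeLimit = timeLimit,
                   incumbent = list(objective = E - length(witness), x = NULL),
                   verbose = verbose, stage = "stage1")
  if (sol$status != "optimal") {
    infeasibleError("stage-1 MILP infeasible despite rich-medium growth")
  }
  size <- as.integer(E - sol$objective)
  if (!is.null(sol$x)) {
    witness <- milp$metabolite[sol$x[milp$thetaIdx] == 0]
  }
  stopifnot(length(witness) == size)
  if (!grows(model, medium(c(witness, exempt), uptakeMagnitude), cutoff)) {
    solverError("stage-1 witness fails the FBA growth re-check")
  }
  list(size = size, witness = sort(witness))
}

## Stage-2 core shared by uniqueMinenv and preferredMinenv: maximize an
## integer weight over theta at fixed cardinality, then make the selected
## set unique by a fix-and-resolve sweep in `order` (ascending preference),
## keeping a metabolite exactly when some optimal solution contains it.
solveStage2 <- function(model, K, weights, order, cutoff, uptakeMagnitude,
                        exempt, timeLimit, verbose, warmSet = NULL) {
  milp <- buildMinenvMILP(model, cutoff, uptakeMagnitude, exempt,
                          cardinality = K)
  E <- length(milp$thetaIdx)
  inc <- NULL
  if (!is.null(warmSet)) {
    inc <- list(objective = sum(weights[!(milp$metabolite %in% warmSet)]),
                x = NULL)
  }
  sol <- milpSolve(milp, weights, timeLimit = timeLimit, incumbent = inc,
                   verbose = verbose, stage = "stage2")
  if (sol$status != "optimal") {
    solverError("stage-2 MILP infeasible at the stage-1 cardinality")
  }
  z2 <- sol$objective
  fix0 <- integer(); fix1 <- integer()
  for (k in order) {
    if (length(fix0) >= K) break
    remaining <- setdiff(order, c(fix0, fix1))
    if (length(fix0) + length(remaining) <= K) {
      # every remaining candidate is needed to reach cardinality K
      fix0 <- c(fix0, remaining)
      break
    }
    if (k %in% fix0 || k %in% fix1) next
    trial <- milpSolve(milp, weights, timeLimit = timeLimit,
                       fix0 = c(fix0, k), fix1 = fix1,
                       verbose = FALSE, stage = "stage2-fix")
    if (trial$status == "optimal" && trial$objective == z2) {
      fix0 <- c(fix0, k)
    } else {
      fix1 <- c(fix1, k)
    }
  }
  members <- sort(milp$metabolite[fix0])
  if (length(members) != K) {
    solverError("stage-2 refinement lost the cardinality constraint")
  }
  theta <- stats::setNames(as.numeric(!(milp$metabolite %in% members)),
                           milp$metabolite)
  list(members = members, theta = theta, objective = z2)
}

#' Unique minimal environment of a model
#'
#' Runs both optimization stages: stage 1 fixes the minimal number of
#' consumed exchange metabolites, stage 2 selects, among all media of that
#' minimal cardinality that sustain the biomass cutoff, the one minimizing
#' the summed molar-weight rank of its members (ranks from
#' [molarOrdering()]: ascending mass, ties by id). Residual rank-sum ties
#' are resolved toward the lexicographically smallest sorted rank vector,
#' so the reported set is a deterministic function of the model alone.
#' The result is verified by plain FBA and each member is confirmed
#' necessary (removing it drops biomass below the cutoff).
#'
#' @inheritParams minimalMediumSize
#' @param critical also compute the critical subset
#'   ([criticalMetabolites()]) and store it in the result.
#' @return a [MinenvResult-class].
#' @examples
#' m <- generateToyModel(toyModelSpec(nPrecursors = 2, seed = 7))
#' uniqueMinenv(m)
#' @export
uniqueMinenv <- function(model, cutoff = 0.1, uptakeMagnitude = 1000,
                         exempt = character(), timeLimit = 300,
                         verbose = FALSE, critical = FALSE) {
  st1 <- minimalMediumSize(model, cutoff, uptakeMagnitude, exempt,
                           timeLimit, verbose)
  ranks <- molarOrderingRestricted(model, exempt)
  if (st1$size == 0L) {
    res <- methods::new("MinenvResult", organism = model@id, minimalSize = 0L,
                        minenv = character(), molarRankSum = 0,
                        cutoff = cutoff, solverStatus = "optimal",
                        theta = stats::setNames(rep(1, length(ranks)),
                                                names(ranks)))
  } else {
    ord <- match(names(ranks), exchangeMetabolitesRestricted(model, exempt))
    st2 <- solveStage2(model, st1$size, weights = rankWeights(model, exempt),
                       order = ord, cutoff = cutoff,
                       uptakeMagnitude = uptakeMagnitude, exempt = exempt,
                       timeLimit = timeLimit, verbose = verbose,
                       warmSet = st1$witness)
    res <- methods::new("MinenvResult", organism = model@id,
                        minimalSize = st1$size, minenv = st2$members,
                        molarRankSum = sum(ranks[st2$members]),
                        cutoff = cutoff, solverStatus = "optimal",
                        theta = st2$theta)
  }
  verifyMinenv(model, res, uptakeMagnitude, exempt)
  if (critical) {
    res@critical <- criticalMetabolites(model, res,
                                        uptakeMagnitude = uptakeMagnitude)
  }
  res
}

## exchange metabolites and rank helpers restricted to the counted
## (non-exempt) set, in exchange order
exchangeMetabolitesRestricted <- function(model, exempt) {
  setdiff(exchangeMetabolites(model), exempt)
}

molarOrderingRestricted <- function(model, exempt = character()) {
  ids <- exchangeMetabolitesRestricted(model, exempt)
  if (!length(ids)) return(stats::setNames(integer(), character()))
  mass <- resolveMasses(model, ids)
  ord <- order(mass, ids, method = "radix")
  stats::setNames(seq_along(ids), ids[ord])
}

rankWeights <- function(model, exempt = character()) {
  ids <- exchangeMetabolitesRestricted(model, exempt)
  ranks <- molarOrderingRestricted(model, exempt)
  unname(ranks[match(ids, names(ranks))])
}

## FBA re-check: the reported set grows, and no member is redundant. Any
## redundant member is pruned (guards against MILP tolerance leakage).
verifyMinenv <- function(model, res, uptakeMagnitude, exempt) {
  if (!grows(model, medium(c(res@minenv, exempt), uptakeMagnitude),
             res@cutoff)) {
    solverError("reported minimal environment fails the FBA growth re-check")
  }
  for (m in res@minenv) {
    if (grows(model, medium(c(setdiff(res@minenv, m), exempt),
                            uptakeMagnitude), res@cutoff)) {
      solverError(sprintf(
        "member '%s' of the reported minimal environment is redundant", m))
    }
  }
  invisible(TRUE)
}

#' Critical metabolites of a minimal environment
#'
#' A member is critical when the organism cannot grow without its uptake
#' even if every other exchangeable metabolite is freely available: closing
#' that single exchange under the otherwise-open rich medium drops biomass
#' below the cutoff. Critical metabolites are exactly the compounds present
#' in every growth-supporting uptake set.
#'
#' @param model a [MetabolicModel-class].
#' @param result a [MinenvResult-class] from [uniqueMinenv()] on this model.
#' @param uptakeMagnitude uptake bound magnitude.
#' @return character vector (subset of \code{minenv(result)}).
#' @export
criticalMetabolites <- function(model, result, uptakeMagnitude = 1000) {
  stopifnot(is(model, "MetabolicModel"), is(result, "MinenvResult"))
  allEx <- exchangeMetabolites(model)
  crit <- vapply(result@minenv, function(m) {
    !grows(model, medium(setdiff(allEx, m), uptakeMagnitude), result@cutoff)
  }, logical(1))
  unname(result@minenv[crit])
}

#' Equal-mass swap degeneracy check
#'
#' For every member of the minimal environment, tests whether any
#' non-member exchangeable metabolite of identical molar mass could take
#' its place while preserving growth at the cutoff. A nonempty answer means
#' the mass-rank ordering alone did not pin down the reported set among
#' equal-weight alternatives.
#'
#' @param model a [MetabolicModel-class].
#' @param result a [MinenvResult-class] for this model.
#' @param uptakeMagnitude uptake bound magnitude.
#' @return data.frame with columns \code{in_compound} (the substitute) and
#'   \code{out_compound} (the member it replaces); zero rows when no swap
#'   is feasible.
#' @export
swapDegeneracyCheck <- function(model, result, uptakeMagnitude = 1000) {
  stopifnot(is(model, "MetabolicModel"), is(result, "MinenvResult"))
  out <- data.frame(in_compound = character(), out_compound = character(),
                    stringsAsFactors = FALSE)
  if (!length(result@minenv)) return(out)
  allEx <- exchangeMetabolites(model)
  mass <- stats::setNames(resolveMasses(model, allEx), allEx)
  nonMembers <- setdiff(allEx, result@minenv)
  for (m in result@minenv) {
    same <- nonMembers[abs(mass[nonMembers] - mass[m]) < 1e-9]
    for (cand in same) {
      swapped <- c(setdiff(result@minenv, m), cand)
      if (grows(model, medium(swapped, uptakeMagnitude), result@cutoff)) {
        out <- rbind(out, data.frame(in_compound = cand, out_compound = m,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out
}

#' Minimal environment preferring a reference compound set
#'
#' Recomputes the stage-2 selection with a two-tier objective: first
#' minimize the number of members outside the preferred set (e.g. compounds
#' present in a curated media collection), then minimize the molar-rank
#' sum. The stage-1 cardinality is unchanged. Implemented as a single
#' weighted objective with the tier-1 weight exceeding any attainable
#' rank-sum difference, so tier 2 can never override tier 1.
#'
#' @inheritParams minimalMediumSize
#' @param preferred character vector of preferred exchange-metabolite ids.
#' @return a [MinenvResult-class].
#' @export
preferredMinenv <- function(model, preferred, cutoff = 0.1,
                            uptakeMagnitude = 1000, exempt = character(),
                            timeLimit = 300, verbose = FALSE) {
  st1 <- minimalMediumSize(model, cutoff, uptakeMagnitude, exempt,
                           timeLimit, verbose)
  ranks <- molarOrderingRestricted(model, exempt)
  if (st1$size == 0L) {
    res <- methods::new("MinenvResult", organism = model@id, minimalSize = 0L,
                        minenv = character(), molarRankSum = 0,
                        cutoff = cutoff, solverStatus = "optimal",
                        theta = stats::setNames(rep(1, length(ranks)),
                                                names(ranks)))
    verifyMinenv(model, res, uptakeMagnitude, exempt)
    return(res)
  }
  ids <- exchangeMetabolitesRestricted(model, exempt)
  E <- length(ids)
  tier1 <- E * (E + 1) / 2 + 1 # exceeds the largest possible rank sum
  w <- unname(ranks[match(ids, names(ranks))]) +
    tier1 * !(ids %in% preferred)
  ord <- order(w, seq_along(ids))
  st2 <- solveStage2(model, st1$size, weights = w, order = ord,
                     cutoff = cutoff, uptakeMagnitude = uptakeMagnitude,
                     exempt = exempt, timeLimit = timeLimit,
                     verbose = verbose, warmSet = st1$witness)
  res <- methods::new("MinenvResult", organism = model@id,
                      minimalSize = st1$size, minenv = st2$members,
                      molarRankSum = sum(ranks[st2$members]),
                      cutoff = cutoff, solverStatus = "optimal",
                      theta = st2$theta)
  verifyMinenv(model, res, uptakeMagnitude, exempt)
  res
}

#' Stability of the minimal environment under single-gene deletions
#'
#' Deletes each gene in turn (through the GPR rules), recomputes the unique
#' minimal environment of the perturbed model, and reports which deletions
#' changed the composition or the size of the set. Genes whose deletion
#' abolishes growth even on the all-open rich medium are recorded as lethal
#' and excluded from both ratios.
#'
#' @inheritParams minimalMediumSize
#' @return list with \code{fraction_composition_changed},
#'   \code{fraction_size_changed}, \code{lethal} (gene ids), and
#'   \code{per_gene} (data.frame: gene, lethal, composition_changed,
#'   size_changed, size).
#' @export
minenvStabilityUnderDeletions <- function(model, cutoff = 0.1,
                                          uptakeMagnitude = 1000,
                                          exempt = character(),
                                          timeLimit = 300, verbose = FALSE) {
  if (!length(model@genes)) {
    preconditionError(sprintf("model '%s' has no GPR rules", model@id))
  }
  base <- uniqueMinenv(model, cutoff, uptakeMagnitude, exempt, timeLimit,
                       verbose)
  per <- lapply(model@genes, function(g) {
    m2 <- deleteGene(model, g)
    if (!grows(m2, richMedium(m2, uptakeMagnitude), cutoff)) {
      return(data.frame(gene = g, lethal = TRUE, composition_changed = NA,
                        size_changed = NA, size = NA_integer_,
                        stringsAsFactors = FALSE))
    }
    r2 <- uniqueMinenv(m2, cutoff, uptakeMagnitude, exempt, timeLimit,
                       verbose)
    data.frame(gene = g, lethal = FALSE,
               composition_changed = !setequal(r2@minenv, base@minenv),
               size_changed = r2@minimalSize != base@minimalSize,
               size = r2@minimalSize, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  ok <- !per$lethal
  list(
    fraction_composition_changed = mean(per$composition_changed[ok]),
    fraction_size_changed = mean(per$size_changed[ok]),
    lethal = per$gene[per$lethal],
    per_gene = per
  )
}

#' Write minimal-environment results as a tab-separated table
#'
#' One row per organism: id, minimal size, comma-joined member ids,
#' comma-joined critical ids (empty when not computed).
#'
#' @param results a [MinenvResult-class] or list of them.
#' @param path output path or connection (\code{""} for standard output).
#' @return the table, invisibly.
#' @export
writeMinenvTable <- function(results, path = "") {
  if (is(results, "MinenvResult")) results <- list(results)
  tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(
      organism = r@organism,
      minimal_size = r@minimalSize,
      minenv = paste(r@minenv, collapse = ","),
      critical = if (is.null(r@critical)) "" else
        paste(r@critical, collapse = ","),
      stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Read a minimal-environment table
#'
#' @param path a file written by [writeMinenvTable()].
#' @return named list of character vectors (organism -> member ids); the
#'   sizes and critical sets are attached as attributes \code{sizes} and
#'   \code{critical}.
#' @export
readMinenvTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(minenv = "character",
                                          critical = "character"))
  need <- c("organism", "minimal_size", "minenv")
  if (!all(need %in% names(tab))) {
    parseError(paste("minenv table must have columns:",
                     paste(need, collapse = ", ")))
  }
  splitIds <- function(x) {
    if (is.na(x) || !nzchar(x)) character() else strsplit(x, ",")[[1]]
  }
  sets <- lapply(tab$minenv, splitIds)
  names(sets) <- tab$organism
  attr(sets, "sizes") <- stats::setNames(tab$minimal_size, tab$organism)
  if ("critical" %in% names(tab)) {
    attr(sets, "critical") <- stats::setNames(
      lapply(tab$critical, splitIds), tab$organism)
  }
  sets
}
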