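## Comparative ecology of minimal environments: Jaccard similarity,
## aggregate media, within- vs across-environment resampling tests, and
## fastidiousness-covariate correlations.

#' Construct an EcologicalProfile
#'
#' @param presence binary matrix (or data.frame) with organism rownames and
#'   environment colnames.
#' @return an [EcologicalProfile-class].
#' @export
ecologicalProfile <- function(presence) {
  presence <- as.matrix(presence)
  storage.mode(presence) <- "numeric"
  methods::new("EcologicalProfile", presence = presence)
}

#' Read / write a presence-absence profile
#'
#' Tab-separated organism x environment 0/1 table; first column holds the
#' organism ids, the header row the environment ids.
#'
#' @param path file path.
#' @return an [EcologicalProfile-class].
#' @export
readEcologicalProfile <- function(path) {
  tab <- tryCatch(utils::read.delim(path, check.names = FALSE),
                  error = function(e) parseError(conditionMessage(e)))
  if (ncol(tab) < 2) {
    parseError(sprintf(
      "profile '%s' needs an organism column plus >= 1 environment column (is the header present?)",
      path))
  }
  if (any(grepl("^[0-9.]+$", names(tab)))) {
    parseError(sprintf(
      "profile '%s' has numeric column names; is the header row missing?",
      path))
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m) || !all(m %in% c(0, 1))) {
    parseError(sprintf("profile '%s' must contain only 0/1 entries", path))
  }
  rownames(m) <- as.character(tab[[1]])
  tryCatch(ecologicalProfile(m), error = function(e) {
    parseError(sprintf("profile '%s' invalid: %s", path,
                       conditionMessage(e)))
  })
}

#' @rdname readEcologicalProfile
#' @param profile an [EcologicalProfile-class].
#' @export
writeEcologicalProfile <- function(profile, path) {
  tab <- data.frame(organism = organisms(profile),
                    presence(profile), check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Jaccard similarity of two sets
#'
#' \eqn{|s1 \cap s2| / |s1 \cup s2|}; two empty sets are identical, so
#' their similarity is defined as 1.
#'
#' @param s1,s2 vectors interpreted as sets.
#' @return similarity in \[0, 1\].
#' @export
jaccard <- function(s1, s2) {
  s1 <- unique(s1); s2 <- unique(s2)
  u <- length(union(s1, s2))
  if (u == 0) return(1)
  length(intersect(s1, s2)) / u
}

#' Aggregate minimal environment of a group of organisms
#'
#' The union of the groups' member sets: the shared nutrient pool the group
#' would collectively require.
#'
#' @param minenvs nonempty list of character vectors.
#' @return character vector (sorted union).
#' @export
aggregateMinenv <- function(minenvs) {
  if (!length(minenvs)) {
    preconditionError("aggregateMinenv needs a nonempty list of sets")
  }
  sort(unique(unlist(minenvs, use.names = FALSE)))
}

## organisms present both in the minenv map and the profile
sharedOrganisms <- function(minenvs, profile) {
  intersect(names(minenvs), organisms(profile))
}

## environment-membership sets per organism
environmentSets <- function(profile, orgs) {
  p <- presence(profile)
  lapply(stats::setNames(orgs, orgs),
         function(o) colnames(p)[p[o, ] == 1])
}

#' Binned similarity curve of nutritional vs ecological distance
#'
#' For every unordered pair of shared organisms computes the ecological
#' distance (1 - Jaccard similarity of environment-membership sets) and the
#' minimal-environment similarity (100 x Jaccard similarity of the member
#' sets), bins the pairs into equal-width ecological-distance bins over
#' \[0, 1\], and reports per bin and per similarity threshold the fraction
#' of pairs whose similarity exceeds the threshold. A Spearman correlation
#' of the bin ratio against the bin midpoint summarizes each threshold's
#' curve; bins with fewer than \code{minPairsPerBin} pairs are flagged and
#' excluded from the correlation.
#'
#' @param minenvs named list: organism -> character vector of member ids.
#' @param profile an [EcologicalProfile-class].
#' @param nBins number of equal-width distance bins (default 20).
#' @param thresholds similarity percentage thresholds (default 30, 50, 70).
#' @param minPairsPerBin minimum pairs for a bin to enter the correlation
#'   (default 1000, the exclusion rule used for large surveys; lower it for
#'   small communities).
#' @return a [SimilarityCurve-class].
#' @export
binnedSimilarityCurve <- function(minenvs, profile, nBins = 20,
                                  thresholds = c(30, 50, 70),
                                  minPairsPerBin = 1000) {
  orgs <- sharedOrganisms(minenvs, profile)
  if (length(orgs) < 2) {
    preconditionError("need >= 2 organisms shared between minenvs and profile")
  }
  envSets <- environmentSets(profile, orgs)
  nOrg <- length(orgs)
  pairIdx <- utils::combn(nOrg, 2)
  ecoDist <- numeric(ncol(pairIdx))
  nutSim <- numeric(ncol(pairIdx))
  for (k in seq_len(ncol(pairIdx))) {
    a <- orgs[pairIdx[1, k]]; b <- orgs[pairIdx[2, k]]
    ecoDist[k] <- 1 - jaccard(envSets[[a]], envSets[[b]])
    nutSim[k] <- 100 * jaccard(minenvs[[a]], minenvs[[b]])
  }
  edges <- seq(0, 1, length.out = nBins + 1)
  bin <- pmin(findInterval(ecoDist, edges, rightmost.closed = TRUE), nBins)
  counts <- tabulate(bin, nBins)
  ratio <- matrix(NA_real_, nBins, length(thresholds),
                  dimnames = list(NULL, paste0("ge", thresholds)))
  for (t in seq_along(thresholds)) {
    above <- nutSim >= thresholds[t]
    for (bi in seq_len(nBins)) {
      if (counts[bi] > 0) ratio[bi, t] <- mean(above[bin == bi])
    }
  }
  flagged <- counts < minPairsPerBin
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  sp <- do.call(rbind, lapply(seq_along(thresholds), function(t) {
    use <- !flagged & counts > 0
    if (sum(use) >= 3) {
      ct <- suppressWarnings(stats::cor.test(mid[use], ratio[use, t],
                                             method = "spearman"))
      data.frame(threshold = thresholds[t], rho = unname(ct$estimate),
                 p = ct$p.value, nBins = sum(use))
    } else {
      data.frame(threshold = thresholds[t], rho = NA_real_, p = NA_real_,
                 nBins = sum(use))
    }
  }))
  psp <- do.call(rbind, lapply(seq_along(thresholds), function(t) {
    ct <- suppressWarnings(stats::cor.test(
      1 - ecoDist, as.numeric(nutSim >= thresholds[t]), method = "spearman"))
    data.frame(threshold = thresholds[t], rho = unname(ct$estimate),
               p = ct$p.value, nPairs = length(ecoDist))
  }))
  methods::new("SimilarityCurve", binEdges = edges, thresholds = thresholds,
               ratio = ratio, pairCounts = counts, flagged = flagged,
               spearman = sp, pairSpearman = psp)
}

#' Split-half aggregate-environment distance test
#'
#' Repeatedly splits the member organisms of one environment into two
#' disjoint groups, computes the Jaccard distance between the two groups'
#' aggregate minimal environments, and compares against control trials in
#' which both groups are drawn from organisms strictly outside the
#' environment. Smaller within-environment distances than random distances
#' indicate that co-occurring organisms share nutritional requirements.
#'
#' @param minenvs named list: organism -> member set.
#' @param profile an [EcologicalProfile-class].
#' @param environment environment id.
#' @param nTrials number of random splits (default 100).
#' @param groupSize organisms per group; defaults to half the member count.
#' @param seed integer seed; results are a deterministic function of it.
#' @return list with \code{within_mean}, \code{within_sd},
#'   \code{random_mean}, \code{random_sd} and \code{per_trial}
#'   (data.frame: trial, within, random).
#' @export
splitHalfEnvironmentDistance <- function(minenvs, profile, environment,
                                         nTrials = 100, groupSize = NULL,
                                         seed = 1) {
  orgs <- sharedOrganisms(minenvs, profile)
  p <- presence(profile)
  if (!environment %in% colnames(p)) {
    lookupError(sprintf("unknown environment '%s'", environment))
  }
  members <- intersect(orgs, rownames(p)[p[, environment] == 1])
  outsiders <- setdiff(orgs, rownames(p)[p[, environment] == 1])
  if (is.null(groupSize)) groupSize <- floor(length(members) / 2)
  if (length(members) < 2 * groupSize || groupSize < 1) {
    preconditionError(sprintf(
      "environment '%s' has %d members with minimal environments; need >= 2 x groupSize (%d)",
      environment, length(members), groupSize))
  }
  if (length(outsiders) < 2 * groupSize) {
    preconditionError(sprintf(
      "only %d organisms outside environment '%s'; need >= 2 x groupSize",
      length(outsiders), environment))
  }
  aggDist <- function(g1, g2) {
    1 - jaccard(aggregateMinenv(minenvs[g1]), aggregateMinenv(minenvs[g2]))
  }
  per <- withSeed(seed, {
    do.call(rbind, lapply(seq_len(nTrials), function(tr) {
      pick <- sample(members, 2 * groupSize)
      g1 <- pick[seq_len(groupSize)]
      g2 <- pick[groupSize + seq_len(groupSize)]
      rpick <- sample(outsiders, 2 * groupSize)
      r1 <- rpick[seq_len(groupSize)]
      r2 <- rpick[groupSize + seq_len(groupSize)]
      data.frame(trial = tr, within = aggDist(g1, g2),
                 random = aggDist(r1, r2))
    }))
  })
  list(within_mean = mean(per$within), within_sd = stats::sd(per$within),
       random_mean = mean(per$random), random_sd = stats::sd(per$random),
       per_trial = per)
}

#' In-silico growth on aggregate media
#'
#' Per trial, builds an aggregate medium from the minimal environments of a
#' random fraction of an environment's member organisms, then asks by flux
#' balance analysis which held-out members (inside) and which randomly
#' sampled non-members (outside, matched in number) grow on it. Builder
#' organisms are never tested.
#'
#' @param models named list: organism -> [MetabolicModel-class].
#' @param minenvs named list: organism -> member set.
#' @param profile an [EcologicalProfile-class].
#' @param environment environment id.
#' @param holdoutFraction fraction of members held out of the aggregate
#'   (default 0.5: the aggregate is built from half the members).
#' @param cutoff biomass cutoff.
#' @param nTrials number of trials (default 20).
#' @param seed integer seed.
#' @param uptakeMagnitude uptake bound magnitude.
#' @return list with \code{inside_growth_fraction},
#'   \code{outside_growth_fraction} and \code{per_trial}
#'   (data.frame: trial, inside, outside, aggregate_size).
#' @export
growthOnAggregate <- function(models, minenvs, profile, environment,
                              holdoutFraction = 0.5, cutoff = 0.1,
                              nTrials = 20, seed = 1,
                              uptakeMagnitude = 1000) {
  orgs <- intersect(sharedOrganisms(minenvs, profile), names(models))
  p <- presence(profile)
  if (!environment %in% colnames(p)) {
    lookupError(sprintf("unknown environment '%s'", environment))
  }
  members <- intersect(orgs, rownames(p)[p[, environment] == 1])
  outsiders <- setdiff(orgs, rownames(p)[p[, environment] == 1])
  if (length(members) < 2) {
    preconditionError(sprintf(
      "environment '%s' has %d members with models; need >= 2",
      environment, length(members)))
  }
  nHold <- max(1L, round(holdoutFraction * length(members)))
  nHold <- min(nHold, length(members) - 1L)
  per <- withSeed(seed, {
    do.call(rbind, lapply(seq_len(nTrials), function(tr) {
      held <- sample(members, nHold)
      builders <- setdiff(members, held)
      agg <- aggregateMinenv(minenvs[builders])
      inside <- vapply(held, function(o) {
        growsOnSubset(models[[o]], agg, cutoff, uptakeMagnitude)
      }, logical(1))
      outs <- if (length(outsiders)) {
        sample(outsiders, min(length(held), length(outsiders)))
      } else character()
      outside <- vapply(outs, function(o) {
        growsOnSubset(models[[o]], agg, cutoff, uptakeMagnitude)
      }, logical(1))
      data.frame(trial = tr, inside = mean(inside),
                 outside = if (length(outside)) mean(outside) else NA_real_,
                 aggregate_size = length(agg))
    }))
  })
  list(inside_growth_fraction = mean(per$inside),
       outside_growth_fraction = mean(per$outside, na.rm = TRUE),
       per_trial = per)
}

## growth of a model on an aggregate medium given as a metabolite id set;
## ids absent from the model's exchanges simply cannot be taken up
growsOnSubset <- function(model, mediumSet, cutoff, uptakeMagnitude) {
  open <- intersect(mediumSet, exchangeMetabolites(model))
  grows(model, medium(open, uptakeMagnitude), cutoff)
}

#' Model-free containment test on curated media
#'
#' Same resampling scheme as [growthOnAggregate()], but the aggregate is
#' the union of the builders' known media and "growth" of a tested organism
#' means its own medium is fully contained in the aggregate.
#'
#' @param media named list: organism -> metabolite set (e.g. curated
#'   defined-media compositions).
#' @param profile an [EcologicalProfile-class].
#' @param environment environment id.
#' @param nTrials number of trials (default 100).
#' @param seed integer seed.
#' @param holdoutFraction fraction of members held out (default 0.5).
#' @return list with \code{inside_fraction}, \code{outside_fraction} and
#'   \code{per_trial}.
#' @export
containmentTest <- function(media, profile, environment, nTrials = 100,
                            seed = 1, holdoutFraction = 0.5) {
  orgs <- sharedOrganisms(media, profile)
  p <- presence(profile)
  if (!environment %in% colnames(p)) {
    lookupError(sprintf("unknown environment '%s'", environment))
  }
  members <- intersect(orgs, rownames(p)[p[, environment] == 1])
  outsiders <- setdiff(orgs, rownames(p)[p[, environment] == 1])
  if (length(members) < 2) {
    preconditionError(sprintf(
      "environment '%s' has %d members with media; need >= 2",
      environment, length(members)))
  }
  nHold <- max(1L, round(holdoutFraction * length(members)))
  nHold <- min(nHold, length(members) - 1L)
  per <- withSeed(seed, {
    do.call(rbind, lapply(seq_len(nTrials), function(tr) {
      held <- sample(members, nHold)
      builders <- setdiff(members, held)
      agg <- aggregateMinenv(media[builders])
      contained <- function(o) all(media[[o]] %in% agg)
      inside <- vapply(held, contained, logical(1))
      outs <- if (length(outsiders)) {
        sample(outsiders, min(length(held), length(outsiders)))
      } else character()
      outside <- vapply(outs, contained, logical(1))
      data.frame(trial = tr, inside = mean(inside),
                 outside = if (length(outside)) mean(outside) else NA_real_)
    }))
  })
  list(inside_fraction = mean(per$inside),
       outside_fraction = mean(per$outside, na.rm = TRUE),
       per_trial = per)
}

#' Correlate fastidiousness with an organism covariate
#'
#' Spearman rank correlation (average ranks for ties) between minimal-
#' environment sizes and any per-organism covariate (lifestyle class rank,
#' environment count, genome size, growth rate, cooperation score, ...)
#' over the organisms present in both maps.
#'
#' @param minenvSizes named numeric vector: organism -> size.
#' @param covariate named numeric vector: organism -> value.
#' @param method correlation method; only \code{"spearman"}.
#' @return list with \code{rho}, \code{p}, \code{n}.
#' @export
fastidiousnessCorrelates <- function(minenvSizes, covariate,
                                     method = c("spearman")) {
  method <- match.arg(method)
  orgs <- intersect(names(minenvSizes), names(covariate))
  if (length(orgs) < 3) {
    preconditionError(sprintf(
      "only %d organisms shared between sizes and covariate; need >= 3",
      length(orgs)))
  }
  ct <- suppressWarnings(stats::cor.test(
    as.numeric(minenvSizes[orgs]), as.numeric(covariate[orgs]),
    method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(orgs))
}

#' Mean pairwise score of an organism
#'
#' Averages a pairwise score (e.g. cooperation or competition) over every
#' pair containing the organism.
#'
#' @param org organism id.
#' @param pairScores data.frame with columns \code{orgA}, \code{orgB},
#'   \code{score}.
#' @return numeric mean.
#' @export
meanPairScore <- function(org, pairScores) {
  stopifnot(all(c("orgA", "orgB", "score") %in% names(pairScores)))
  hit <- pairScores$orgA == org | pairScores$orgB == org
  if (!any(hit)) {
    lookupError(sprintf("organism '%s' appears in no pair", org))
  }
  mean(pairScores$score[hit])
}

#' Read a two-column covariate table
#'
#' @param path TSV with header: organism, value.
#' @return named numeric vector.
#' @export
readCovariates <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) parseError("covariate table needs 2 columns")
  stats::setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
}

#' Read a three-column pair-score table
#'
#' @param path TSV with header: orgA, orgB, score.
#' @return data.frame with columns orgA, orgB, score.
#' @export
readPairScores <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 3) parseError("pair-score table needs 3 columns")
  names(tab)[1:3] <- c("orgA", "orgB", "score")
  tab
}
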