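## Flux balance analysis core: apply a medium, maximize biomass, test growth.

#' Construct a Medium
#'
#' @param allowedUptake character vector of exchange-metabolite ids open for
#'   uptake (may be empty).
#' @param uptakeMagnitude positive uptake-bound magnitude in flux units.
#'   The default of 1000 is the conventional unconstrained flux bound; it is
#'   also the big-M constant coupling the consumption indicators in the
#'   minimal-environment MILP, so the two must match for the MILP's witness
#'   media to verify by plain FBA.
#' @return a [Medium-class].
#' @export
medium <- function(allowedUptake = character(), uptakeMagnitude = 1000) {
  methods::new("Medium", allowedUptake = unique(as.character(allowedUptake)),
               uptakeMagnitude = uptakeMagnitude)
}

#' The all-exchanges-open rich medium of a model
#'
#' @param model a [MetabolicModel-class].
#' @param uptakeMagnitude uptake bound magnitude.
#' @return a [Medium-class] allowing uptake of every exchangeable metabolite.
#' @export
richMedium <- function(model, uptakeMagnitude = 1000) {
  medium(exchangeMetabolites(model), uptakeMagnitude)
}

## Reaction bounds after applying a medium. Uptake is the flux direction
## that supplies the metabolite to the network: for the conventional
## exchange orientation (coefficient -1) uptake is negative flux, so allowed
## metabolites get lower bound -magnitude and all others 0, while secretion
## (the opposite direction) stays open for every exchange. Reversed-
## orientation exchanges (+1) are handled symmetrically.
mediumBounds <- function(model, med) {
  rxn <- model@reactions
  lb <- rxn$lower_bound
  ub <- rxn$upper_bound
  ex <- exchangeMap(model)
  unknown <- setdiff(med@allowedUptake, ex$metabolite)
  if (length(unknown)) {
    preconditionError(paste(
      "medium metabolites without exchange reaction in model:",
      paste(unknown, collapse = ", ")))
  }
  open <- ex$metabolite %in% med@allowedUptake
  conv <- ex$coefficient < 0
  j <- ex$column
  # the medium can only restrict uptake further than the model's own bound
  lb[j[conv]] <- ifelse(open[conv],
                        pmax(lb[j[conv]], -med@uptakeMagnitude),
                        pmax(lb[j[conv]], 0))
  ub[j[!conv]] <- ifelse(open[!conv],
                         pmin(ub[j[!conv]], med@uptakeMagnitude),
                         pmin(ub[j[!conv]], 0))
  list(lb = lb, ub = ub)
}

#' Maximize biomass production on a medium
#'
#' Solves the flux balance analysis linear program: maximize the biomass
#' flux subject to the steady-state constraint \eqn{S V = 0} and the flux
#' bounds obtained by applying the medium.
#'
#' @param model a [MetabolicModel-class].
#' @param med a [Medium-class]; defaults to the all-open rich medium.
#' @return a [FluxSolution-class].
#' @export
maximizeBiomass <- function(model, med = richMedium(model)) {
  stopifnot(is(model, "MetabolicModel"), is(med, "Medium"))
  bnd <- mediumBounds(model, med)
  rxn <- model@reactions
  obj <- as.numeric(rxn$id == model@biomassReaction)
  bad <- !is.finite(bnd$lb)
  if (any(bad)) bnd$lb[bad] <- -1e7 # free reverse direction, kept finite
  res <- solveLP(obj, model@stoichiometry, rep(0, nrow(model@metabolites)),
                 bnd$lb, bnd$ub, maximize = TRUE)
  methods::new("FluxSolution", status = res$status,
               objective = if (is.na(res$objective)) 0 else res$objective,
               fluxes = if (!is.null(res$x)) {
                 stats::setNames(res$x, rxn$id)
               } else stats::setNames(numeric(0), character(0)))
}

#' Does the model grow on a medium?
#'
#' Growth means the maximal biomass flux reaches the cutoff. The default
#' cutoff of 0.1 absolute flux units is the nominal "nonzero biomass"
#' threshold used throughout the package; alternatively the cutoff may be
#' interpreted as a fraction of the maximal biomass attainable on the
#' all-exchanges-open rich medium. Comparisons use a 1e-6 slack so LP
#' round-off at the boundary never flips the verdict; the boundary itself
#' (objective equal to cutoff) counts as growth.
#'
#' @param model a [MetabolicModel-class].
#' @param med a [Medium-class].
#' @param cutoff nonnegative biomass threshold (flux units, or a fraction
#'   when \code{cutoffType = "fraction"}).
#' @param cutoffType \code{"absolute"} or \code{"fraction"} of the rich-
#'   medium optimum.
#' @return logical.
#' @export
grows <- function(model, med, cutoff = 0.1,
                  cutoffType = c("absolute", "fraction")) {
  cutoffType <- match.arg(cutoffType)
  stopifnot(cutoff >= 0)
  if (cutoffType == "fraction") {
    full <- maximizeBiomass(model, richMedium(model, med@uptakeMagnitude))
    if (full@status == "unbounded") {
      solverError("rich-medium FBA is unbounded; fractional cutoff undefined")
    }
    cutoff <- cutoff * full@objective
  }
  sol <- maximizeBiomass(model, med)
  if (sol@status == "unbounded") return(TRUE)
  if (sol@status != "optimal") {
    solverError(paste("FBA solve returned status", sol@status))
  }
  sol@objective >= cutoff - 1e-6
}
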