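## S4 classes for the central data objects.

setClassUnion("characterOrNULL", c("character", "NULL"))

#' MetabolicModel: a stoichiometric network with bounds and a biomass reaction
#'
#' Container for a genome-scale metabolic model: a metabolite table, a
#' reaction table, the sparse stoichiometric matrix \eqn{S} (one row per
#' metabolite, one column per reaction), a designated biomass reaction,
#' gene identifiers, and free-form metadata.
#'
#' Metabolite table columns: \code{id}, \code{name}, \code{formula},
#' \code{molar_mass}, \code{compartment}. Reaction table columns: \code{id},
#' \code{name}, \code{lower_bound}, \code{upper_bound}, \code{gpr},
#' \code{is_exchange}. An exchange reaction moves exactly one metabolite
#' across the system boundary; by the dominant convention its stoichiometric
#' coefficient is \eqn{-1} so that negative flux is uptake and positive flux
#' is secretion.
#'
#' @slot id single organism/model identifier.
#' @slot metabolites data.frame of metabolite annotations.
#' @slot reactions data.frame of reaction annotations and flux bounds.
#' @slot stoichiometry sparse \code{dgCMatrix}, metabolites x reactions.
#' @slot biomassReaction id of the biomass reaction.
#' @slot genes character vector of gene identifiers.
#' @slot metadata free-form list (e.g. generator ground truth).
#'
#' @seealso [readMetabolicModel()], [generateToyModel()]
#' @exportClass MetabolicModel
setClass("MetabolicModel",
  representation(
    id = "character",
    metabolites = "data.frame",
    reactions = "data.frame",
    stoichiometry = "Matrix",
    biomassReaction = "character",
    genes = "character",
    metadata = "list"
  ),
  prototype(id = "model", genes = character(), metadata = list())
)

setValidity("MetabolicModel", function(object) {
  msgs <- character()
  met <- object@metabolites
  rxn <- object@reactions
  S <- object@stoichiometry
  need_met <- c("id", "formula", "molar_mass", "compartment")
  need_rxn <- c("id", "lower_bound", "upper_bound", "gpr", "is_exchange")
  if (!all(need_met %in% names(met))) {
    return(paste("metabolite table must have columns:",
                 paste(need_met, collapse = ", ")))
  }
  if (!all(need_rxn %in% names(rxn))) {
    return(paste("reaction table must have columns:",
                 paste(need_rxn, collapse = ", ")))
  }
  if (anyDuplicated(met$id)) msgs <- c(msgs, "duplicated metabolite ids")
  if (anyDuplicated(rxn$id)) msgs <- c(msgs, "duplicated reaction ids")
  if (nrow(S) != nrow(met) || ncol(S) != nrow(rxn)) {
    msgs <- c(msgs, "stoichiometry dimensions do not match tables")
  }
  if (length(object@biomassReaction) != 1L ||
      !(object@biomassReaction %in% rxn$id)) {
    msgs <- c(msgs, "biomass reaction not found among reactions")
  }
  bad <- which(rxn$lower_bound > rxn$upper_bound)
  if (length(bad)) {
    msgs <- c(msgs, paste("lower_bound > upper_bound for:",
                          paste(rxn$id[bad], collapse = ", ")))
  }
  if (nrow(S) == nrow(met) && ncol(S) == nrow(rxn)) {
    nz <- diff(methods::as(S, "CsparseMatrix")@p)
    bad <- which(rxn$is_exchange & nz != 1L)
    if (length(bad)) {
      msgs <- c(msgs, paste("exchange reaction touching != 1 metabolite:",
                            paste(rxn$id[bad], collapse = ", ")))
    }
    # step-2 objective needs a molar weight for every exchangeable metabolite
    exm <- exchangeMetaboliteRows(object)
    if (length(exm)) {
      noinfo <- is.na(met$molar_mass[exm]) &
        (is.na(met$formula[exm]) | !nzchar(met$formula[exm]))
      if (any(noinfo)) {
        msgs <- c(msgs, paste(
          "exchange metabolite without formula or molar_mass:",
          paste(met$id[exm][noinfo], collapse = ", ")))
      }
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Medium: a set of exchange metabolites permitted for uptake
#'
#' Applying a medium to a model opens uptake (lower bound
#' \code{-uptakeMagnitude} for conventionally oriented exchanges) for the
#' listed exchange metabolites and closes uptake for every other exchange.
#' Secretion remains open for all exchanges: a medium restricts only what may
#' enter the cell.
#'
#' @slot allowedUptake character vector of exchange-metabolite ids.
#' @slot uptakeMagnitude positive uptake-bound magnitude (flux units).
#' @exportClass Medium
setClass("Medium",
  representation(allowedUptake = "character", uptakeMagnitude = "numeric"),
  prototype(allowedUptake = character(), uptakeMagnitude = 1000)
)

setValidity("Medium", function(object) {
  if (length(object@uptakeMagnitude) != 1L || !is.finite(object@uptakeMagnitude) ||
      object@uptakeMagnitude <= 0) {
    return("uptakeMagnitude must be a single positive finite number")
  }
  if (anyDuplicated(object@allowedUptake)) return("duplicated metabolite ids")
  TRUE
})

#' FluxSolution: result of a flux balance analysis solve
#'
#' @slot status one of \code{"optimal"}, \code{"infeasible"},
#'   \code{"unbounded"}, \code{"maxiter"}.
#' @slot objective optimal biomass flux (only meaningful when optimal).
#' @slot fluxes named numeric vector of reaction fluxes.
#' @exportClass FluxSolution
setClass("FluxSolution",
  representation(status = "character", objective = "numeric",
                 fluxes = "numeric"),
  prototype(status = "optimal", objective = 0, fluxes = numeric())
)

#' MinenvResult: a unique minimal environment and its diagnostics
#'
#' @slot organism model identifier the result belongs to.
#' @slot minimalSize minimal number of uptaken exchange metabolites
#'   (the fastidiousness measure).
#' @slot minenv ids of the metabolites in the unique minimal environment.
#' @slot molarRankSum sum of molar-weight ranks over the members.
#' @slot critical subset of \code{minenv} that is irreplaceable
#'   (filled by [criticalMetabolites()]; \code{NULL} until computed).
#' @slot cutoff biomass cutoff used.
#' @slot solverStatus solver status string.
#' @slot theta named binary vector over exchange metabolites; 0 = consumed
#'   (member of the minimal environment), 1 = not consumed.
#' @exportClass MinenvResult
setClass("MinenvResult",
  representation(
    organism = "character",
    minimalSize = "integer",
    minenv = "character",
    molarRankSum = "numeric",
    critical = "characterOrNULL",
    cutoff = "numeric",
    solverStatus = "character",
    theta = "numeric"
  ),
  prototype(organism = "model", minimalSize = 0L, minenv = character(),
            molarRankSum = 0, critical = NULL, cutoff = 0.1,
            solverStatus = "optimal", theta = numeric())
)

setValidity("MinenvResult", function(object) {
  msgs <- character()
  if (length(object@minenv) != object@minimalSize) {
    msgs <- c(msgs, "|minenv| != minimalSize")
  }
  if (!is.null(object@critical) && !all(object@critical %in% object@minenv)) {
    msgs <- c(msgs, "critical set not contained in minenv")
  }
  if (length(object@theta)) {
    if (is.null(names(object@theta))) {
      msgs <- c(msgs, "theta must be named by exchange metabolite id")
    } else {
      members <- names(object@theta)[object@theta == 0]
      if (!setequal(members, object@minenv)) {
        msgs <- c(msgs, "theta == 0 entries must equal the minenv set")
      }
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' EcologicalProfile: binary organism-by-environment presence matrix
#'
#' @slot presence binary matrix, organisms in rows, environments in columns,
#'   with dimnames.
#' @exportClass EcologicalProfile
setClass("EcologicalProfile",
  representation(presence = "matrix"))

setValidity("EcologicalProfile", function(object) {
  p <- object@presence
  if (is.null(rownames(p)) || is.null(colnames(p))) {
    return("presence matrix must have organism rownames and environment colnames")
  }
  if (anyDuplicated(rownames(p)) || anyDuplicated(colnames(p))) {
    return("duplicated organism or environment ids")
  }
  if (!all(p %in% c(0, 1))) return("presence matrix must be binary 0/1")
  if (any(rowSums(p) < 1)) {
    return(paste("organisms present in no environment:",
                 paste(rownames(p)[rowSums(p) < 1], collapse = ", ")))
  }
  TRUE
})

#' SimilarityCurve: binned nutritional-vs-ecological similarity summary
#'
#' @slot binEdges ecological-distance bin boundaries (length nBins + 1).
#' @slot thresholds MINENV similarity percentage thresholds.
#' @slot ratio matrix bin x threshold: fraction of pairs in the bin whose
#'   MINENV similarity exceeds the threshold (NA for empty bins).
#' @slot pairCounts number of organism pairs per bin.
#' @slot flagged bins with fewer than the minimum pair count.
#' @slot spearman data.frame with one row per threshold: \code{rho}, \code{p},
#'   \code{nBins} (flagged bins excluded; NA when fewer than 3 usable bins).
#' @slot pairSpearman data.frame with one row per threshold: Spearman rho
#'   and p of ecological similarity against the thresholded nutritional
#'   similarity indicator across all organism pairs (the pair-level
#'   statistic; positive when co-distributed organisms share nutrition).
#' @exportClass SimilarityCurve
setClass("SimilarityCurve",
  representation(binEdges = "numeric", thresholds = "numeric",
                 ratio = "matrix", pairCounts = "integer",
                 flagged = "logical", spearman = "data.frame",
                 pairSpearman = "data.frame"))

#' RunConfig: options shared by the command-layer workflows
#'
#' @slot cutoff biomass cutoff in flux units (default 0.1).
#' @slot uptakeMagnitude uptake-bound magnitude, also the big-M coupling
#'   constant of the MILP (default 1000).
#' @slot solver backend name (only \code{"simplex"}, the built-in solver).
#' @slot timeLimit per-solve MILP wall-clock limit in seconds.
#' @slot seed integer seed for every stochastic resampling step.
#' @slot exemptMetabolites exchange metabolites exempted from the count
#'   (uptake always free, never reported as members).
#' @slot verbose emit one structured log line per MILP solve.
#' @exportClass RunConfig
setClass("RunConfig",
  representation(cutoff = "numeric", uptakeMagnitude = "numeric",
                 solver = "character", timeLimit = "numeric",
                 seed = "integer", exemptMetabolites = "character",
                 verbose = "logical"),
  prototype(cutoff = 0.1, uptakeMagnitude = 1000, solver = "simplex",
            timeLimit = 300, seed = 1L, exemptMetabolites = character(),
            verbose = FALSE))

setValidity("RunConfig", function(object) {
  if (object@cutoff < 0) return("cutoff must be >= 0")
  if (object@timeLimit <= 0) return("timeLimit must be > 0")
  if (object@uptakeMagnitude <= 0) return("uptakeMagnitude must be > 0")
  if (!identical(object@solver, "simplex")) {
    return(paste("unknown solver:", object@solver))
  }
  TRUE
})
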