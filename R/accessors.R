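## Accessors and show methods.

#' @describeIn MetabolicModel-class metabolite annotation table
#' @param x object
#' @export
setMethod("metabolites", "MetabolicModel", function(x) x@metabolites)

#' @describeIn MetabolicModel-class reaction annotation table
#' @export
setMethod("reactions", "MetabolicModel", function(x) x@reactions)

#' @describeIn MetabolicModel-class sparse stoichiometric matrix
#' @export
setMethod("stoichiometry", "MetabolicModel", function(x) x@stoichiometry)

#' @describeIn MetabolicModel-class id of the biomass reaction
#' @export
setMethod("biomassReaction", "MetabolicModel", function(x) x@biomassReaction)

#' @describeIn MetabolicModel-class gene identifiers
#' @export
setMethod("genes", "MetabolicModel", function(x) x@genes)

#' @describeIn MetabolicModel-class model identifier
#' @export
setMethod("modelId", "MetabolicModel", function(x) x@id)

#' @describeIn MetabolicModel-class ids of exchange reactions
#' @export
setMethod("exchangeReactions", "MetabolicModel",
          function(x) x@reactions$id[x@reactions$is_exchange])

#' @describeIn MetabolicModel-class ids of exchangeable metabolites, in the
#'   order of their exchange reactions
#' @export
setMethod("exchangeMetabolites", "MetabolicModel",
          function(x) x@metabolites$id[exchangeMetaboliteRows(x)])

setMethod("show", "MetabolicModel", function(object) {
  cat("MetabolicModel '", object@id, "': ",
      nrow(object@metabolites), " metabolites, ",
      nrow(object@reactions), " reactions (",
      sum(object@reactions$is_exchange), " exchanges), ",
      length(object@genes), " genes\n", sep = "")
  cat("  biomass reaction:", object@biomassReaction, "\n")
})

#' @describeIn Medium-class metabolites open for uptake
#' @param x object
#' @export
setMethod("allowedUptake", "Medium", function(x) x@allowedUptake)

#' @describeIn Medium-class uptake bound magnitude
#' @export
setMethod("uptakeMagnitude", "Medium", function(x) x@uptakeMagnitude)

setMethod("show", "Medium", function(object) {
  cat("Medium:", length(object@allowedUptake),
      "metabolites open for uptake (magnitude",
      object@uptakeMagnitude, ")\n")
  if (length(object@allowedUptake)) {
    cat(" ", paste(utils::head(object@allowedUptake, 10), collapse = ", "))
    if (length(object@allowedUptake) > 10) cat(", ...")
    cat("\n")
  }
})

#' @describeIn FluxSolution-class reaction flux vector
#' @param x object
#' @export
setMethod("fluxes", "FluxSolution", function(x) x@fluxes)

#' @describeIn FluxSolution-class solver status string
#' @export
setMethod("solverStatus", "FluxSolution", function(x) x@status)

setMethod("show", "FluxSolution", function(object) {
  cat("FluxSolution: status", object@status,
      "objective", format(object@objective), "\n")
})

#' @describeIn MinenvResult-class minimal environment size (fastidiousness)
#' @param x object
#' @export
setMethod("minimalSize", "MinenvResult", function(x) x@minimalSize)

#' @describeIn MinenvResult-class member metabolite ids
#' @export
setMethod("minenv", "MinenvResult", function(x) x@minenv)

#' @describeIn MinenvResult-class critical subset (NULL until computed)
#' @export
setMethod("criticalSet", "MinenvResult", function(x) x@critical)

#' @describeIn MinenvResult-class binary consumption indicators
#'   (0 = consumed)
#' @export
setMethod("thetaValues", "MinenvResult", function(x) x@theta)

#' @describeIn MinenvResult-class solver status string
#' @export
setMethod("solverStatus", "MinenvResult", function(x) x@solverStatus)

#' @describeIn MinenvResult-class id of the organism the result belongs to
#' @export
setMethod("modelId", "MinenvResult", function(x) x@organism)

setMethod("show", "MinenvResult", function(object) {
  cat("MinenvResult for '", object@organism, "': ", object@minimalSize,
      " metabolites (cutoff ", object@cutoff, ", status ",
      object@solverStatus, ")\n", sep = "")
  if (length(object@minenv)) {
    cat("  minenv:", paste(object@minenv, collapse = ", "), "\n")
  }
  if (!is.null(object@critical)) {
    cat("  critical:", if (length(object@critical))
      paste(object@critical, collapse = ", ") else "(none)", "\n")
  }
})

#' @describeIn EcologicalProfile-class organism ids
#' @param x object
#' @export
setMethod("organisms", "EcologicalProfile",
          function(x) rownames(x@presence))

#' @describeIn EcologicalProfile-class environment ids
#' @export
setMethod("environments", "EcologicalProfile",
          function(x) colnames(x@presence))

#' @describeIn EcologicalProfile-class the binary presence matrix
#' @export
setMethod("presence", "EcologicalProfile", function(x) x@presence)

setMethod("show", "EcologicalProfile", function(object) {
  cat("EcologicalProfile:", nrow(object@presence), "organisms x",
      ncol(object@presence), "environments;",
      sum(object@presence), "presences\n")
})

setMethod("show", "SimilarityCurve", function(object) {
  cat("SimilarityCurve:", length(object@pairCounts), "bins,",
      sum(object@pairCounts), "pairs; thresholds:",
      paste(object@thresholds, collapse = ", "), "\n")
  cat("  bin-level correlation:\n")
  print(object@spearman)
  cat("  pair-level correlation:\n")
  print(object@pairSpearman)
})

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig: cutoff=", object@cutoff,
      " uptakeMagnitude=", object@uptakeMagnitude,
      " solver=", object@solver,
      " timeLimit=", object@timeLimit,
      " seed=", object@seed, "\n", sep = "")
})
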