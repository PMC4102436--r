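## Generics for accessors and core operations.

#' @export
setGeneric("metabolites", function(x) standardGeneric("metabolites"))
#' @export
setGeneric("reactions", function(x) standardGeneric("reactions"))
#' @export
setGeneric("stoichiometry", function(x) standardGeneric("stoichiometry"))
#' @export
setGeneric("biomassReaction", function(x) standardGeneric("biomassReaction"))
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))
#' @export
setGeneric("modelId", function(x) standardGeneric("modelId"))
#' @export
setGeneric("exchangeReactions", function(x) standardGeneric("exchangeReactions"))
#' @export
setGeneric("exchangeMetabolites", function(x) standardGeneric("exchangeMetabolites"))
#' @export
setGeneric("allowedUptake", function(x) standardGeneric("allowedUptake"))
#' @export
setGeneric("uptakeMagnitude", function(x) standardGeneric("uptakeMagnitude"))
#' @export
setGeneric("minimalSize", function(x) standardGeneric("minimalSize"))
#' @export
setGeneric("minenv", function(x) standardGeneric("minenv"))
#' @export
setGeneric("criticalSet", function(x) standardGeneric("criticalSet"))
#' @export
setGeneric("thetaValues", function(x) standardGeneric("thetaValues"))
#' @export
setGeneric("fluxes", function(x) standardGeneric("fluxes"))
#' @export
setGeneric("solverStatus", function(x) standardGeneric("solverStatus"))
#' @export
setGeneric("organisms", function(x) standardGeneric("organisms"))
#' @export
setGeneric("environments", function(x) standardGeneric("environments"))
#' @export
setGeneric("presence", function(x) standardGeneric("presence"))
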