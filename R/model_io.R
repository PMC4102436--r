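## Model construction and I/O: COBRA-style JSON and SBML Level 3 (FBC).

#' Construct a MetabolicModel from tables
#'
#' Low-level constructor used by the readers and the synthetic generator.
#' Exchange reactions are auto-detected as reactions touching exactly one
#' metabolite, or by an \code{EX_} id prefix; an explicit
#' \code{is_exchange} column in \code{reactions} overrides detection.
#'
#' @param id model identifier.
#' @param metabolites data.frame with columns \code{id} and optionally
#'   \code{name}, \code{formula}, \code{molar_mass}, \code{compartment}.
#' @param reactions data.frame with columns \code{id}, \code{lower_bound},
#'   \code{upper_bound} and optionally \code{name}, \code{gpr},
#'   \code{is_exchange}.
#' @param stoich named list (one element per reaction, in reaction order) of
#'   named numeric vectors: metabolite id -> signed coefficient.
#' @param biomass id of the biomass reaction.
#' @param genes character vector of gene ids; defaults to the genes
#'   appearing in GPR rules.
#' @param metadata free-form list.
#' @return a validated [MetabolicModel-class].
#' @export
metabolicModel <- function(id, metabolites, reactions, stoich, biomass,
                           genes = NULL, metadata = list()) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$formula)) metabolites$formula <- NA_character_
  if (is.null(metabolites$molar_mass)) metabolites$molar_mass <- NA_real_
  if (is.null(metabolites$compartment)) metabolites$compartment <- "c"
  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(reactions$gpr)) reactions$gpr <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  if (length(stoich) != nrow(reactions)) {
    modelError("stoich must have one entry per reaction")
  }
  i <- integer(); j <- integer(); v <- numeric()
  for (k in seq_along(stoich)) {
    s <- stoich[[k]]
    s <- s[s != 0]
    if (!length(s)) next
    idx <- match(names(s), metabolites$id)
    if (anyNA(idx)) {
      modelError(sprintf("reaction '%s' references unknown metabolite(s): %s",
                         reactions$id[k],
                         paste(names(s)[is.na(idx)], collapse = ", ")))
    }
    i <- c(i, idx); j <- c(j, rep(k, length(s))); v <- c(v, unname(s))
  }
  S <- Matrix::sparseMatrix(i = i, j = j, x = v,
                            dims = c(nrow(metabolites), nrow(reactions)),
                            dimnames = list(metabolites$id, reactions$id))
  if (is.null(reactions$is_exchange)) {
    nz <- diff(methods::as(S, "CsparseMatrix")@p)
    reactions$is_exchange <- (nz == 1L | startsWith(reactions$id, "EX_")) &
      reactions$id != biomass # the designated biomass is never an exchange
  }
  if (is.null(genes)) {
    genes <- unique(unlist(lapply(reactions$gpr[nzchar(reactions$gpr)],
                                  function(r) gprGenes(gprParse(r)))))
    if (is.null(genes)) genes <- character()
  }
  methods::new("MetabolicModel", id = id, metabolites = metabolites,
               reactions = reactions, stoichiometry = S,
               biomassReaction = biomass, genes = as.character(genes),
               metadata = metadata)
}

#' Read a metabolic model
#'
#' Reads a genome-scale metabolic model from a COBRA-community-style JSON
#' file or an SBML Level 3 file with the FBC package (flux bounds,
#' objective, gene associations). The biomass reaction is taken from the
#' objective (JSON: nonzero \code{objective_coefficient}; SBML: the active
#' FBC objective).
#'
#' @param path file path.
#' @param dialect \code{"auto"} (by file extension), \code{"json"}, or
#'   \code{"sbml"}.
#' @return a validated [MetabolicModel-class].
#' @export
readMetabolicModel <- function(path, dialect = c("auto", "json", "sbml")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) parseError(sprintf("file not found: %s", path))
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  }
  model <- if (dialect == "json") readModelJSON(path) else readModelSBML(path)
  v <- methods::validObject(model, test = TRUE)
  if (!isTRUE(v)) modelError(paste0("invalid model in '", path, "': ", v))
  model
}

#' Write a metabolic model
#'
#' Writes the model in the JSON dialect or as SBML Level 3 + FBC.
#' Writing then re-reading preserves stoichiometry, bounds, GPR strings,
#' formulas/masses and exchange flags.
#'
#' @param model a [MetabolicModel-class].
#' @param path output file path.
#' @param dialect \code{"auto"}, \code{"json"} or \code{"sbml"}.
#' @return \code{path}, invisibly.
#' @export
writeMetabolicModel <- function(model, path,
                                dialect = c("auto", "json", "sbml")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  }
  if (dialect == "json") writeModelJSON(model, path)
  else writeModelSBML(model, path)
  invisible(path)
}

## ---- JSON dialect ---------------------------------------------------------

readModelJSON <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) parseError(
                    sprintf("cannot parse JSON model '%s': %s",
                            path, conditionMessage(e))))
  for (fld in c("metabolites", "reactions")) {
    if (is.null(doc[[fld]])) {
      parseError(sprintf("JSON model '%s' lacks required field '%s'",
                         path, fld))
    }
  }
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    if (is.null(m$id)) parseError("metabolite without id in JSON model")
    data.frame(id = m$id, name = m$name %||% m$id,
               formula = as.character(m$formula %||% NA_character_),
               molar_mass = as.numeric(m$molar_mass %||% NA_real_),
               compartment = m$compartment %||% "c",
               stringsAsFactors = FALSE)
  }))
  rxns <- do.call(rbind, lapply(doc$reactions, function(r) {
    if (is.null(r$id)) parseError("reaction without id in JSON model")
    data.frame(id = r$id, name = r$name %||% r$id,
               lower_bound = as.numeric(r$lower_bound %||% -1000),
               upper_bound = as.numeric(r$upper_bound %||% 1000),
               gpr = as.character(r$gene_reaction_rule %||% ""),
               stringsAsFactors = FALSE)
  }))
  stoich <- lapply(doc$reactions, function(r) {
    s <- unlist(r$metabolites)
    if (is.null(s)) stats::setNames(numeric(), character()) else s
  })
  objc <- vapply(doc$reactions,
                 function(r) as.numeric(r$objective_coefficient %||% 0),
                 numeric(1))
  biomass <- rxns$id[objc != 0]
  if (length(biomass) != 1L) {
    biomass <- grep("biomass", rxns$id, ignore.case = TRUE, value = TRUE)
    if (length(biomass) != 1L) {
      modelError(sprintf(
        "model '%s': no unique biomass reaction (objective_coefficient)", path))
    }
  }
  genes <- vapply(doc$genes %||% list(), function(g) as.character(g$id),
                  character(1))
  metabolicModel(id = doc$id %||% tools::file_path_sans_ext(basename(path)),
                 metabolites = mets, reactions = rxns, stoich = stoich,
                 biomass = biomass, genes = if (length(genes)) genes else NULL)
}

writeModelJSON <- function(model, path) {
  S <- model@stoichiometry
  met <- model@metabolites
  rxn <- model@reactions
  mets <- lapply(seq_len(nrow(met)), function(i) {
    out <- list(id = met$id[i], name = met$name[i],
                compartment = met$compartment[i])
    if (!is.na(met$formula[i])) out$formula <- met$formula[i]
    if (!is.na(met$molar_mass[i])) out$molar_mass <- met$molar_mass[i]
    out
  })
  rxns <- lapply(seq_len(nrow(rxn)), function(j) {
    s <- S[, j]
    s <- s[s != 0]
    list(id = rxn$id[j], name = rxn$name[j],
         metabolites = as.list(s),
         lower_bound = rxn$lower_bound[j],
         upper_bound = rxn$upper_bound[j],
         gene_reaction_rule = rxn$gpr[j],
         objective_coefficient =
           if (rxn$id[j] == model@biomassReaction) 1 else 0)
  })
  doc <- list(id = model@id, metabolites = mets, reactions = rxns,
              genes = lapply(model@genes, function(g) list(id = g)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

## ---- SBML Level 3 + FBC ---------------------------------------------------

SBML_NS <- c(
  sbml = "http://www.sbml.org/sbml/level3/version1/core",
  fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2",
  mv = "https://minenv.invalid/sbml-annotations"
)

readModelSBML <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) parseError(
                    sprintf("cannot parse SBML file '%s': %s",
                            path, conditionMessage(e))))
  ns <- SBML_NS
  mnode <- xml2::xml_find_first(doc, ".//sbml:model", ns)
  if (inherits(mnode, "xml_missing")) {
    parseError(sprintf("no <model> element in '%s'", path))
  }
  sp <- xml2::xml_find_all(mnode, ".//sbml:listOfSpecies/sbml:species", ns)
  if (!length(sp)) parseError(sprintf("no species in SBML model '%s'", path))
  mets <- do.call(rbind, lapply(sp, function(s) {
    mm <- xml2::xml_attr(s, "molarMass")
    data.frame(
      id = stripPrefix(xml2::xml_attr(s, "id"), "M_"),
      name = xml2::xml_attr(s, "name") %na% stripPrefix(
        xml2::xml_attr(s, "id"), "M_"),
      formula = xml2::xml_attr(s, "chemicalFormula"),
      molar_mass = if (is.na(mm)) NA_real_ else as.numeric(mm),
      compartment = xml2::xml_attr(s, "compartment") %na% "c",
      stringsAsFactors = FALSE)
  }))
  params <- xml2::xml_find_all(mnode, ".//sbml:listOfParameters/sbml:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  rn <- xml2::xml_find_all(mnode, ".//sbml:listOfReactions/sbml:reaction", ns)
  if (!length(rn)) parseError(sprintf("no reactions in SBML model '%s'", path))
  rxns <- do.call(rbind, lapply(rn, function(r) {
    lbref <- xml2::xml_attr(r, "lowerFluxBound")
    ubref <- xml2::xml_attr(r, "upperFluxBound")
    data.frame(
      id = stripPrefix(xml2::xml_attr(r, "id"), "R_"),
      name = xml2::xml_attr(r, "name") %na% stripPrefix(
        xml2::xml_attr(r, "id"), "R_"),
      lower_bound = if (!is.na(lbref) && lbref %in% names(pval))
        pval[[lbref]] else -1000,
      upper_bound = if (!is.na(ubref) && ubref %in% names(pval))
        pval[[ubref]] else 1000,
      gpr = readGeneAssociation(r),
      stringsAsFactors = FALSE)
  }))
  stoich <- lapply(rn, function(r) {
    reac <- xml2::xml_find_all(r, "./sbml:listOfReactants/sbml:speciesReference", ns)
    prod <- xml2::xml_find_all(r, "./sbml:listOfProducts/sbml:speciesReference", ns)
    s <- c(
      stats::setNames(-as.numeric(xml2::xml_attr(reac, "stoichiometry") %na% "1"),
                      stripPrefix(xml2::xml_attr(reac, "species"), "M_")),
      stats::setNames(as.numeric(xml2::xml_attr(prod, "stoichiometry") %na% "1"),
                      stripPrefix(xml2::xml_attr(prod, "species"), "M_")))
    # a species on both sides contributes its net coefficient
    if (anyDuplicated(names(s))) s <- c(tapply(s, names(s), sum))
    s
  })
  fobj <- xml2::xml_find_all(
    mnode, ".//fbc:listOfObjectives//fbc:fluxObjective", ns)
  biomass <- stripPrefix(xml2::xml_attr(fobj, "reaction"), "R_")
  biomass <- biomass[!is.na(biomass)]
  if (length(biomass) != 1L) {
    modelError(sprintf("SBML model '%s' lacks a unique biomass objective", path))
  }
  gp <- xml2::xml_find_all(mnode, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  genes <- xml2::xml_attr(gp, "label") %na%
    stripPrefix(xml2::xml_attr(gp, "id"), "G_")
  metabolicModel(
    id = xml2::xml_attr(mnode, "id") %na% tools::file_path_sans_ext(basename(path)),
    metabolites = mets, reactions = rxns, stoich = stoich,
    biomass = biomass, genes = if (length(genes)) genes else NULL)
}

readGeneAssociation <- function(rnode) {
  ns <- SBML_NS
  ga <- xml2::xml_find_first(rnode, "./fbc:geneProductAssociation", ns)
  if (inherits(ga, "xml_missing")) return("")
  child <- xml2::xml_find_first(ga, "./*")
  assocToString(child)
}

assocToString <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    return(stripPrefix(xml2::xml_attr(node, "geneProduct"), "G_"))
  }
  kids <- xml2::xml_find_all(node, "./*")
  parts <- vapply(kids, assocToString, character(1))
  op <- if (nm == "and") " and " else " or "
  paste0("(", paste(parts, collapse = op), ")")
}

writeModelSBML <- function(model, path) {
  met <- model@metabolites
  rxn <- model@reactions
  S <- model@stoichiometry
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  L <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"", SBML_NS[["sbml"]], "\" ",
           "xmlns:fbc=\"", SBML_NS[["fbc"]], "\" ",
           "xmlns:mv=\"", SBML_NS[["mv"]], "\" ",
           "level=\"3\" version=\"1\" fbc:required=\"false\">"),
    sprintf("  <model id=\"%s\" fbc:strict=\"true\">", esc(model@id)),
    "    <listOfCompartments>")
  for (cmp in unique(met$compartment)) {
    L <- c(L, sprintf("      <compartment id=\"%s\" constant=\"true\"/>",
                      esc(cmp)))
  }
  L <- c(L, "    </listOfCompartments>", "    <listOfSpecies>")
  for (i in seq_len(nrow(met))) {
    extra <- ""
    if (!is.na(met$formula[i]) && nzchar(met$formula[i])) {
      extra <- paste0(extra, sprintf(" fbc:chemicalFormula=\"%s\"",
                                     esc(met$formula[i])))
    }
    if (!is.na(met$molar_mass[i])) {
      extra <- paste0(extra, sprintf(" mv:molarMass=\"%.10g\"",
                                     met$molar_mass[i]))
    }
    L <- c(L, sprintf(
      paste0("      <species id=\"M_%s\" name=\"%s\" compartment=\"%s\"",
             " hasOnlySubstanceUnits=\"false\" boundaryCondition=\"false\"",
             " constant=\"false\"%s/>"),
      esc(met$id[i]), esc(met$name[i]), esc(met$compartment[i]), extra))
  }
  L <- c(L, "    </listOfSpecies>", "    <listOfParameters>")
  for (j in seq_len(nrow(rxn))) {
    L <- c(L,
      sprintf("      <parameter id=\"bnd_lb_%d\" value=\"%.10g\" constant=\"true\"/>",
              j, rxn$lower_bound[j]),
      sprintf("      <parameter id=\"bnd_ub_%d\" value=\"%.10g\" constant=\"true\"/>",
              j, rxn$upper_bound[j]))
  }
  L <- c(L, "    </listOfParameters>", "    <listOfReactions>")
  for (j in seq_len(nrow(rxn))) {
    s <- S[, j]; s <- s[s != 0]
    L <- c(L, sprintf(
      paste0("      <reaction id=\"R_%s\" name=\"%s\" reversible=\"%s\"",
             " fast=\"false\" fbc:lowerFluxBound=\"bnd_lb_%d\"",
             " fbc:upperFluxBound=\"bnd_ub_%d\">"),
      esc(rxn$id[j]), esc(rxn$name[j]),
      if (rxn$lower_bound[j] < 0) "true" else "false", j, j))
    if (nzchar(rxn$gpr[j])) {
      L <- c(L, "        <fbc:geneProductAssociation>",
             paste0("          ", assocToXML(gprParse(rxn$gpr[j]))),
             "        </fbc:geneProductAssociation>")
    }
    reac <- s[s < 0]; prod <- s[s > 0]
    if (length(reac)) {
      L <- c(L, "        <listOfReactants>",
        sprintf(paste0("          <speciesReference species=\"M_%s\"",
                       " stoichiometry=\"%.10g\" constant=\"true\"/>"),
                esc(names(reac)), -unname(reac)),
        "        </listOfReactants>")
    }
    if (length(prod)) {
      L <- c(L, "        <listOfProducts>",
        sprintf(paste0("          <speciesReference species=\"M_%s\"",
                       " stoichiometry=\"%.10g\" constant=\"true\"/>"),
                esc(names(prod)), unname(prod)),
        "        </listOfProducts>")
    }
    L <- c(L, "      </reaction>")
  }
  L <- c(L, "    </listOfReactions>",
    "    <fbc:listOfObjectives fbc:activeObjective=\"obj\">",
    "      <fbc:objective fbc:id=\"obj\" fbc:type=\"maximize\">",
    "        <fbc:listOfFluxObjectives>",
    sprintf(paste0("          <fbc:fluxObjective fbc:reaction=\"R_%s\"",
                   " fbc:coefficient=\"1\"/>"), esc(model@biomassReaction)),
    "        </fbc:listOfFluxObjectives>",
    "      </fbc:objective>",
    "    </fbc:listOfObjectives>")
  if (length(model@genes)) {
    L <- c(L, "    <fbc:listOfGeneProducts>",
      sprintf("      <fbc:geneProduct fbc:id=\"G_%s\" fbc:label=\"%s\"/>",
              gsub("[^A-Za-z0-9_]", "_", model@genes), esc(model@genes)),
      "    </fbc:listOfGeneProducts>")
  }
  L <- c(L, "  </model>", "</sbml>")
  writeLines(L, path)
  invisible(path)
}

assocToXML <- function(ast) {
  if (is.character(ast)) {
    return(sprintf("<fbc:geneProductRef fbc:geneProduct=\"G_%s\"/>",
                   gsub("[^A-Za-z0-9_]", "_", ast)))
  }
  inner <- paste(vapply(ast$args, assocToXML, character(1)), collapse = "")
  sprintf("<fbc:%s>%s</fbc:%s>", ast$op, inner, ast$op)
}

stripPrefix <- function(x, prefix) {
  ifelse(startsWith(x, prefix), substring(x, nchar(prefix) + 1L), x)
}

## NA-coalescing helper for attribute vectors
`%na%` <- function(a, b) ifelse(is.na(a), b, a)
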