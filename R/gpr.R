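## Gene-protein-reaction (GPR) boolean rules.
##
## A GPR rule maps gene presence to reaction availability: AND joins the
## subunits of a complex (all genes required), OR joins isozymes (any gene
## suffices). Supported syntax: gene identifiers, `and`/`or` (case
## insensitive; `&`/`|` accepted), and parentheses.

gprTokenize <- function(rule) {
  rule <- gsub("&&?", " and ", rule)
  rule <- gsub("\\|\\|?", " or ", rule)
  rule <- gsub("([()])", " \\1 ", rule)
  toks <- strsplit(trimws(rule), "\\s+")[[1]]
  toks[nzchar(toks)]
}

## Parse into nested list ast: list(op="and"/"or", args=...) or gene id string.
gprParse <- function(rule) {
  toks <- gprTokenize(rule)
  if (!length(toks)) return(NULL)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  takeTok <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parseOr <- function() {
    left <- parseAnd()
    while (!is.na(peek()) && tolower(peek()) == "or") {
      takeTok()
      left <- list(op = "or", args = list(left, parseAnd()))
    }
    left
  }
  parseAnd <- function() {
    left <- parseAtom()
    while (!is.na(peek()) && tolower(peek()) == "and") {
      takeTok()
      left <- list(op = "and", args = list(left, parseAtom()))
    }
    left
  }
  parseAtom <- function() {
    t <- peek()
    if (is.na(t)) parseError(sprintf("truncated GPR rule '%s'", rule))
    if (t == "(") {
      takeTok()
      inner <- parseOr()
      if (is.na(peek()) || takeTok() != ")") {
        parseError(sprintf("unbalanced parentheses in GPR rule '%s'", rule))
      }
      return(inner)
    }
    if (t == ")" || tolower(t) %in% c("and", "or")) {
      parseError(sprintf("malformed GPR rule '%s'", rule))
    }
    takeTok()
  }
  ast <- parseOr()
  if (pos <= length(toks)) {
    parseError(sprintf("trailing tokens in GPR rule '%s'", rule))
  }
  ast
}

gprEval <- function(ast, present) {
  if (is.null(ast)) return(TRUE) # no gene association: reaction always on
  if (is.character(ast)) return(ast %in% present)
  vals <- vapply(ast$args, gprEval, logical(1), present = present)
  if (ast$op == "and") all(vals) else any(vals)
}

gprGenes <- function(ast) {
  if (is.null(ast)) return(character())
  if (is.character(ast)) return(ast)
  unique(unlist(lapply(ast$args, gprGenes)))
}

#' Delete a gene from a model through its GPR rules
#'
#' Returns a copy of the model in which every reaction whose GPR boolean
#' expression evaluates to FALSE with the gene absent (all other genes
#' present) has its flux bounds set to \code{[0, 0]}. Reactions without a
#' gene association are untouched.
#'
#' @param model a [MetabolicModel-class] with GPR rules.
#' @param gene gene identifier known to the model.
#' @return the modified [MetabolicModel-class].
#' @export
deleteGene <- function(model, gene) {
  stopifnot(is(model, "MetabolicModel"))
  if (!gene %in% model@genes) {
    lookupError(sprintf("gene '%s' not present in model '%s'", gene, model@id))
  }
  present <- setdiff(model@genes, gene)
  rxn <- model@reactions
  for (j in seq_len(nrow(rxn))) {
    rule <- rxn$gpr[j]
    if (is.na(rule) || !nzchar(rule)) next
    ast <- gprParse(rule)
    if (!gprEval(ast, present)) {
      rxn$lower_bound[j] <- 0
      rxn$upper_bound[j] <- 0
    }
  }
  model@reactions <- rxn
  model
}
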