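## Molar masses and the molar-weight ordering of exchangeable metabolites.
##
## The step-2 optimization disambiguates equally small media by preferring
## low molecular-weight nutrients, so every exchangeable metabolite needs a
## resolvable mass: an explicit molar_mass annotation wins, otherwise the
## mass is computed from the chemical formula with standard atomic weights.

# Conventional (abridged IUPAC 2021) atomic weights, g/mol.
ATOMIC_MASS <- c(
  H = 1.008, He = 4.003, Li = 6.94, Be = 9.012, B = 10.81, C = 12.011,
  N = 14.007, O = 15.999, F = 18.998, Ne = 20.180, Na = 22.990, Mg = 24.305,
  Al = 26.982, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Ar = 39.95,
  K = 39.098, Ca = 40.078, Cr = 51.996, Mn = 54.938, Fe = 55.845,
  Co = 58.933, Ni = 58.693, Cu = 63.546, Zn = 65.38, As = 74.922,
  Se = 78.971, Br = 79.904, Mo = 95.95, Ag = 107.868, Cd = 112.414,
  Sn = 118.710, I = 126.904, W = 183.84, Hg = 200.592, Pb = 207.2
)

#' Molar mass of a chemical formula
#'
#' Computes the molar mass of one or more chemical formula strings (e.g.
#' \code{"C6H12O6"}, \code{"(NH4)2SO4"}) from standard atomic weights.
#' Generic residue symbols (\code{R}, \code{X}, \code{*}) and unknown
#' elements are not assigned a mass: they raise a mass-unavailable error,
#' because silently guessing a weight would corrupt the molar ordering that
#' makes minimal environments unique.
#'
#' @param formula character vector of formula strings.
#' @return numeric vector of masses in g/mol.
#' @examples
#' compoundMass(c("H2O", "C6H12O6"))
#' @export
compoundMass <- function(formula) {
  vapply(formula, function(f) {
    if (is.na(f) || !nzchar(f)) {
      massError("empty formula: mass unavailable")
    }
    parseFormulaMass(f)
  }, numeric(1), USE.NAMES = FALSE)
}

# recursive-descent formula parser supporting parenthesised groups
parseFormulaMass <- function(f) {
  pos <- 1L
  n <- nchar(f)
  parseGroup <- function() {
    total <- 0
    while (pos <= n) {
      ch <- substr(f, pos, pos)
      if (ch == "(") {
        pos <<- pos + 1L
        inner <- parseGroup()
        if (pos > n || substr(f, pos, pos) != ")") {
          massError(sprintf("unbalanced parentheses in formula '%s'", f))
        }
        pos <<- pos + 1L
        total <- total + inner * parseCount()
      } else if (ch == ")") {
        return(total)
      } else if (grepl("[A-Z]", ch)) {
        sym <- ch
        pos <<- pos + 1L
        if (pos <= n && grepl("[a-z]", substr(f, pos, pos))) {
          sym <- paste0(sym, substr(f, pos, pos))
          pos <<- pos + 1L
        }
        if (!sym %in% names(ATOMIC_MASS)) {
          massError(sprintf(
            "formula '%s' contains '%s' with no defined atomic mass", f, sym))
        }
        total <- total + ATOMIC_MASS[[sym]] * parseCount()
      } else {
        massError(sprintf("cannot parse formula '%s' at position %d ('%s')",
                          f, pos, ch))
      }
    }
    total
  }
  parseCount <- function() {
    start <- pos
    while (pos <= n && grepl("[0-9]", substr(f, pos, pos))) pos <<- pos + 1L
    if (pos > start) as.numeric(substr(f, start, pos - 1L)) else 1
  }
  m <- parseGroup()
  if (pos <= n) massError(sprintf("trailing characters in formula '%s'", f))
  m
}

## Resolved masses for a set of metabolite rows: explicit annotation first,
## formula fallback; errors list every offender at once.
resolveMasses <- function(model, ids) {
  met <- model@metabolites
  idx <- match(ids, met$id)
  mass <- met$molar_mass[idx]
  need <- which(is.na(mass))
  bad <- character()
  for (k in need) {
    f <- met$formula[idx[k]]
    m <- tryCatch(compoundMass(f), minenvMassError = function(e) NA_real_)
    if (is.na(m)) bad <- c(bad, ids[k]) else mass[k] <- m
  }
  if (length(bad)) {
    massError(paste("molar mass unavailable for:", paste(bad, collapse = ", ")))
  }
  mass
}

#' Molar-weight ordering of the exchangeable metabolites
#'
#' Ranks every exchangeable metabolite of a model by ascending molar mass,
#' breaking mass ties by lexicographic metabolite id so that the ordering is
#' identical across runs and machines. The ranks (a permutation of
#' \code{1..E}) are the objective coefficients of the second optimization
#' stage: among all minimum-cardinality media, the one with the smallest
#' summed rank is selected, which preferentially includes low molecular
#' weight compounds and makes the reported minimal environment unique.
#'
#' @param model a [MetabolicModel-class].
#' @return named integer vector of ranks (1-based), named by metabolite id
#'   and ordered by rank, so \code{names()} is the ranked id list.
#' @examples
#' m <- generateToyModel(toyModelSpec(nPrecursors = 2, seed = 1))
#' molarOrdering(m)
#' @export
molarOrdering <- function(model) {
  ids <- exchangeMetabolites(model)
  if (!length(ids)) return(stats::setNames(integer(), character()))
  mass <- resolveMasses(model, ids)
  ord <- order(mass, ids, method = "radix")
  stats::setNames(seq_along(ids), ids[ord])
}
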