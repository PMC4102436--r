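## Internal helpers: structured errors, seeded RNG scopes, small utilities.

## Error taxonomy shared with the command layer: each condition carries a
## stable class so batch drivers can triage failures by category.
minenvError <- function(class, message, ..., call. = FALSE) {
  structure(
    class = c(class, "minenvError", "error", "condition"),
    list(message = message, call = if (call.) sys.call(-1) else NULL, ...)
  )
}

parseError <- function(message, ...) {
  stop(minenvError("minenvParseError", message, ...))
}
modelError <- function(message, ...) {
  stop(minenvError("minenvModelError", message, ...))
}
massError <- function(message, ...) {
  stop(minenvError("minenvMassError", message, ...))
}
infeasibleError <- function(message, ...) {
  stop(minenvError("minenvInfeasibleError", message, ...))
}
timeoutError <- function(message, ...) {
  stop(minenvError("minenvTimeoutError", message, ...))
}
solverError <- function(message, ...) {
  stop(minenvError("minenvSolverError", message, ...))
}
lookupError <- function(message, ...) {
  stop(minenvError("minenvLookupError", message, ...))
}
preconditionError <- function(message, ...) {
  stop(minenvError("minenvPreconditionError", message, ...))
}

## Row indices (into the metabolite table) of the single metabolite touched
## by each exchange reaction, in exchange-reaction order.
exchangeMetaboliteRows <- function(model) {
  rxn <- model@reactions
  ex <- which(rxn$is_exchange)
  if (!length(ex)) return(integer())
  S <- methods::as(model@stoichiometry, "CsparseMatrix")
  vapply(ex, function(j) S@i[(S@p[j] + 1L):S@p[j + 1L]][1L] + 1L, integer(1))
}

## Map exchange metabolite id -> exchange reaction id (and coefficient sign).
exchangeMap <- function(model) {
  rows <- exchangeMetaboliteRows(model)
  ex <- which(model@reactions$is_exchange)
  S <- model@stoichiometry
  coef <- vapply(seq_along(ex), function(k) S[rows[k], ex[k]], numeric(1))
  data.frame(
    metabolite = model@metabolites$id[rows],
    reaction = model@reactions$id[ex],
    column = ex,
    coefficient = coef,
    stringsAsFactors = FALSE
  )
}

## Evaluate `expr` under a locally seeded RNG, restoring global state.
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

## Derive a child seed from a base seed and a stream label, keeping results
## inside the 32-bit integer range.
childSeed <- function(seed, stream) {
  h <- fnv1a(paste0(seed, ":", stream))
  as.integer(h %% 2147483647)
}

## FNV-1a string hash (used for child seeds and config fingerprints in logs).
fnv1a <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte (b < 256); keep h a double < 2^32
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b)
    # 32-bit modular multiply by the FNV prime without double overflow
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h
}

configHash <- function(config) {
  key <- paste(config@cutoff, config@uptakeMagnitude, config@solver,
               config@timeLimit, config@seed,
               paste(config@exemptMetabolites, collapse = ","), sep = "|")
  sprintf("%08x", fnv1a(key))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
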