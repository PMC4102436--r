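## Mixed-integer linear programming layer for minimal environments.
##
## The MILP couples each exchange flux f_i to a binary indicator theta_i via
##   f_i >= f_min * (1 - theta_i),   f_min = -uptakeMagnitude (big-M),
## so theta_i = 1 forces the exchange shut for uptake (f_i >= 0) while
## theta_i = 0 leaves uptake open; maximizing sum(theta) therefore minimizes
## the number of consumed exchange metabolites. Exchanges written in the
## reversed orientation (+1 coefficient) get the mirrored constraint
## f_i <= -f_min * (1 - theta_i).
##
## The solver is an exact depth-first branch-and-bound over the theta
## binaries with LP relaxations from the built-in simplex. All objective
## coefficients on theta are integers and every other variable has zero
## cost, so nodes are pruned with the integer bound floor(LP bound); the
## incumbent search explores the theta = 1 branch first and breaks all ties
## by lowest variable index, which makes the search fully deterministic.

## Assemble the equality-form MILP skeleton. Variables: fluxes (n), theta
## (E non-exempt exchanges), coupling slacks (E), and optionally one
## cardinality slack. Rows: metabolite balances, coupling rows, optional
## cardinality row  sum(theta) - s = E - K.
buildMinenvMILP <- function(model, cutoff, uptakeMagnitude = 1000,
                            exempt = character(), cardinality = NULL) {
  M <- uptakeMagnitude
  rxn <- model@reactions
  n <- nrow(rxn)
  ex <- exchangeMap(model)
  keep <- !(ex$metabolite %in% exempt)
  exTheta <- ex[keep, , drop = FALSE]
  E <- nrow(exTheta)

  lb <- rxn$lower_bound
  ub <- rxn$upper_bound
  # uptake is opened up to the magnitude M but never beyond the model's own
  # bounds (matching mediumBounds); exempt exchanges stay open unconditionally
  conv <- ex$coefficient < 0
  lb[ex$column[conv]] <- pmax(lb[ex$column[conv]], -M)
  ub[ex$column[!conv]] <- pmin(ub[ex$column[!conv]], M)
  bm <- match(model@biomassReaction, rxn$id)
  lb[bm] <- max(lb[bm], cutoff)
  if (lb[bm] > ub[bm]) {
    infeasibleError(sprintf(
      "biomass cutoff %g exceeds the biomass upper bound %g", cutoff, ub[bm]))
  }
  lb[!is.finite(lb)] <- -1e7

  m <- nrow(model@metabolites)
  nv <- n + 2L * E
  A <- matrix(0, m + E, nv)
  A[seq_len(m), seq_len(n)] <- as.matrix(model@stoichiometry)
  b <- rep(0, m + E)
  vlb <- c(lb, rep(0, E), rep(0, E))
  vub <- c(ub, rep(1, E), rep(0, E))
  thetaIdx <- n + seq_len(E)
  slackIdx <- n + E + seq_len(E)
  for (k in seq_len(E)) {
    j <- exTheta$column[k]
    r <- m + k
    if (exTheta$coefficient[k] < 0) {
      # f_j - M theta_k - s_k = -M  (s in [0, ub_j + M])
      A[r, j] <- 1; A[r, thetaIdx[k]] <- -M; A[r, slackIdx[k]] <- -1
      b[r] <- -M
      vub[slackIdx[k]] <- min(ub[j], 1e7) + M
    } else {
      # f_j + M theta_k + s_k = M   (s in [0, M - lb_j])
      A[r, j] <- 1; A[r, thetaIdx[k]] <- M; A[r, slackIdx[k]] <- 1
      b[r] <- M
      vub[slackIdx[k]] <- M - max(lb[j], -1e7)
    }
  }
  if (!is.null(cardinality)) {
    A <- rbind(A, 0)
    A[nrow(A), thetaIdx] <- 1
    crow <- nrow(A)
    A <- cbind(A, 0)
    A[crow, ncol(A)] <- -1
    b <- c(b, E - cardinality)
    vlb <- c(vlb, 0)
    vub <- c(vub, cardinality)
  }
  list(A = A, b = b, lb = vlb, ub = vub, thetaIdx = thetaIdx,
       metabolite = exTheta$metabolite, nvar = ncol(A))
}

## Exact branch-and-bound maximization of an integer-coefficient objective
## over the theta binaries. Returns the optimum and an optimal vertex, or
## raises a timeout error carrying the incumbent and the best bound.
milpSolve <- function(milp, objTheta, timeLimit = 300,
                      incumbent = NULL, fix0 = integer(), fix1 = integer(),
                      verbose = FALSE, stage = "milp") {
  t0 <- Sys.time()
  obj <- rep(0, milp$nvar)
  obj[milp$thetaIdx] <- objTheta
  lb0 <- milp$lb; ub0 <- milp$ub
  ub0[milp$thetaIdx[fix0]] <- 0
  lb0[milp$thetaIdx[fix1]] <- 1
  if (any(lb0 > ub0)) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL,
                nodes = 0L, bound = NA_real_))
  }
  best <- -Inf
  bestx <- NULL
  if (!is.null(incumbent)) { best <- incumbent$objective; bestx <- incumbent$x }
  rootBound <- NA_real_
  nodes <- 0L
  stack <- list(list(lb = lb0, ub = ub0))
  while (length(stack)) {
    if (as.numeric(Sys.time() - t0) > timeLimit) {
      timeoutError(sprintf(
        "MILP time limit (%gs) reached; incumbent %g, best bound %g",
        timeLimit, best, rootBound),
        incumbent = bestx, objective = best, bound = rootBound)
    }
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    rel <- solveLP(obj, milp$A, milp$b, node$lb, node$ub, maximize = TRUE)
    nodes <- nodes + 1L
    if (rel$status == "unbounded") {
      solverError("MILP relaxation unbounded; model has unbounded fluxes")
    }
    if (rel$status != "optimal") next
    if (nodes == 1L) rootBound <- rel$objective
    # integer-valued optimum: anything not strictly better than the
    # incumbent after rounding down cannot improve it
    if (floor(rel$objective + 1e-6) <= best) next
    th <- rel$x[milp$thetaIdx]
    frac <- abs(th - round(th))
    if (all(frac < 1e-6)) {
      best <- round(sum(objTheta * round(th)))
      bestx <- rel$x
      bestx[milp$thetaIdx] <- round(th)
      next
    }
    pick <- which(frac >= 1e-6)
    pick <- pick[order(abs(th[pick] - 0.5), pick)][1L]
    j <- milp$thetaIdx[pick]
    lo <- node; lo$ub[j] <- 0
    hi <- node; hi$lb[j] <- 1
    stack[[length(stack) + 1L]] <- lo # explored second
    stack[[length(stack) + 1L]] <- hi # theta = 1 first
  }
  if (verbose) {
    message(sprintf(
      "milp stage=%s status=%s objective=%g bound=%g nodes=%d wall=%.2fs",
      stage, if (is.finite(best)) "optimal" else "infeasible",
      best, rootBound, nodes, as.numeric(Sys.time() - t0)))
  }
  if (!is.finite(best)) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL,
                nodes = nodes, bound = rootBound))
  }
  list(status = "optimal", objective = best, x = bestx, nodes = nodes,
       bound = rootBound)
}

## Greedy warm start for stage 1: close exchanges one at a time (most
## promising first, by descending relaxation theta) while growth persists.
greedyWitness <- function(model, cutoff, M, exempt, milp) {
  rel <- solveLP(replace(rep(0, milp$nvar), milp$thetaIdx, 1),
                 milp$A, milp$b, milp$lb, milp$ub, maximize = TRUE)
  ord <- if (rel$status == "optimal") {
    order(-rel$x[milp$thetaIdx], seq_along(milp$thetaIdx))
  } else {
    seq_along(milp$thetaIdx)
  }
  open <- milp$metabolite
  for (k in ord) {
    mtry <- setdiff(open, milp$metabolite[k])
    if (grows(model, medium(c(mtry, exempt), M), cutoff)) open <- mtry
  }
  open
}
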