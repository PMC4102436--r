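## Thin R wrapper over the compiled bounded-variable simplex.
##
## solveLP maximizes obj'x subject to A x = b and lb <= x <= ub. Lower
## bounds must be finite; upper bounds may be +Inf (an unblocked improving
## ray is reported as "unbounded"). Feasibility/optimality tolerances are
## 1e-7 on reduced costs and 1e-7 on phase-1 residuals, appropriate for the
## flux scales (bounds of order 1e3) used throughout.

LP_STATUS <- c("optimal", "infeasible", "unbounded", "maxiter")

solveLP <- function(obj, A, b, lb, ub, maximize = TRUE) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  if (!maximize) obj <- -obj
  res <- .simplex_solve(A, as.numeric(b), as.numeric(obj),
                        as.numeric(lb), as.numeric(ub))
  status <- LP_STATUS[res$status + 1L]
  if (status == "maxiter") {
    solverError("LP solver hit its iteration limit")
  }
  list(status = status,
       objective = if (status == "optimal") {
         if (maximize) res$objective else -res$objective
       } else NA_real_,
       x = if (status == "optimal") res$x else NULL)
}
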