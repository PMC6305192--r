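# Thin R wrapper around the compiled bounded-variable simplex.

lp_status <- c("optimal", "infeasible", "iteration_limit", "unbounded",
               "numerical")

# min c'x  s.t.  A x = b,  lb <= x <= ub. Returns list(status, x, objective).
solve_lp <- function(A, b, cc, lb, ub, maxiter = 50000L) {
  A <- as.matrix(A)
  res <- .simplex_solve(A, as.numeric(b), as.numeric(cc), as.numeric(lb),
                        as.numeric(ub), as.integer(maxiter))
  status <- lp_status[res$status + 1L]
  if (status %in% c("iteration_limit", "numerical"))
    stop("LP solver failed (", status, "); m=", nrow(A), " n=", ncol(A))
  list(status = status, x = as.numeric(res$x), objective = res$objective)
}

# Assemble the steady-state LP skeleton of a model: dense S (sorted ids),
# bound vectors, and the reaction-id ordering shared by all flux vectors.
lp_skeleton <- function(model) {
  S <- stoichiometric_matrix(model)
  rids <- colnames(S)
  ord <- match(rids, model$reactions$id)
  list(S = as.matrix(S), rids = rids,
       lb = model$reactions$lower_bound[ord],
       ub = model$reactions$upper_bound[ord])
}
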