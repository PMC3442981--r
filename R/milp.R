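# Branch-and-bound for mixed-binary linear programs over the bounded
# simplex in lp.R. Depth-first with dive-on-rounding, most-fractional
# branching, and bound pruning against the incumbent. Sized for the
# knockout-design MILPs this package builds (tens of binaries at most).
#
# `target`: optional early-exit threshold -- stop as soon as an integral
# solution with objective >= target is in hand (used for the
# deterministic tie-break refinement, where only feasibility at a known
# optimum is in question).

milpSolve <- function(A, b, c, lb, ub, int_idx, sense = c("max", "min"),
                      atol = 1e-9, target = NULL, maxnodes = 200000L) {
  sense <- match.arg(sense)
  sgn <- if (sense == "min") -1 else 1
  cint <- sgn * c
  if (!is.null(target)) target <- sgn * target
  best <- list(obj = -Inf, x = NULL)
  stack <- list(list(lb = lb, ub = ub))
  nodes <- 0L
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nodes <- nodes + 1L
    if (nodes > maxnodes) stop("branch-and-bound node limit reached")
    fit <- simplexLP(A, b, cint, nd$lb, nd$ub, "max")
    if (fit$status == "unbounded")
      stop("MILP relaxation unbounded; a variable bound is missing")
    if (fit$status != "optimal") next
    if (fit$obj <= best$obj + atol) next
    # clamp into the node box before integrality testing: a solver
    # tolerance-level bound violation must not masquerade as a
    # fractional value, or branching would recreate the same node
    xi <- pmin(pmax(fit$x[int_idx], nd$lb[int_idx]), nd$ub[int_idx])
    fr <- abs(xi - round(xi))
    if (length(fr) == 0L || max(fr) <= 1e-6) {
      x <- fit$x
      x[int_idx] <- round(xi)
      best <- list(obj = fit$obj, x = x)
      if (!is.null(target) && best$obj >= target - atol) break
      next
    }
    k <- which.max(fr)
    j <- int_idx[k]
    nd0 <- nd; nd0$ub[j] <- floor(xi[k])
    nd1 <- nd; nd1$lb[j] <- floor(xi[k]) + 1
    if (xi[k] - floor(xi[k]) >= 0.5)
      stack <- c(stack, list(nd0), list(nd1))
    else
      stack <- c(stack, list(nd1), list(nd0))
  }
  if (is.null(best$x))
    list(status = "infeasible", nodes = nodes)
  else
    list(status = "optimal", x = best$x, obj = sgn * best$obj,
         nodes = nodes)
}
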