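# Bounded-variable LP interface over the compiled simplex core
# (src/simplex.cpp). Solves
#
#   max/min  c'x   s.t.  A x = b,  lb <= x <= ub
#
# with finite or infinite bounds, returning the primal solution, dual
# row prices (lambda) and reduced costs. Sized for desk-scale metabolic
# models; minimization is handled by negating the objective, with the
# returned objective, lambda and reduced costs flipped back so the KKT
# conventions below hold in the original problem.

simplexLP <- function(A, b, c, lb, ub, sense = c("max", "min"),
                      tol = 1e-9, maxit = 100000L) {
  sense <- match.arg(sense)
  A <- as.matrix(A)
  stopifnot(length(b) == nrow(A), length(c) == ncol(A),
            length(lb) == ncol(A), length(ub) == ncol(A))
  if (any(lb > ub)) return(list(status = "infeasible"))
  sgn <- if (sense == "min") -1 else 1
  fit <- .simplex_core(A, as.numeric(b), sgn * as.numeric(c),
                       as.numeric(lb), as.numeric(ub), tol,
                       as.integer(maxit))
  status <- c("optimal", "infeasible", "unbounded")[fit$status + 1L]
  if (status != "optimal") return(list(status = status))
  list(status = "optimal",
       x = fit$x,
       obj = sgn * fit$obj,
       lambda = sgn * fit$lambda,
       reduced = sgn * fit$reduced,
       iterations = fit$iterations)
}

# KKT-based duality audit for a solved LP in this package's conventions.
# For sense "max": reduced cost d_j = c_j - lambda'A_j; mu_ub = max(d,0),
# mu_lb = max(-d,0); dual objective lambda'b + sum(ub*mu_ub - lb*mu_lb)
# must equal the primal objective at an optimum (strong duality). For
# sense "min" the signs of lambda and d returned by simplexLP are
# already flipped, so mu_ub = max(-d,0), mu_lb = max(d,0) and the dual
# contribution of the bounds enters with the opposite sign.
lpDualObjective <- function(fit, b, lb, ub, sense = "max") {
  d <- fit$reduced
  if (sense == "max") {
    mu_ub <- pmax(d, 0); mu_lb <- pmax(-d, 0)
  } else {
    mu_ub <- pmax(-d, 0); mu_lb <- pmax(d, 0)
  }
  # a bound at infinity cannot be active; any multiplier there is
  # tolerance-level noise and would otherwise contribute Inf * 0
  mu_ub[!is.finite(ub)] <- 0
  mu_lb[!is.finite(lb)] <- 0
  ubt <- ifelse(mu_ub > 0, ub * mu_ub, 0)
  lbt <- ifelse(mu_lb > 0, lb * mu_lb, 0)
  s <- if (sense == "max") 1 else -1
  sum(fit$lambda * b) + s * sum(ubt) - s * sum(lbt)
}
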