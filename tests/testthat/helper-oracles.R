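# Independent oracles used across the suite. These deliberately avoid
# the code paths they check: the LP oracle enumerates basic solutions
# directly, and the GPR oracle enumerates gene subsets exhaustively.

# Vertex-enumeration LP oracle for small problems (finite bounds,
# full-row-rank A): the optimum of a bounded feasible LP is attained at
# a basic solution, so trying every basis x bound assignment finds it.
# Returns the optimal value of max c'x s.t. Ax = b, lb <= x <= ub, or
# NULL when infeasible.
oracleLPMax <- function(A, b, c, lb, ub) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(all(is.finite(lb)), all(is.finite(ub)), m < n)
  best <- NULL
  for (B in utils::combn(n, m, simplify = FALSE)) {
    AB <- A[, B, drop = FALSE]
    if (abs(det(AB)) < 1e-9) next
    NB <- setdiff(seq_len(n), B)
    grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(NB)))
    for (g in seq_len(nrow(grid))) {
      at_ub <- as.logical(grid[g, ])
      xn <- ifelse(at_ub, ub[NB], lb[NB])
      xb <- solve(AB, b - A[, NB, drop = FALSE] %*% xn)
      x <- numeric(n); x[NB] <- xn; x[B] <- xb
      if (all(x >= lb - 1e-8) && all(x <= ub + 1e-8)) {
        obj <- sum(c * x)
        if (is.null(best) || obj > best) best <- obj
      }
    }
  }
  best
}

# Exhaustive gene-subset oracle: all inclusion-minimal gene sets whose
# deletion makes every listed GPR expression evaluate FALSE.
oracleMinimalKnockouts <- function(exprs, genes) {
  found <- list()
  for (k in seq_along(genes)) {
    for (s in utils::combn(genes, k, simplify = FALSE)) {
      if (any(vapply(found, function(f) all(f %in% s), logical(1))))
        next
      if (all(!vapply(exprs, evaluateGPR, logical(1), s)))
        found <- c(found, list(s))
    }
  }
  found
}

# Random GPR expression tree (for the parse/deparse idempotence
# property); depth-limited, drawing genes from a fixed pool.
randomGprTree <- function(depth = 3L, pool = paste0("G", 1:6)) {
  if (depth == 0L || stats::runif(1) < 0.4)
    return(structure(list(op = "gene", gene = sample(pool, 1)),
                     class = "gpr"))
  op <- sample(c("and", "or"), 1)
  k <- sample(2:3, 1)
  structure(list(op = op, args = replicate(k, unclass(
    randomGprTree(depth - 1L, pool)), simplify = FALSE)), class = "gpr")
}

pyrEnv <- function() environmentSpec()

runBudstrainCLI <- function(...) {
  script <- system.file("scripts", "budstrain.R", package = "budstrain")
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(
    system2(rscript, c(script, ...), stdout = TRUE, stderr = TRUE))
  list(status = attr(out, "status") %||% 0L, output = out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
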