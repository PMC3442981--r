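#' Molar masses used for flux-to-mass-yield conversion
#'
#' Standard molar masses (g/mol) of the fermentation species handled by
#' this package: R,R-2,3-butanediol, glucose, ethanol, glycerol, acetate.
#'
#' @format named numeric (g/mol).
#' @export
molarMasses <- c(butanediol = 90.121, glucose = 180.156, ethanol = 46.068,
                 glycerol = 92.094, acetate = 60.052)

#' Apply environment constraints to a model
#'
#' Overrides model bounds with the environment's uptake and maintenance
#' constraints: each uptake entry sets the lower bound of its exchange
#' reaction (uptake negative), each maintenance entry sets the lower
#' bound of the maintenance reaction. All other bounds are left as the
#' model declares them.
#'
#' @param model a [MetabolicModel-class].
#' @param env an [EnvironmentSpec-class], or NULL for no overrides.
#' @return a derived [MetabolicModel-class] copy.
#' @export
applyEnvironment <- function(model, env) {
  if (is.null(env)) return(model)
  stopifnot(is(env, "EnvironmentSpec"))
  for (id in names(env@uptakes)) {
    k <- rxnIndex(model, id)
    if (classifyReaction(model, id) != "exchange")
      stop("uptake bound for non-exchange reaction: ", id)
    model@reactions$lb[k] <- env@uptakes[[id]]
  }
  for (id in names(env@maintenance)) {
    k <- rxnIndex(model, id)
    if (model@reactions$kind[k] != "maintenance")
      stop("maintenance bound for non-maintenance reaction: ", id)
    model@reactions$lb[k] <- env@maintenance[[id]]
  }
  validObject(model)
  model
}

#' Flux balance analysis
#'
#' Solves the FBA linear program: optimize the flux of one reaction
#' subject to steady-state mass balance (S v = 0) and flux bounds, with
#' environment overrides applied first. Returns the flux vector, the
#' objective value, the solver status, and the LP dual prices (one per
#' metabolite) and reduced costs used by the strong-duality audit.
#'
#' @param model a [MetabolicModel-class].
#' @param env an [EnvironmentSpec-class] or NULL.
#' @param objective_id reaction whose flux is optimized; defaults to the
#'   model objective (biomass).
#' @param sense "max" or "min".
#' @param tol LP tolerance.
#' @return a [FluxDistribution-class].
#' @examples
#' m <- makePyrcore()
#' sol <- solveFBA(m, environmentSpec())
#' objectiveValue(sol)   # maximal growth of the fixture
#' @export
solveFBA <- function(model, env = NULL, objective_id = objectiveId(model),
                     sense = c("max", "min"), tol = 1e-9) {
  sense <- match.arg(sense)
  model <- applyEnvironment(model, env)
  k <- rxnIndex(model, objective_id)
  n <- nrow(model@reactions)
  cvec <- numeric(n); cvec[k] <- 1
  fit <- simplexLP(as.matrix(model@stoichiometry),
                   b = numeric(nrow(model@metabolites)),
                   c = cvec,
                   lb = model@reactions$lb, ub = model@reactions$ub,
                   sense = sense, tol = tol)
  if (fit$status != "optimal")
    return(new("FluxDistribution", fluxes = numeric(), objective = NA_real_,
               status = fit$status, duals = numeric(), reduced = numeric()))
  new("FluxDistribution",
      fluxes = stats::setNames(fit$x, model@reactions$id),
      objective = fit$obj,
      status = "optimal",
      duals = stats::setNames(fit$lambda, model@metabolites$id),
      reduced = stats::setNames(fit$reduced, model@reactions$id))
}

#' Dual objective of a solved FBA problem
#'
#' Reconstructs the LP dual objective from the dual prices and reduced
#' costs stored in a [FluxDistribution-class]. At an optimum this equals
#' the primal objective (strong duality); the package's property tests
#' assert agreement to 1e-6 relative.
#'
#' @param model,env the model and environment the distribution was
#'   solved under.
#' @param fd an optimal [FluxDistribution-class].
#' @param sense the sense the problem was solved with.
#' @return numeric(1) dual objective value.
#' @export
dualObjective <- function(model, env, fd, sense = "max") {
  stopifnot(fd@status == "optimal")
  model <- applyEnvironment(model, env)
  lpDualObjective(list(lambda = unname(fd@duals), reduced = unname(fd@reduced)),
                  b = numeric(nrow(model@metabolites)),
                  lb = model@reactions$lb, ub = model@reactions$ub,
                  sense = sense)
}

#' Lexicographic two-stage optimization
#'
#' Optimizes a primary reaction flux, fixes it (within a tolerance of
#' \code{1e-9 * max(1, |optimum|)}), then optimizes a secondary reaction
#' flux. This is how every "production at maximal growth" number in this
#' package is computed: FBA optima are usually degenerate, so the vertex
#' a solver happens to return is not meaningful for the secondary flux.
#'
#' @param model a [MetabolicModel-class].
#' @param env an [EnvironmentSpec-class] or NULL.
#' @param primary_id,secondary_id reaction ids.
#' @param primary_sense,secondary_sense "max" or "min".
#' @param tol relative tolerance for fixing the primary optimum.
#' @return the second-stage [FluxDistribution-class]; its objective is
#'   the secondary optimum. Non-optimal first-stage status propagates.
#' @export
fixAndOptimize <- function(model, env = NULL, primary_id, secondary_id,
                           primary_sense = "max", secondary_sense = "max",
                           tol = 1e-9) {
  model <- applyEnvironment(model, env)
  s1 <- solveFBA(model, NULL, primary_id, primary_sense)
  if (s1@status != "optimal") return(s1)
  opt <- s1@objective
  eps <- tol * max(1, abs(opt))
  k <- rxnIndex(model, primary_id)
  model@reactions$lb[k] <- max(model@reactions$lb[k], opt - eps)
  model@reactions$ub[k] <- min(model@reactions$ub[k], opt + eps)
  solveFBA(model, NULL, secondary_id, secondary_sense)
}

#' Flux variability analysis
#'
#' For each requested reaction, minimizes and maximizes its flux while
#' growth is held at at least \code{growth_fraction} of its maximum.
#'
#' @param model a [MetabolicModel-class].
#' @param env an [EnvironmentSpec-class] or NULL.
#' @param reaction_ids reactions to scan (may be empty).
#' @param growth_fraction fraction of maximal growth in [0, 1] to impose.
#' @param tol relative tolerance when fixing the growth bound.
#' @return data.frame with columns \code{reaction}, \code{min},
#'   \code{max}.
#' @export
solveFVA <- function(model, env = NULL, reaction_ids,
                     growth_fraction = 1, tol = 1e-9) {
  stopifnot(growth_fraction >= 0, growth_fraction <= 1)
  model <- applyEnvironment(model, env)
  reaction_ids <- as.character(reaction_ids)
  if (length(reaction_ids) == 0L)
    return(data.frame(reaction = character(), min = numeric(),
                      max = numeric()))
  rxnIndex(model, reaction_ids)
  base <- solveFBA(model)
  if (base@status != "optimal")
    stop("FVA base problem is ", base@status)
  mu <- base@objective
  k <- rxnIndex(model, objectiveId(model))
  floorv <- growth_fraction * mu - tol * max(1, abs(mu))
  model@reactions$lb[k] <- max(model@reactions$lb[k], floorv)
  res <- lapply(reaction_ids, function(r) {
    lo <- solveFBA(model, NULL, r, "min")
    hi <- solveFBA(model, NULL, r, "max")
    if (lo@status != "optimal" || hi@status != "optimal")
      stop("FVA subproblem for ", r, " is not optimal")
    c(lo@objective, hi@objective)
  })
  data.frame(reaction = reaction_ids,
             min = vapply(res, `[`, numeric(1), 1L),
             max = vapply(res, `[`, numeric(1), 2L))
}

#' Production envelope of a target reaction
#'
#' Computes the attainable (min, max) target flux along an equispaced
#' grid of growth values from 0 to the maximum. A collapsed envelope at
#' maximal growth (min = max > 0) is the signature of growth-coupled
#' production.
#'
#' @param model a [MetabolicModel-class].
#' @param env an [EnvironmentSpec-class] or NULL.
#' @param target_id target reaction id (typically a product exchange).
#' @param n_points number of grid points (>= 2).
#' @param tol relative tolerance when fixing growth.
#' @return a [ProductionEnvelope-class].
#' @export
productionEnvelope <- function(model, env = NULL, target_id, n_points = 20L,
                               tol = 1e-9) {
  stopifnot(n_points >= 2L)
  model <- applyEnvironment(model, env)
  rxnIndex(model, target_id)
  base <- solveFBA(model)
  if (base@status != "optimal")
    stop("envelope base problem is ", base@status)
  mu <- base@objective
  if (mu <= tol) {
    warning("maximum growth is zero; returning a single-point envelope")
    rng <- solveFVA(model, NULL, target_id, growth_fraction = 0)
    return(new("ProductionEnvelope", target = target_id, growth = 0,
               min = rng$min, max = rng$max))
  }
  grid <- seq(0, 1, length.out = n_points) * mu
  k <- rxnIndex(model, objectiveId(model))
  lo <- hi <- numeric(n_points)
  for (i in seq_len(n_points)) {
    # growth is fixed (within tolerance) at each grid value, so the
    # envelope of the objective against itself collapses onto the grid
    mi <- model
    eps <- tol * max(1, abs(grid[i]))
    mi@reactions$lb[k] <- max(mi@reactions$lb[k], grid[i] - eps)
    mi@reactions$ub[k] <- min(mi@reactions$ub[k], grid[i] + eps)
    a <- solveFBA(mi, NULL, target_id, "min")
    b <- solveFBA(mi, NULL, target_id, "max")
    if (a@status != "optimal" || b@status != "optimal")
      stop("envelope subproblem at growth ", grid[i], " is not optimal")
    lo[i] <- a@objective; hi[i] <- b@objective
  }
  # numeric guard: min can exceed max by solver tolerance at degenerate points
  sw <- lo > hi
  if (any(sw)) { m2 <- (lo[sw] + hi[sw]) / 2; lo[sw] <- m2; hi[sw] <- m2 }
  new("ProductionEnvelope", target = target_id, growth = grid,
      min = lo, max = hi)
}

#' Apply reaction and gene knockouts
#'
#' Returns a derived model in which the listed reactions, plus every
#' reaction whose GPR evaluates FALSE under the listed gene deletions,
#' have both bounds set to zero. The original model is untouched. The
#' full set of zeroed reactions is attached as attribute
#' \code{"knockedOut"}.
#'
#' @param model a [MetabolicModel-class].
#' @param reactions character vector of reaction ids to disable.
#' @param genes character vector of gene ids to delete.
#' @return a derived [MetabolicModel-class] with attribute
#'   \code{"knockedOut"}.
#' @examples
#' m <- makePyrcore()
#' attr(applyKnockouts(m, genes = c("ADH1")), "knockedOut")   # none: isozymes
#' attr(applyKnockouts(m, genes = c("ADH1", "ADH3", "ADH5")), "knockedOut")
#' @export
applyKnockouts <- function(model, reactions = character(),
                           genes = character()) {
  reactions <- as.character(reactions); genes <- as.character(genes)
  rxnIndex(model, reactions)                       # errors before mutation
  unknown <- setdiff(genes, model@genes)
  if (length(unknown))
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "))
  off <- reactions
  if (length(genes)) {
    silenced <- model@reactions$id[!vapply(model@reactions$id, function(r)
      evaluateGPR(gprOf(model, r), genes), logical(1))]
    off <- union(off, silenced)
  }
  for (r in off) {
    k <- rxnIndex(model, r)
    model@reactions$lb[k] <- 0
    model@reactions$ub[k] <- 0
  }
  attr(model, "knockedOut") <- sort(off)
  model
}

#' Convert molar fluxes to a mass yield
#'
#' Computes the mass yield Y = (v_target * MW_target) /
#' (|v_substrate| * MW_substrate) in g product per g substrate, the unit
#' strain-design tables report.
#'
#' @param v_target target flux (mmol/gDCW/h).
#' @param v_substrate substrate uptake flux (non-zero; sign ignored).
#' @param mw_target,mw_substrate molar masses (g/mol), e.g. from
#'   [molarMasses].
#' @return a list of class \code{"yieldReport"} carrying all inputs and
#'   \code{yield}.
#' @examples
#' fluxToMassYield(10 / 11, -10, molarMasses["butanediol"],
#'                 molarMasses["glucose"])
#' @export
fluxToMassYield <- function(v_target, v_substrate, mw_target, mw_substrate) {
  if (abs(v_substrate) == 0)
    stop("substrate flux is zero; mass yield undefined")
  y <- (v_target * mw_target) / (abs(v_substrate) * mw_substrate)
  structure(list(v_target = v_target, v_substrate = v_substrate,
                 mw_target = unname(mw_target),
                 mw_substrate = unname(mw_substrate),
                 yield = unname(y)),
            class = "yieldReport")
}

#' @method print yieldReport
#' @export
print.yieldReport <- function(x, ...) {
  cat(sprintf("yield %.6g g/g (target %.6g mmol/gDCW/h x %.6g g/mol over |%.6g| x %.6g)\n",
              x$yield, x$v_target, x$mw_target, x$v_substrate,
              x$mw_substrate))
  invisible(x)
}
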