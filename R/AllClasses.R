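#' @import methods
#' @importFrom Matrix sparseMatrix Matrix t colSums rowSums
NULL

#' MetabolicModel: a constraint-based metabolic model
#'
#' Holds a compartmentalized stoichiometric model: metabolites, reactions
#' with flux bounds (mmol/gDCW/h) and gene-protein-reaction (GPR) rules,
#' the sparse stoichiometric matrix S (metabolites x reactions, negative
#' coefficients = consumed), the gene inventory, and the id of the
#' biomass (objective) reaction. Metabolite ids follow the convention
#' \code{<species>_<compartment>} (e.g. \code{glc_e}, \code{pyr_c}), which
#' makes transport detection purely syntactic.
#'
#' @slot metabolites data.frame with columns \code{id}, \code{name},
#'   \code{compartment}.
#' @slot reactions data.frame with columns \code{id}, \code{name},
#'   \code{lb}, \code{ub}, \code{gpr} (rule string, "" = always on),
#'   \code{kind} (one of exchange, transport, internal, biomass,
#'   maintenance).
#' @slot stoichiometry \code{dgCMatrix}, metabolites x reactions.
#' @slot genes character vector of gene ids.
#' @slot objective character(1), reaction id of the biomass objective.
#' @seealso [metabolicModel()], [makePyrcore()], [solveFBA()]
#' @export
setClass("MetabolicModel",
  representation(
    metabolites = "data.frame",
    reactions = "data.frame",
    stoichiometry = "Matrix",
    genes = "character",
    objective = "character"
  ))

setValidity("MetabolicModel", function(object) {
  msg <- character()
  met <- object@metabolites
  rxn <- object@reactions
  S <- object@stoichiometry
  need <- function(df, cols, what)
    if (!all(cols %in% names(df)))
      msg <<- c(msg, paste0(what, " must have columns ",
                            paste(cols, collapse = ", ")))
  need(met, c("id", "name", "compartment"), "metabolites")
  need(rxn, c("id", "name", "lb", "ub", "gpr", "kind"), "reactions")
  if (length(msg)) return(msg)
  if (anyDuplicated(met$id)) msg <- c(msg, "duplicated metabolite ids")
  if (anyDuplicated(rxn$id)) msg <- c(msg, "duplicated reaction ids")
  if (any(!nzchar(met$compartment)))
    msg <- c(msg, "every metabolite needs a non-empty compartment")
  if (!identical(dim(S), c(nrow(met), nrow(rxn))))
    msg <- c(msg, "stoichiometry dimensions must be |metabolites| x |reactions|")
  else {
    if (!identical(rownames(S), met$id) || !identical(colnames(S), rxn$id))
      msg <- c(msg, "stoichiometry dimnames must match metabolite/reaction ids")
    if (any(Matrix::colSums(S != 0) == 0))
      msg <- c(msg, "every reaction needs non-empty stoichiometry")
  }
  if (any(rxn$lb > rxn$ub))
    msg <- c(msg, paste("lb > ub for reaction(s):",
                        paste(rxn$id[rxn$lb > rxn$ub], collapse = ", ")))
  if (!all(rxn$kind %in% c("exchange", "transport", "internal",
                           "biomass", "maintenance")))
    msg <- c(msg, "unknown reaction kind")
  if (sum(rxn$kind == "biomass") > 1L)
    msg <- c(msg, "at most one biomass reaction")
  if (sum(rxn$kind == "maintenance") > 1L)
    msg <- c(msg, "at most one maintenance reaction")
  if (length(object@objective) != 1L || !(object@objective %in% rxn$id))
    msg <- c(msg, "objective must name one existing reaction")
  gprGenesAll <- tryCatch(
    unique(unlist(lapply(rxn$gpr, function(g) gprGenes(parseGPR(g))))),
    error = function(e) {
      msg <<- c(msg, conditionMessage(e)); character()
    })
  if (!all(gprGenesAll %in% object@genes))
    msg <- c(msg, paste("GPR gene(s) missing from gene inventory:",
                        paste(setdiff(gprGenesAll, object@genes), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a MetabolicModel
#'
#' @param metabolites data.frame with \code{id} and \code{compartment}
#'   (and optionally \code{name}) columns, or a character vector of ids
#'   ending in \code{_<compartment>}.
#' @param reactions data.frame with columns \code{id}, \code{lb},
#'   \code{ub} and optionally \code{name}, \code{gpr}, \code{kind}. A
#'   \code{kind} of \code{NA} is classified structurally (see
#'   [classifyReaction()]); only \code{biomass} and \code{maintenance}
#'   need tagging.
#' @param stoichiometry named list, one element per reaction id, each a
#'   named numeric of metabolite coefficients (negative = consumed).
#' @param genes character vector of gene ids; defaults to the genes
#'   referenced by the GPR rules.
#' @param objective reaction id of the biomass objective; defaults to the
#'   reaction tagged \code{biomass}.
#' @return a validated [MetabolicModel-class].
#' @export
metabolicModel <- function(metabolites, reactions, stoichiometry,
                           genes = NULL, objective = NULL) {
  if (is.character(metabolites))
    metabolites <- data.frame(id = metabolites)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$compartment))
    metabolites$compartment <- sub("^.*_([^_]+)$", "\\1", metabolites$id)
  metabolites <- metabolites[c("id", "name", "compartment")]
  rownames(metabolites) <- NULL

  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(reactions$gpr)) reactions$gpr <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  if (is.null(reactions$kind)) reactions$kind <- NA_character_
  reactions <- reactions[c("id", "name", "lb", "ub", "gpr", "kind")]
  rownames(reactions) <- NULL

  stopifnot(setequal(names(stoichiometry), reactions$id))
  i <- integer(); j <- integer(); x <- numeric()
  for (k in seq_len(nrow(reactions))) {
    co <- stoichiometry[[reactions$id[k]]]
    co <- co[co != 0]
    if (length(co) == 0L)
      stop("reaction ", reactions$id[k], " has empty stoichiometry")
    mi <- match(names(co), metabolites$id)
    if (anyNA(mi))
      stop("reaction ", reactions$id[k], " references undeclared metabolite(s): ",
           paste(names(co)[is.na(mi)], collapse = ", "))
    i <- c(i, mi); j <- c(j, rep(k, length(co))); x <- c(x, unname(co))
  }
  S <- Matrix::sparseMatrix(i = i, j = j, x = x,
                            dims = c(nrow(metabolites), nrow(reactions)),
                            dimnames = list(metabolites$id, reactions$id))
  for (k in which(is.na(reactions$kind)))
    reactions$kind[k] <- classifyStructurally(S, metabolites, k)
  new("MetabolicModel",
      metabolites = metabolites,
      reactions = reactions,
      stoichiometry = S,
      genes = if (is.null(genes))
        sort(unique(unlist(lapply(reactions$gpr,
          function(g) gprGenes(parseGPR(g))))))
      else sort(unique(genes)),
      objective = objective %||% reactions$id[
        which(reactions$kind == "biomass")[1]])
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' EnvironmentSpec: simulation environment constraints
#'
#' Captures the constraint set a simulation is run under: uptake bounds
#' on exchange reactions (sign convention: uptake is negative, so glucose
#' uptake of 10 mmol/gDCW/h is a lower bound of -10) and the
#' non-growth-associated ATP maintenance requirement (a lower bound on
#' the maintenance reaction).
#'
#' @slot uptakes named numeric; lower bounds for exchange reactions.
#' @slot maintenance named numeric; lower bounds for maintenance
#'   reactions (usually one entry, e.g. \code{c(ATPM = 1)}).
#' @seealso [environmentSpec()], [applyEnvironment()]
#' @export
setClass("EnvironmentSpec",
  representation(uptakes = "numeric", maintenance = "numeric"))

setValidity("EnvironmentSpec", function(object) {
  msg <- character()
  if (length(object@uptakes) && is.null(names(object@uptakes)))
    msg <- c(msg, "uptakes must be named by exchange reaction id")
  if (length(object@maintenance) && is.null(names(object@maintenance)))
    msg <- c(msg, "maintenance must be named by reaction id")
  if (any(object@uptakes > 0))
    msg <- c(msg, "uptake bounds are lower bounds and must be <= 0 (uptake negative)")
  if (any(object@maintenance < 0))
    msg <- c(msg, "maintenance lower bound must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct an EnvironmentSpec
#'
#' The default reproduces the simulation constraints used throughout this
#' package: glucose uptake 10, oxygen uptake 2, ATP maintenance 1
#' (mmol/gDCW/h).
#'
#' @param uptakes named numeric of exchange-reaction lower bounds
#'   (uptake negative).
#' @param maintenance named numeric of maintenance-reaction lower bounds.
#' @return an [EnvironmentSpec-class].
#' @export
environmentSpec <- function(uptakes = c(EX_glc_e = -10, EX_o2_e = -2),
                            maintenance = c(ATPM = 1)) {
  new("EnvironmentSpec", uptakes = uptakes, maintenance = maintenance)
}

#' FluxDistribution: one steady-state flux solution
#'
#' @slot fluxes named numeric, one flux per reaction (empty unless
#'   status is "optimal").
#' @slot objective numeric(1), objective value (NA unless optimal).
#' @slot status one of "optimal", "infeasible", "unbounded".
#' @slot duals named numeric, metabolite dual prices (lambda) from the LP.
#' @slot reduced named numeric, reaction reduced costs.
#' @seealso [solveFBA()]
#' @export
setClass("FluxDistribution",
  representation(fluxes = "numeric", objective = "numeric",
                 status = "character", duals = "numeric",
                 reduced = "numeric"))

setValidity("FluxDistribution", function(object) {
  if (!object@status %in% c("optimal", "infeasible", "unbounded"))
    "status must be optimal, infeasible or unbounded" else TRUE
})

#' ProductionEnvelope: attainable product flux versus growth
#'
#' Ordered triples (growth, minimum target flux, maximum target flux)
#' along a grid of growth values from zero to the maximum. A collapsed
#' envelope (min = max > 0) at maximal growth indicates growth-coupled
#' production.
#'
#' @slot target character(1), target reaction id.
#' @slot growth numeric, non-decreasing growth grid.
#' @slot min,max numeric, attainable target-flux range per grid point.
#' @seealso [productionEnvelope()]
#' @export
setClass("ProductionEnvelope",
  representation(target = "character", growth = "numeric",
                 min = "numeric", max = "numeric"))

setValidity("ProductionEnvelope", function(object) {
  msg <- character()
  n <- length(object@growth)
  if (length(object@min) != n || length(object@max) != n)
    msg <- c(msg, "growth, min, max must have equal length")
  else {
    if (is.unsorted(object@growth)) msg <- c(msg, "growth grid must be non-decreasing")
    if (any(object@min > object@max + 1e-6))
      msg <- c(msg, "envelope minimum exceeds maximum")
  }
  if (length(msg)) msg else TRUE
})

#' KnockoutStrategy: a designed set of reaction deletions
#'
#' @slot reactions character, deleted reaction ids.
#' @slot geneSets list of minimal gene deletion sets realizing the
#'   reaction deletions (empty until gene mapping is run).
#' @slot growth numeric(1), predicted maximum specific growth.
#' @slot targetFlux numeric(1), target flux maximized at maximal growth
#'   (lexicographic).
#' @slot targetFluxMin numeric(1), guaranteed minimum target flux at
#'   maximal growth.
#' @slot yield numeric(1), predicted mass yield (g product / g substrate).
#' @slot target character(1), target reaction id.
#' @slot gap numeric(1), MILP optimality gap at return.
#' @slot bound numeric(1), best MILP dual bound.
#' @seealso [solveOptKnock()], [verifyStrategy()]
#' @export
setClass("KnockoutStrategy",
  representation(reactions = "character", geneSets = "list",
                 growth = "numeric", targetFlux = "numeric",
                 targetFluxMin = "numeric", yield = "numeric",
                 target = "character", gap = "numeric", bound = "numeric"))

setMethod("show", "MetabolicModel", function(object) {
  k <- table(factor(object@reactions$kind,
                    c("exchange", "transport", "internal",
                      "biomass", "maintenance")))
  cat("MetabolicModel:", nrow(object@metabolites), "metabolites,",
      nrow(object@reactions), "reactions,",
      length(object@genes), "genes\n")
  cat("  compartments:", paste(sort(unique(object@metabolites$compartment)),
                               collapse = ", "), "\n")
  cat("  kinds:", paste(sprintf("%s=%d", names(k), k), collapse = " "), "\n")
  cat("  objective:", object@objective, "\n")
})

setMethod("show", "FluxDistribution", function(object) {
  cat("FluxDistribution: status", object@status)
  if (object@status == "optimal")
    cat(", objective", format(object@objective, digits = 10))
  cat("\n")
  if (object@status == "optimal") {
    nz <- object@fluxes[abs(object@fluxes) > 1e-9]
    cat("  ", length(nz), "of", length(object@fluxes),
        "reactions carry flux\n")
  }
})

setMethod("show", "ProductionEnvelope", function(object) {
  cat("ProductionEnvelope for", object@target, "over",
      length(object@growth), "growth points\n")
  print(utils::head(as.data.frame(object), 6L))
})

setMethod("show", "KnockoutStrategy", function(object) {
  cat("KnockoutStrategy: delete {",
      paste(object@reactions, collapse = ", "), "}\n")
  cat(sprintf("  growth %.6g, target %s max %.6g min %.6g, yield %.6g g/g\n",
              object@growth, object@target, object@targetFlux,
              object@targetFluxMin, object@yield))
  if (length(object@geneSets))
    cat("  gene sets:",
        paste(vapply(object@geneSets,
                     function(g) paste(g$genes, collapse = "+"),
                     character(1)), collapse = " | "), "\n")
})

#' @describeIn ProductionEnvelope-class coerce to a data.frame with
#'   columns growth, min, max.
#' @param x a \code{ProductionEnvelope}.
#' @param ... unused.
#' @export
as.data.frame.ProductionEnvelope <- function(x, ...) {
  data.frame(growth = x@growth, min = x@min, max = x@max)
}
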