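#' @name accessors
#' @title Accessors for MetabolicModel and result objects
#' @description Slot access goes through these accessors; camelCase
#'   generics with methods for the package classes.
#' @param object a package object.
#' @param value replacement value.
NULL

#' @rdname accessors
#' @export
setGeneric("reactionIds", function(object) standardGeneric("reactionIds"))
#' @rdname accessors
#' @export
setGeneric("metaboliteIds", function(object) standardGeneric("metaboliteIds"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("objectiveId", function(object) standardGeneric("objectiveId"))
#' @rdname accessors
#' @export
setGeneric("stoichiometricMatrix",
           function(object) standardGeneric("stoichiometricMatrix"))
#' @rdname accessors
#' @export
setGeneric("lowerBounds", function(object) standardGeneric("lowerBounds"))
#' @rdname accessors
#' @export
setGeneric("upperBounds", function(object) standardGeneric("upperBounds"))
#' @rdname accessors
#' @export
setGeneric("reactionKinds", function(object) standardGeneric("reactionKinds"))
#' @rdname accessors
#' @export
setGeneric("gprRules", function(object) standardGeneric("gprRules"))
#' @rdname accessors
#' @export
setGeneric("fluxes", function(object) standardGeneric("fluxes"))
#' @rdname accessors
#' @export
setGeneric("objectiveValue", function(object) standardGeneric("objectiveValue"))
#' @rdname accessors
#' @export
setGeneric("solverStatus", function(object) standardGeneric("solverStatus"))
#' @rdname accessors
#' @export
setGeneric("deletedReactions",
           function(object) standardGeneric("deletedReactions"))

#' @rdname accessors
#' @export
setMethod("reactionIds", "MetabolicModel",
          function(object) object@reactions$id)
#' @rdname accessors
#' @export
setMethod("metaboliteIds", "MetabolicModel",
          function(object) object@metabolites$id)
#' @rdname accessors
#' @export
setMethod("geneIds", "MetabolicModel", function(object) object@genes)
#' @rdname accessors
#' @export
setMethod("objectiveId", "MetabolicModel", function(object) object@objective)
#' @rdname accessors
#' @export
setMethod("stoichiometricMatrix", "MetabolicModel",
          function(object) object@stoichiometry)
#' @rdname accessors
#' @export
setMethod("lowerBounds", "MetabolicModel",
          function(object) stats::setNames(object@reactions$lb,
                                           object@reactions$id))
#' @rdname accessors
#' @export
setMethod("upperBounds", "MetabolicModel",
          function(object) stats::setNames(object@reactions$ub,
                                           object@reactions$id))
#' @rdname accessors
#' @export
setMethod("reactionKinds", "MetabolicModel",
          function(object) stats::setNames(object@reactions$kind,
                                           object@reactions$id))
#' @rdname accessors
#' @export
setMethod("gprRules", "MetabolicModel",
          function(object) stats::setNames(object@reactions$gpr,
                                           object@reactions$id))

#' @rdname accessors
#' @export
setMethod("fluxes", "FluxDistribution", function(object) object@fluxes)
#' @rdname accessors
#' @export
setMethod("objectiveValue", "FluxDistribution",
          function(object) object@objective)
#' @rdname accessors
#' @export
setMethod("solverStatus", "FluxDistribution",
          function(object) object@status)
#' @rdname accessors
#' @export
setMethod("deletedReactions", "KnockoutStrategy",
          function(object) object@reactions)

rxnIndex <- function(model, id) {
  k <- match(id, model@reactions$id)
  if (anyNA(k))
    stop("unknown reaction id(s): ", paste(id[is.na(k)], collapse = ", "))
  k
}

#' Parsed GPR expression of one reaction
#' @param model a [MetabolicModel-class].
#' @param reaction_id reaction id.
#' @return a \code{"gpr"} expression (see [parseGPR()]).
#' @export
gprOf <- function(model, reaction_id) {
  parseGPR(model@reactions$gpr[rxnIndex(model, reaction_id)])
}

#' Compartment-stripped species identity of metabolites
#'
#' Metabolite ids follow \code{<species>_<compartment>}; the base species
#' is the id with the compartment suffix removed. Two metabolites with
#' the same base species in different compartments are the same chemical
#' entity, which is what transport detection keys on.
#'
#' @param model a [MetabolicModel-class].
#' @return named character, base species per metabolite id.
#' @export
baseSpecies <- function(model) {
  ids <- model@metabolites$id
  comp <- model@metabolites$compartment
  out <- ifelse(endsWith(ids, paste0("_", comp)),
                substr(ids, 1L, nchar(ids) - nchar(comp) - 1L),
                ids)
  stats::setNames(out, ids)
}

#' Classify a reaction by its structure
#'
#' A reaction is an \emph{exchange} iff it touches exactly one metabolite
#' (a system-boundary reaction; negative flux = uptake); a
#' \emph{transport} iff its metabolites span at least two compartments
#' and some base species occurs in more than one of them; \emph{biomass}
#' or \emph{maintenance} iff tagged so when the model was built;
#' otherwise \emph{internal}. Every reaction receives exactly one kind.
#'
#' @param model a [MetabolicModel-class].
#' @param reaction_id reaction id.
#' @return character(1) kind.
#' @export
classifyReaction <- function(model, reaction_id) {
  k <- rxnIndex(model, reaction_id)
  tagged <- model@reactions$kind[k]
  if (tagged %in% c("biomass", "maintenance")) return(tagged)
  classifyStructurally(model@stoichiometry, model@metabolites, k)
}

classifyStructurally <- function(S, metabolites, k) {
  co <- S[, k]
  mets <- metabolites$id[co != 0]
  if (length(mets) == 1L) return("exchange")
  comp <- metabolites$compartment[match(mets, metabolites$id)]
  if (length(unique(comp)) >= 2L) {
    ids <- metabolites$id
    bs <- ifelse(endsWith(ids, paste0("_", metabolites$compartment)),
                 substr(ids, 1L, nchar(ids) - nchar(metabolites$compartment) - 1L),
                 ids)
    if (any(table(stats::setNames(bs, ids)[mets]) > 1L)) return("transport")
  }
  "internal"
}
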