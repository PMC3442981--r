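#' Write / read a model in the native JSON schema
#'
#' The schema (versioned \code{"budstrain-model/1"}) is a lossless,
#' line-oriented serialization of a [MetabolicModel-class]: metabolites
#' (id, name, compartment), reactions (id, name, bounds, GPR string,
#' kind, stoichiometry), the gene inventory, and the objective id.
#'
#' @param model a [MetabolicModel-class].
#' @param path file path.
#' @return \code{readModelJSON} returns a validated
#'   [MetabolicModel-class]; \code{writeModelJSON} returns \code{path}
#'   invisibly.
#' @examples
#' p <- tempfile(fileext = ".json")
#' writeModelJSON(makePyrcore(), p)
#' m <- readModelJSON(p)
#' @export
writeModelJSON <- function(model, path) {
  stopifnot(is(model, "MetabolicModel"))
  validObject(model)
  S <- model@stoichiometry
  rxns <- lapply(seq_len(nrow(model@reactions)), function(k) {
    r <- model@reactions[k, ]
    co <- S[, k]
    co <- co[co != 0]
    list(id = r$id, name = r$name, lb = r$lb, ub = r$ub, gpr = r$gpr,
         kind = r$kind, stoichiometry = as.list(co))
  })
  doc <- list(schema = "budstrain-model/1",
              metabolites = lapply(seq_len(nrow(model@metabolites)),
                function(i) as.list(model@metabolites[i, ])),
              reactions = rxns,
              genes = as.list(model@genes),
              objective = model@objective)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeModelJSON
#' @export
readModelJSON <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  need <- function(key) {
    if (is.null(doc[[key]]))
      stop("model JSON schema error at /", key, ": required key missing")
    doc[[key]]
  }
  schema <- need("schema")
  if (!identical(schema, "budstrain-model/1"))
    stop("model JSON schema error at /schema: expected budstrain-model/1, got ",
         schema)
  mets <- need("metabolites"); rxns <- need("reactions")
  metdf <- data.frame(
    id = vapply(mets, function(x) x$id, character(1)),
    name = vapply(mets, function(x) x$name %||% x$id, character(1)),
    compartment = vapply(mets, function(x) x$compartment, character(1)))
  rxndf <- data.frame(
    id = vapply(rxns, function(x) x$id, character(1)),
    name = vapply(rxns, function(x) x$name %||% x$id, character(1)),
    lb = vapply(rxns, function(x) as.numeric(x$lb %||%
      stop("model JSON schema error at /reactions/", x$id,
           "/lb: missing bound")), numeric(1)),
    ub = vapply(rxns, function(x) as.numeric(x$ub %||%
      stop("model JSON schema error at /reactions/", x$id,
           "/ub: missing bound")), numeric(1)),
    gpr = vapply(rxns, function(x) x$gpr %||% "", character(1)),
    kind = vapply(rxns, function(x) x$kind %||% NA_character_,
                  character(1)))
  sto <- lapply(rxns, function(x) {
    co <- x$stoichiometry
    if (is.null(co) || length(co) == 0L)
      stop("model JSON schema error at /reactions/", x$id,
           "/stoichiometry: missing or empty")
    stats::setNames(vapply(co, as.numeric, numeric(1)), names(co))
  })
  names(sto) <- rxndf$id
  metabolicModel(metdf, rxndf, sto,
                 genes = unlist(doc$genes) %||% NULL,
                 objective = need("objective"))
}

sbmlNs <- c(
  l3 = "http://www.sbml.org/sbml/level3/version1/core",
  fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2",
  l2 = "http://www.sbml.org/sbml/level2/version4")

#' Write a model as SBML
#'
#' Two dialects are supported. \code{"fbc"} (default) writes SBML Level
#' 3 Version 1 with the Flux Balance Constraints (fbc v2) extension:
#' bounds as global parameters, the objective as an fbc objective, and
#' GPRs as nested \code{fbc:and}/\code{fbc:or} gene-product
#' associations. \code{"cobra"} writes the legacy Level 2 dialect used
#' by genome-scale model distributions that predate fbc: bounds as
#' kinetic-law parameters (LOWER_BOUND / UPPER_BOUND /
#' OBJECTIVE_COEFFICIENT) and GPRs as \code{GENE_ASSOCIATION:} notes.
#' Maintenance/biomass tags travel in reaction notes (\code{KIND:}) so
#' round trips preserve them.
#'
#' @param model a [MetabolicModel-class].
#' @param path file path.
#' @param dialect \code{"fbc"} or \code{"cobra"}.
#' @return \code{path}, invisibly.
#' @seealso [readSBML()]
#' @export
writeSBML <- function(model, path, dialect = c("fbc", "cobra")) {
  dialect <- match.arg(dialect)
  stopifnot(is(model, "MetabolicModel"))
  validObject(model)
  if (dialect == "fbc") writeSBMLfbc(model, path) else
    writeSBMLcobra(model, path)
  invisible(path)
}

xesc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

sbmlNotes <- function(kind, gpr = NULL, indent = "        ") {
  lines <- character()
  if (kind %in% c("biomass", "maintenance"))
    lines <- c(lines, sprintf("<p>KIND: %s</p>", kind))
  if (!is.null(gpr) && nzchar(gpr))
    lines <- c(lines, sprintf("<p>GENE_ASSOCIATION: %s</p>", xesc(gpr)))
  if (length(lines) == 0L) return(character())
  c(paste0(indent, "<notes>"),
    paste0(indent, '  <body xmlns="http://www.w3.org/1999/xhtml">'),
    paste0(indent, "    ", lines),
    paste0(indent, "  </body>"),
    paste0(indent, "</notes>"))
}

gprToFbcXML <- function(node, indent) {
  pad <- strrep(" ", indent)
  switch(node$op,
    gene = sprintf('%s<fbc:geneProductRef fbc:geneProduct="G_%s"/>',
                   pad, node$gene),
    and = c(sprintf("%s<fbc:and>", pad),
            unlist(lapply(node$args, gprToFbcXML, indent + 2L)),
            sprintf("%s</fbc:and>", pad)),
    or = c(sprintf("%s<fbc:or>", pad),
           unlist(lapply(node$args, gprToFbcXML, indent + 2L)),
           sprintf("%s</fbc:or>", pad)))
}

speciesRefs <- function(co, tag) {
  vapply(names(co), function(m) sprintf(
    '            <speciesReference species="%s" stoichiometry="%.15g" constant="true"/>',
    m, abs(co[[m]])), character(1))
}

writeSBMLfbc <- function(model, path) {
  S <- model@stoichiometry
  comps <- sort(unique(model@metabolites$compartment))
  num <- function(x) sprintf("%.15g", x)
  # bounds as shared parameters keyed by value
  vals <- sort(unique(c(model@reactions$lb, model@reactions$ub)))
  pid <- stats::setNames(sprintf("bnd_%d", seq_along(vals)), num(vals))
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
            sbmlNs[["l3"]], sbmlNs[["fbc"]]),
    '  <model id="model" fbc:strict="true">',
    "    <listOfCompartments>",
    sprintf('      <compartment id="%s" constant="true"/>', comps),
    "    </listOfCompartments>",
    "    <listOfSpecies>")
  for (i in seq_len(nrow(model@metabolites))) {
    m <- model@metabolites[i, ]
    out <- c(out, sprintf(
      '      <species id="%s" name="%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
      m$id, xesc(m$name), m$compartment))
  }
  out <- c(out, "    </listOfSpecies>", "    <listOfParameters>",
           sprintf('      <parameter id="%s" value="%s" constant="true"/>',
                   pid, names(pid)),
           "    </listOfParameters>", "    <listOfReactions>")
  for (k in seq_len(nrow(model@reactions))) {
    r <- model@reactions[k, ]
    co <- S[, k]; co <- co[co != 0]
    out <- c(out, sprintf(
      '      <reaction id="%s" name="%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">',
      r$id, xesc(r$name), tolower(r$lb < 0), pid[[num(r$lb)]],
      pid[[num(r$ub)]]))
    out <- c(out, sbmlNotes(r$kind))
    if (any(co < 0))
      out <- c(out, "        <listOfReactants>",
               speciesRefs(co[co < 0]), "        </listOfReactants>")
    if (any(co > 0))
      out <- c(out, "        <listOfProducts>",
               speciesRefs(co[co > 0]), "        </listOfProducts>")
    if (nzchar(r$gpr))
      out <- c(out, "        <fbc:geneProductAssociation>",
               gprToFbcXML(parseGPR(r$gpr), 10L),
               "        </fbc:geneProductAssociation>")
    out <- c(out, "      </reaction>")
  }
  out <- c(out, "    </listOfReactions>",
           "    <fbc:listOfObjectives fbc:activeObjective=\"obj\">",
           '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
           "        <fbc:listOfFluxObjectives>",
           sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
                   model@objective),
           "        </fbc:listOfFluxObjectives>",
           "      </fbc:objective>",
           "    </fbc:listOfObjectives>",
           "    <fbc:listOfGeneProducts>",
           sprintf('      <fbc:geneProduct fbc:id="G_%s" fbc:label="%s"/>',
                   model@genes, model@genes),
           "    </fbc:listOfGeneProducts>",
           "  </model>", "</sbml>")
  writeLines(out, path)
}

writeSBMLcobra <- function(model, path) {
  S <- model@stoichiometry
  comps <- sort(unique(model@metabolites$compartment))
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" level="2" version="4">', sbmlNs[["l2"]]),
    '  <model id="model">',
    "    <listOfCompartments>",
    sprintf('      <compartment id="%s"/>', comps),
    "    </listOfCompartments>",
    "    <listOfSpecies>",
    sprintf('      <species id="%s" name="%s" compartment="%s" boundaryCondition="false"/>',
            model@metabolites$id, xesc(model@metabolites$name),
            model@metabolites$compartment),
    "    </listOfSpecies>",
    "    <listOfReactions>")
  for (k in seq_len(nrow(model@reactions))) {
    r <- model@reactions[k, ]
    co <- S[, k]; co <- co[co != 0]
    obj <- as.numeric(r$id == model@objective)
    out <- c(out, sprintf(
      '      <reaction id="%s" name="%s" reversible="%s">',
      r$id, xesc(r$name), tolower(r$lb < 0)),
      sbmlNotes(r$kind, r$gpr))
    if (any(co < 0))
      out <- c(out, "        <listOfReactants>",
               speciesRefs(co[co < 0]), "        </listOfReactants>")
    if (any(co > 0))
      out <- c(out, "        <listOfProducts>",
               speciesRefs(co[co > 0]), "        </listOfProducts>")
    out <- c(out,
      "        <kineticLaw>",
      "          <listOfParameters>",
      sprintf('            <parameter id="LOWER_BOUND" value="%.15g"/>', r$lb),
      sprintf('            <parameter id="UPPER_BOUND" value="%.15g"/>', r$ub),
      sprintf('            <parameter id="OBJECTIVE_COEFFICIENT" value="%g"/>', obj),
      "          </listOfParameters>",
      "        </kineticLaw>",
      "      </reaction>")
  }
  writeLines(c(out, "    </listOfReactions>", "  </model>", "</sbml>"),
             path)
}

#' Read a constraint-based model from SBML
#'
#' Auto-detects the dialect: SBML Level 3 with the fbc extension
#' (bounds as flux-bound parameters, GPRs as gene-product associations)
#' or legacy Level 2 with COBRA-style notes (kinetic-law LOWER_BOUND /
#' UPPER_BOUND parameters, \code{GENE_ASSOCIATION:} notes,
#' OBJECTIVE_COEFFICIENT marking the biomass reaction). The detected
#' dialect and the model size are reported with \code{message()}.
#' Conventions for external files: \code{M_}/\code{R_}/\code{G_} id
#' prefixes are stripped when every id carries them; species flagged
#' \code{boundaryCondition="true"} are dropped from stoichiometries (so
#' boundary-species exchange reactions become single-metabolite
#' exchanges); a reaction with \code{KIND:} notes, or failing that an
#' id of \code{ATPM}, is tagged maintenance.
#'
#' @param path an SBML file.
#' @return a validated [MetabolicModel-class].
#' @export
readSBML <- function(path) {
  doc <- xml2::read_xml(path)
  root <- xml2::xml_name(doc)
  if (root != "sbml") stop("not an SBML document: root element is ", root)
  level <- xml2::xml_attr(doc, "level")
  ns <- xml2::xml_ns(doc)
  has_fbc <- any(grepl("/fbc/", unlist(ns)))
  dialect <- if (has_fbc) "fbc" else "cobra-notes"
  xml2::xml_ns_strip(doc)   # query by local names across dialects

  species <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  sid <- xml2::xml_attr(species, "id")
  sbound <- xml2::xml_attr(species, "boundaryCondition") %in% "true"
  stripPrefix <- function(ids, pre)
    if (length(ids) && all(startsWith(ids, pre)))
      substring(ids, nchar(pre) + 1L) else ids
  sid_clean <- stripPrefix(sid, "M_")
  metdf <- data.frame(
    id = sid_clean,
    name = ifelse(is.na(xml2::xml_attr(species, "name")), sid_clean,
                  xml2::xml_attr(species, "name")),
    compartment = xml2::xml_attr(species, "compartment"))[!sbound, ]
  boundary <- sid[sbound]

  rnodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (length(rnodes) == 0L) stop("SBML file declares no reactions")
  rid_raw <- xml2::xml_attr(rnodes, "id")
  rid <- stripPrefix(rid_raw, "R_")

  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  readStoich <- function(node) {
    refs <- xml2::xml_find_all(node, "./listOfReactants/speciesReference")
    pros <- xml2::xml_find_all(node, "./listOfProducts/speciesReference")
    getco <- function(nodes, sign) {
      sp <- xml2::xml_attr(nodes, "species")
      st <- as.numeric(xml2::xml_attr(nodes, "stoichiometry"))
      st[is.na(st)] <- 1
      keep <- !(sp %in% boundary)
      stats::setNames(sign * st[keep], stripPrefix(sp, "M_")[keep])
    }
    co <- c(getco(refs, -1), getco(pros, 1))
    tapply(co, names(co), sum)   # merge duplicated species refs
  }
  notesText <- function(node)
    paste(xml2::xml_text(xml2::xml_find_all(node, ".//notes//p")),
          collapse = "\n")

  lb <- ub <- numeric(length(rnodes))
  gpr <- character(length(rnodes)); kind <- rep(NA_character_, length(rnodes))
  objective <- NA_character_
  sto <- vector("list", length(rnodes))
  genes <- character()

  if (dialect == "fbc") {
    gps <- xml2::xml_find_all(doc, ".//*[local-name()=\'geneProduct\']")
    glab <- stats::setNames(
      stripPrefix(xml2::xml_attr(gps, "label"), "G_"),
      xml2::xml_attr(gps, "id"))
    genes <- unname(glab)
    fo <- xml2::xml_find_first(doc, ".//*[local-name()=\'fluxObjective\']")
    if (!inherits(fo, "xml_missing"))
      objective <- stripPrefix(xml2::xml_attr(fo, "reaction"), "R_")
    assocToRule <- function(node) {
      nm <- xml2::xml_name(node)
      if (nm == "geneProductRef") {
        gp <- xml2::xml_attr(node, "geneProduct")
        return(if (gp %in% names(glab)) glab[[gp]]
               else stripPrefix(gp, "G_"))
      }
      kids <- xml2::xml_children(node)
      parts <- vapply(kids, assocToRule, character(1))
      paste0("(", paste(parts, collapse = paste0(" ", nm, " ")), ")")
    }
  }

  for (k in seq_along(rnodes)) {
    node <- rnodes[[k]]
    sto[[k]] <- readStoich(node)
    nt <- notesText(node)
    if (grepl("KIND:\\s*maintenance", nt)) kind[k] <- "maintenance"
    if (grepl("KIND:\\s*biomass", nt)) kind[k] <- "biomass"
    if (dialect == "fbc") {
      lbp <- xml2::xml_attr(node, "lowerFluxBound")
      ubp <- xml2::xml_attr(node, "upperFluxBound")
      if (is.na(lbp) || is.na(ubp) || !(lbp %in% names(pval)) ||
          !(ubp %in% names(pval)))
        stop("reaction ", rid[k], " has no resolvable flux bounds")
      lb[k] <- pval[[lbp]]; ub[k] <- pval[[ubp]]
      ga <- xml2::xml_find_first(node,
        "./*[local-name()=\'geneProductAssociation\']")
      gpr[k] <- if (inherits(ga, "xml_missing")) "" else
        assocToRule(xml2::xml_child(ga))
    } else {
      kp <- xml2::xml_find_all(node, "./kineticLaw//parameter")
      kv <- stats::setNames(as.numeric(xml2::xml_attr(kp, "value")),
                            xml2::xml_attr(kp, "id"))
      if (!all(c("LOWER_BOUND", "UPPER_BOUND") %in% names(kv)))
        stop("reaction ", rid[k], " has no resolvable flux bounds")
      lb[k] <- kv[["LOWER_BOUND"]]; ub[k] <- kv[["UPPER_BOUND"]]
      if (!is.na(kv["OBJECTIVE_COEFFICIENT"]) &&
          kv[["OBJECTIVE_COEFFICIENT"]] != 0)
        objective <- rid[k]
      ga <- regmatches(nt, regexpr("GENE_ASSOCIATION:[^\n]*", nt))
      gpr[k] <- if (length(ga)) trimws(sub("GENE_ASSOCIATION:", "", ga))
        else ""
      gpr[k] <- stripGenePrefix(gpr[k])
    }
  }
  if (is.na(objective))
    stop("SBML file declares no objective (fbc objective or ",
         "OBJECTIVE_COEFFICIENT)")
  kind[is.na(kind) & rid == "ATPM"] <- "maintenance"
  kind[rid == objective] <- "biomass"
  rxndf <- data.frame(
    id = rid,
    name = ifelse(is.na(xml2::xml_attr(rnodes, "name")), rid,
                  xml2::xml_attr(rnodes, "name")),
    lb = lb, ub = ub, gpr = gpr, kind = kind)
  names(sto) <- rid
  mdl <- metabolicModel(metdf, rxndf, sto,
                        genes = if (length(genes)) genes else NULL,
                        objective = objective)
  message(sprintf("read SBML (level %s, %s dialect): %d genes, %d reactions, %d metabolites",
                  level, dialect, length(geneIds(mdl)),
                  length(reactionIds(mdl)), length(metaboliteIds(mdl))))
  mdl
}

# legacy notes often write gene ids with a G_ prefix inside rules
stripGenePrefix <- function(rule) gsub("\\bG_([A-Za-z0-9_.-]+)", "\\1", rule)
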